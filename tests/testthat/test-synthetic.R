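test_that("generators are bit-identical under a fixed seed", {
  a <- generate_toy_protein(toy_hydrolase_layout(),
                            sequence = toy_hydrolase_sequence())
  b <- generate_toy_protein(toy_hydrolase_layout(),
                            sequence = toy_hydrolase_sequence())
  expect_identical(a$frames[[1]]$xyz, b$frames[[1]]$xyz)

  s1 <- generate_volume_series(1e-5, 1000, 50, seed = 8)
  s2 <- generate_volume_series(1e-5, 1000, 50, seed = 8)
  expect_identical(s1$volumes, s2$volumes)

  k1 <- generate_kinetics_dataset(30, 2, noise_cv = 0.05, seed = 8)
  k2 <- generate_kinetics_dataset(30, 2, noise_cv = 0.05, seed = 8)
  expect_identical(k1, k2)

  tp <- small_toy()
  w1 <- generate_solvated_box(tp, n_water = 10, seed = 8)
  w2 <- generate_solvated_box(tp, n_water = 10, seed = 8)
  expect_identical(w1$frames[[1]]$xyz, w2$frames[[1]]$xyz)
  w3 <- generate_solvated_box(tp, n_water = 10, seed = 9)
  expect_false(identical(w1$frames[[1]]$xyz, w3$frames[[1]]$xyz))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(100)
  before <- .Random.seed
  invisible(generate_volume_series(1e-5, 1000, 10, seed = 3))
  invisible(generate_kinetics_dataset(30, 2, noise_cv = 0.1, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("a zero compressibility target yields a rigid series", {
  s <- generate_volume_series(0, 1000, 20, seed = 1)
  expect_equal(s$volumes, rep(1000, 20))
  expect_equal(beta_t(s, temperature = 313)$beta_t, 0)
})

test_that("unachievable fluctuation targets are refused", {
  # sigma/V >= 0.2 would need enormous beta_T at this volume
  expect_error(generate_volume_series(1, 1000, 10), "not achievable")
})

test_that("breathing trajectories carry the prescribed volume fluctuations", {
  tp <- small_toy()
  part <- assign_secondary_structure(tp$topology, tp$frames[[1]])
  loop_name <- part$name[part$class == "loop"][1]
  target <- 2e-5
  traj <- generate_volume_trajectory(tp, part,
                                     setNames(target, loop_name),
                                     n_frames = 60, seed = 5)
  expect_length(traj$frames, 60)
  vs <- region_volume_series(traj, part, loop_name, sample_interval = 1)
  est <- beta_t(vs, temperature = 313)
  # calibrated geometric injection measured back through the real
  # tessellation; at n = 60 the estimator itself carries ~18% sampling sd
  expect_gt(est$beta_t, target / 2)
  expect_lt(est$beta_t, target * 2)
  # zero-target regions stay rigid
  rigid <- generate_volume_trajectory(tp, part, setNames(0, loop_name),
                                      n_frames = 3, seed = 5)
  expect_equal(rigid$frames[[1]]$xyz, rigid$frames[[3]]$xyz)
})

test_that("two breathing regions rank in the order of their targets", {
  th <- generate_toy_protein(
    data.frame(class = c("helix", "loop", "helix", "loop", "helix"),
               length = c(6, 4, 6, 4, 6)))
  part <- assign_secondary_structure(th$topology, th$frames[[1]])
  loops <- part$name[part$class == "loop"]
  targets <- setNames(c(2e-5, 2e-6), loops)
  traj <- generate_volume_trajectory(th, part, targets, n_frames = 30,
                                     seed = 11)
  grid <- do.call(rbind, lapply(loops, function(rn) {
    vs <- region_volume_series(traj, part, rn, sample_interval = 1)
    data.frame(region = rn, beta_t = beta_t(vs, temperature = 313)$beta_t)
  }))
  # a two-condition grid per region: rigid baseline vs breathing
  grid0 <- data.frame(region = loops, beta_t = 0)
  rk <- sensitivity_ranking(rbind(grid, grid0))
  expect_equal(rk$region[1], loops[1])
})

test_that("solvated boxes honour exact shell counts and composition", {
  tp <- small_toy()
  part <- assign_secondary_structure(tp$topology, tp$frames[[1]])
  site <- region_atoms(part, tp$topology, part$name[2])
  sol <- generate_solvated_box(
    tp, n_water = 15, n_ethanol = 4,
    shells = list(list(type = "water", count = 3, site_atoms = site,
                       dmin = 2.5, dmax = 5)),
    seed = 12)
  expect_equal(sum(sol$topology$mol_class == "water"), 45) # 15 x 3 atoms
  expect_equal(sum(sol$topology$mol_class == "ethanol"), 12)
  sc <- count_solvent_near(sol$frames[[1]], sol$topology, site, cutoff = 5)
  expect_equal(sc$n_water, 3L)
  # no ethanol requested near the site
  expect_equal(sc$n_ethanol, 0L)
  # a box without ethanol counts none anywhere
  dry <- generate_solvated_box(tp, n_water = 5, n_ethanol = 0, seed = 2)
  sc2 <- count_solvent_near(dry$frames[[1]], dry$topology,
                            seq_len(nrow(tp$topology)), cutoff = 50)
  expect_equal(sc2$n_ethanol, 0L)
})

test_that("solvent placement respects the minimum separation", {
  tp <- small_toy()
  sol <- generate_solvated_box(tp, n_water = 20, seed = 3, min_sep = 2)
  xyz <- sol$frames[[1]]$xyz
  topo <- sol$topology
  wat_o <- which(topo$mol_class == "water" & topo$element == "O")
  prot <- which(topo$mol_class == "protein")
  for (o in wat_o) {
    d2 <- dhpmd:::.min_image_dist2(xyz[prot, , drop = FALSE], xyz[o, ],
                                   sol$frames[[1]]$box)
    expect_gte(sqrt(min(d2)), 2)
  }
})

test_that("noiseless kinetics data lies exactly on the curve", {
  d <- generate_kinetics_dataset(40, 3, levels = c(10, 40, 100, 300))
  expect_equal(d$rate, 3 * d$substrate_mM / (40 + d$substrate_mM))
  expect_equal(d$rate[d$substrate_mM == 40], 1.5) # S = Km -> Vmax/2
  expect_error(generate_kinetics_dataset(40, 3, levels = c(10, 400)))
})

test_that("overlapping breathing regions are rejected", {
  tp <- small_toy()
  # hand-built partition bypassing the constructor's overlap guard, to
  # exercise the generator's own independence check
  part <- structure(
    data.frame(name = c("a", "b"), class = "loop",
               start = c(1, 1), end = c(4, 12), stringsAsFactors = FALSE),
    class = c("region_partition", "data.frame"))
  expect_error(
    generate_volume_trajectory(tp, part, c(a = 1e-5, b = 1e-5), n_frames = 3),
    "overlap")
})
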