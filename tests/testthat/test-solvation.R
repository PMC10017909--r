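solvated_fixture <- function() {
  # single-atom protein site at the box centre, one water with its O at 3 A,
  # one ethanol with all heavy atoms at >= 6 A
  topo <- topology(
    atom_name = c("CA", "OW", "HW1", "HW2", "C1", "C2", "OE"),
    element = c("C", "O", "H", "H", "C", "C", "O"),
    resid = c(1, 1, 1, 1, 1, 1, 1),
    resname = c("ALA", "SOL", "SOL", "SOL", "ETH", "ETH", "ETH"),
    mol_class = c("protein", rep("water", 3), rep("ethanol", 3)))
  xyz <- rbind(c(10, 10, 10),
               c(13, 10, 10), c(13.9, 10, 10), c(12.7, 10.9, 10),
               c(16, 10, 10), c(17.2, 10, 10), c(18, 10.5, 10))
  md_trajectory(topo, list(md_frame(xyz, c(20, 20, 20))))
}

test_that("solvent-free systems count zero molecules", {
  tp <- small_toy()
  sc <- count_solvent_near(tp$frames[[1]], tp$topology, site_atoms = 1,
                           cutoff = 5)
  expect_equal(sc$n_water, 0L)
  expect_equal(sc$n_ethanol, 0L)
})

test_that("molecules are counted once when any atom enters the cutoff", {
  fx <- solvated_fixture()
  sc <- count_solvent_near(fx$frames[[1]], fx$topology, site_atoms = 1,
                           cutoff = 5)
  expect_equal(sc$n_water, 1L)
  expect_equal(sc$n_ethanol, 0L)
  # ethanol enters at a wider cutoff, still counted once despite 3 atoms
  sc2 <- count_solvent_near(fx$frames[[1]], fx$topology, site_atoms = 1,
                            cutoff = 7)
  expect_equal(sc2$n_ethanol, 1L)
})

test_that("minimum-image distances count solvent across the boundary", {
  topo <- topology(atom_name = c("CA", "OW", "HW1", "HW2"),
                   element = c("C", "O", "H", "H"),
                   resid = c(1, 1, 1, 1),
                   resname = c("ALA", "SOL", "SOL", "SOL"),
                   mol_class = c("protein", rep("water", 3)))
  xyz <- rbind(c(0.2, 5, 5), c(9.7, 5, 5), c(9.0, 5.3, 5), c(9.4, 4.5, 5))
  fr <- md_frame(xyz, c(10, 10, 10))
  sc <- count_solvent_near(fr, topo, site_atoms = 1, cutoff = 5)
  expect_equal(sc$n_water, 1L) # O is 0.5 A away through the boundary
  sc2 <- count_solvent_near(fr, topo, site_atoms = 1, cutoff = 0.4)
  expect_equal(sc2$n_water, 0L)
})

test_that("solvent counts are invariant under box translation", {
  fx <- solvated_fixture()
  f <- fx$frames[[1]]
  shifted <- md_frame(sweep(f$xyz, 2, c(7.7, -3.1, 15.9), "+"), f$box)
  a <- count_solvent_near(f, fx$topology, 1, 5)
  b <- count_solvent_near(shifted, fx$topology, 1, 5)
  expect_equal(a$n_water, b$n_water)
  expect_equal(a$n_ethanol, b$n_ethanol)
})

test_that("cutoff sweep is monotone non-decreasing", {
  fx <- solvated_fixture()
  sw <- solvent_count_sweep(fx$frames[[1]], fx$topology, 1, cutoffs = 3:8)
  expect_true(all(diff(sw$n_water) >= 0))
  expect_true(all(diff(sw$n_ethanol) >= 0))
})

test_that("SASA of an isolated sphere matches the closed form", {
  topo <- topology("X", "C", 1, "ALA", "protein", radius = 1.4)
  fr <- md_frame(matrix(c(10, 10, 10), 1, 3), c(30, 30, 30))
  s <- sasa(fr, topo, subset = 1, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(s$total, 4 * pi * 2.8^2, tolerance = 1e-6)
  expect_equal(s$hydrophobic, s$total) # carbon is apolar
  expect_equal(s$hydrophilic + s$hydrophobic, s$total, tolerance = 1e-9)
})

test_that("tangent and overlapping sphere pairs match closed forms", {
  mk <- function(d) {
    topo <- topology(c("X", "Y"), c("C", "O"), c(1, 2), c("ALA", "ALA"),
                     c("protein", "protein"), radius = c(1.4, 1.4))
    fr <- md_frame(rbind(c(15, 15, 15), c(15 + d, 15, 15)), c(40, 40, 40))
    sasa(fr, topo, probe_radius = 1.4, n_sphere_points = 960)
  }
  R <- 2.8
  # tangent expanded spheres: no occlusion
  s_t <- mk(2 * R)
  expect_equal(s_t$total, 2 * 4 * pi * R^2, tolerance = 1e-6)
  # overlapping: each sphere loses a cap of height h = R - d/2
  for (d in c(3, 4, 5)) {
    s_o <- mk(d)
    h <- R - d / 2
    expect_equal(s_o$total, 2 * (4 * pi * R^2 - 2 * pi * R * h),
                 tolerance = 0.01 * 2 * 4 * pi * R^2)
  }
  # polar split follows the elements (one C, one O)
  s <- mk(4)
  expect_equal(s$hydrophilic, s$total / 2, tolerance = 0.01)
})

test_that("a fully enclosed atom has zero SASA and removal is monotone", {
  centre <- c(15, 15, 15)
  shell <- 2 * rbind(diag(3), -diag(3))
  topo <- topology(rep("X", 7), rep("C", 7), 1:7, rep("ALA", 7),
                   rep("protein", 7), radius = rep(1.4, 7))
  fr <- md_frame(rbind(centre, sweep(shell, 2, centre, "+")), c(40, 40, 40))
  s_full <- sasa(fr, topo, probe_radius = 1.4, n_sphere_points = 960)
  expect_equal(unname(s_full$per_atom[1]), 0)
  # drop one shell atom: every remaining atom's exposure can only grow
  s_less <- sasa(fr, topo, subset = 1:6, probe_radius = 1.4,
                 n_sphere_points = 960)
  expect_true(all(s_less$per_atom[1:6] >= s_full$per_atom[1:6] - 1e-9))
  expect_gt(unname(s_less$per_atom[1]), 0)
})

test_that("ideal and too-distant hydrogen-bond geometries are separated", {
  topo <- topology(c("N", "H", "O"), c("N", "H", "O"), c(1, 1, 2),
                   c("ALA", "ALA", "SER"), rep("protein", 3))
  near <- md_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(2.9, 0, 0)), c(30, 30, 30))
  far <- md_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(4.0, 0, 0)), c(30, 30, 30))
  expect_equal(nrow(detect_hbonds(near, topo, 1, 3)), 1)
  expect_equal(nrow(detect_hbonds(far, topo, 1, 3)), 0)
  # bent geometry beyond the angular tolerance
  bent <- md_frame(rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 2.5, 0)),
                   c(30, 30, 30))
  expect_equal(nrow(detect_hbonds(bent, topo, 1, 3)), 0)
})

test_that("random donor/acceptor placements match the brute-force loop", {
  set.seed(55)
  n_d <- 10; n_a <- 10
  dxyz <- matrix(runif(3 * n_d, 5, 15), ncol = 3)
  # hydrogens 1 A from each donor in a random direction
  dirs <- matrix(rnorm(3 * n_d), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  hxyz <- dxyz + dirs
  axyz <- matrix(runif(3 * n_a, 5, 15), ncol = 3)
  # interleave donor/hydrogen pairs so residue indices stay sorted
  xyz <- matrix(0, 2 * n_d + n_a, 3)
  don_idx <- 2 * seq_len(n_d) - 1
  hyd_idx <- 2 * seq_len(n_d)
  acc_idx <- 2 * n_d + seq_len(n_a)
  xyz[don_idx, ] <- dxyz
  xyz[hyd_idx, ] <- hxyz
  xyz[acc_idx, ] <- axyz
  topo <- topology(
    atom_name = c(rbind(rep("N", n_d), rep("H", n_d)), rep("O", n_a)),
    element = c(rbind(rep("N", n_d), rep("H", n_d)), rep("O", n_a)),
    resid = c(rep(seq_len(n_d), each = 2), n_d + seq_len(n_a)),
    resname = rep("ALA", n_d * 2 + n_a),
    mol_class = rep("protein", n_d * 2 + n_a))
  fr <- md_frame(xyz, c(40, 40, 40))
  got <- detect_hbonds(fr, topo, donors = don_idx, acceptors = acc_idx)
  want <- brute_force_hbonds(xyz, don_idx, hyd_idx, acc_idx)
  expect_equal(nrow(got), want)
})

test_that("donors without hydrogens are skipped with a warning", {
  topo <- topology(c("N", "O"), c("N", "O"), c(1, 2), c("ALA", "SER"),
                   rep("protein", 2))
  fr <- md_frame(rbind(c(0, 0, 0), c(2.9, 0, 0)), c(30, 30, 30))
  expect_warning(hb <- detect_hbonds(fr, topo, 1, 2), "no attached hydrogen")
  expect_equal(nrow(hb), 0)
})
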