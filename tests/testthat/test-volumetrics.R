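frame_of <- function(pts, box) md_frame(pts, box)

test_that("single site owns the whole box", {
  v <- voronoi_cell_volumes(frame_of(matrix(c(5, 5, 5), 1, 3), c(10, 10, 10)))
  expect_equal(v, 1000, tolerance = 1e-12)
})

test_that("two symmetric sites split the box in half", {
  v <- voronoi_cell_volumes(frame_of(rbind(c(2.5, 5, 5), c(7.5, 5, 5)),
                                     c(10, 10, 10)))
  expect_equal(v, c(500, 500), tolerance = 1e-10)
})

test_that("simple cubic lattice gives equal cells matching Monte-Carlo", {
  g <- as.matrix(expand.grid(c(2.5, 7.5), c(2.5, 7.5), c(2.5, 7.5)))
  v <- voronoi_cell_volumes(frame_of(g, c(10, 10, 10)))
  expect_equal(v, rep(125, 8), tolerance = 1e-10)
  mc <- mc_voronoi_volumes(g, c(10, 10, 10), n_points = 1e5, seed = 5)
  expect_true(all(abs(mc - 125) / 125 < 0.05))
})

test_that("cell volumes conserve the box volume and match Monte-Carlo", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(5:20, 1)
    box <- runif(3, 8, 15)
    pts <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, 0, box[3]))
    v <- suppressWarnings(voronoi_cell_volumes(frame_of(pts, box)))
    expect_lt(abs(sum(v) - prod(box)) / prod(box), 1e-6)
    mc <- mc_voronoi_volumes(pts, box, n_points = 2e5, seed = rep)
    # MC standard error of a cell fraction ~ sqrt(p/n)*V: allow 3 sigma
    se <- sqrt(pmax(v, 1e-6) / prod(box) / 2e5) * prod(box)
    expect_true(all(abs(v - mc) < 3.5 * se + 0.02 * v))
  }
})

test_that("cell volumes are invariant under rigid box translation", {
  set.seed(7)
  pts <- matrix(runif(30, 0, 12), ncol = 3)
  box <- c(12, 12, 12)
  v1 <- suppressWarnings(voronoi_cell_volumes(frame_of(pts, box)))
  v2 <- suppressWarnings(
    voronoi_cell_volumes(frame_of(sweep(pts, 2, c(4.1, -2.2, 33.3), "+"),
                                  box)))
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("coincident sites are reported as an error naming the pair", {
  pts <- rbind(c(2, 2, 2), c(5, 5, 5), c(2, 2, 2))
  expect_error(suppressWarnings(voronoi_cell_volumes(frame_of(pts, c(10, 10, 10)))),
               "coincident")
})

test_that("a rigid trajectory yields a constant region volume series", {
  tp <- small_toy()
  part <- assign_secondary_structure(tp$topology, tp$frames[[1]])
  traj <- md_trajectory(tp$topology, lapply(0:4, function(t) {
    md_frame(tp$frames[[1]]$xyz, tp$frames[[1]]$box, time = t)
  }))
  vs <- region_volume_series(traj, part, part$name[2], sample_interval = 1)
  expect_length(vs$volumes, 5)
  expect_lt(diff(range(vs$volumes)), 1e-8)
})

test_that("sampling at twice the frame spacing halves the sample count", {
  tp <- small_toy()
  part <- assign_secondary_structure(tp$topology, tp$frames[[1]])
  traj <- md_trajectory(tp$topology, lapply(0:29, function(t) {
    md_frame(tp$frames[[1]]$xyz, tp$frames[[1]]$box, time = t)
  }))
  vs <- region_volume_series(traj, part, part$name[1], sample_interval = 2)
  expect_length(vs$volumes, 15)
  expect_error(region_volume_series(traj, part, part$name[1],
                                    sample_interval = 0.5),
               "below the frame spacing")
})

test_that("isotropic scaling of a lattice scales interior cells by s^3", {
  # 5x5x5 lattice, spacing 2, centred in the box; scaling all sites about
  # the centre scales every interior cell (bounded only by scaled
  # neighbours) by exactly s^3
  g <- as.matrix(expand.grid(-2:2, -2:2, -2:2)) * 2
  interior <- which(apply(abs(g), 1, max) <= 2)
  box <- c(40, 40, 40)
  mk_frame <- function(s) md_frame(sweep(g * s, 2, box / 2, "+"), box)
  v0 <- sum(suppressWarnings(voronoi_cell_volumes(mk_frame(1)))[interior])
  for (s in c(0.9, 1.1)) {
    v <- sum(suppressWarnings(voronoi_cell_volumes(mk_frame(s)))[interior])
    expect_lt(abs(v / v0 - s^3) / s^3, 0.005)
  }
})

test_that("sites pressed against their periodic images raise a warning", {
  # nearest neighbour 15 A apart but the box is only 10 A wide in x/y:
  # both cells press against their own periodic images
  expect_warning(voronoi_cell_volumes(md_frame(rbind(c(5, 5, 2), c(5, 5, 17)),
                                               c(10, 10, 30))),
                 "periodic images")
})
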