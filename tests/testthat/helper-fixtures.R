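# Independent brute-force oracles and small fixtures shared across tests.

# Monte-Carlo nearest-site volume estimate: sample uniform points in the box,
# assign each to its nearest site under the minimum-image convention, and
# scale occupancy fractions by the box volume. Independent of the clipping
# implementation under test.
mc_voronoi_volumes <- function(pts, box, n_points = 2e5, seed = 1) {
  set.seed(seed)
  q <- cbind(runif(n_points, 0, box[1]), runif(n_points, 0, box[2]),
             runif(n_points, 0, box[3]))
  best_d2 <- rep(Inf, n_points)
  best_i <- rep(NA_integer_, n_points)
  for (i in seq_len(nrow(pts))) {
    d <- sweep(q, 2, pts[i, ])
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    d2 <- rowSums(d^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_i[upd] <- i
  }
  tabulate(best_i, nbins = nrow(pts)) / n_points * prod(box)
}

# brute-force hydrogen-bond enumeration with the same geometric criteria,
# written as a plain double loop
brute_force_hbonds <- function(xyz, donors, hydrogens, acceptors,
                               max_da = 3.5, max_dev = 30) {
  hits <- 0
  for (k in seq_along(donors)) {
    d <- donors[k]; h <- hydrogens[k]
    for (a in acceptors) {
      if (a == d) next
      if (sqrt(sum((xyz[a, ] - xyz[d, ])^2)) > max_da) next
      v1 <- xyz[d, ] - xyz[h, ]; v2 <- xyz[a, ] - xyz[h, ]
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (180 - ang <= max_dev) hits <- hits + 1
    }
  }
  hits
}

# a small two-segment toy protein used in several tests
small_toy <- function() {
  generate_toy_protein(data.frame(class = c("helix", "loop"),
                                  length = c(8, 4)))
}

# the 13 consensus mutants of the reference screen
consensus_thirteen <- function() {
  c("A321I", "S325F", "S325Y", "S325N", "Q332E", "Q332G", "H68A", "H68L",
    "H68M", "H68K", "H68Y", "K70R", "A178L")
}

# Table of printed kinetic parameters (Km mM, Vmax umol/min/mg, Kcat 1/s,
# Kcat/Km as printed) for the wild type and mutants of the reference assay
printed_kinetics_table <- function() {
  data.frame(
    variant = c("WT", "S325N", "H68A", "K70R", "A178L", "H68A/S325N",
                "K70R/S325N", "H68A/K70R/S325N"),
    km = c(37.67, 45.52, 31.38, 33.38, 96.78, 33.27, 40.82, 28.2),
    vmax = c(2.22, 1.96, 5.98, 3.78, 3.97, 3.77, 4.33, 2.54),
    kcat = c(18509.92, 16366.99, 49874.79, 31517.63, 33146.88, 26180.56,
             17182.54, 15484.74),
    eff_printed = c(491.42, 359.56, 1589.33, 944.16, 342.48, 786.91,
                    420.93, 549.1))
}
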