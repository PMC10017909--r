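# Natural-extension-reference-frame placement: position atom D bonded to C
# with bond length r, angle theta (B-C-D) and torsion tau (A-B-C-D), degrees.
.place_atom <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-bc * cos(th) + m * sin(th) * cos(ta) - n * sin(th) * sin(ta))
}

.class_dihedrals <- function(class) {
  switch(class,
         helix = c(phi = -57, psi = -47),
         sheet = c(phi = -120, psi = 135),
         loop = c(phi = -70, psi = 150),
         stop("unknown segment class: ", class))
}

#' Generate a toy protein backbone
#'
#' Builds an N/CA/C/O backbone with ideal bond geometry and per-segment
#' ideal dihedrals (helix phi/psi = -57/-47, sheet -120/135, coil -70/150),
#' chained by natural-extension placement. Deterministic given its arguments.
#'
#' @param segments data.frame with columns `class` ("helix"/"sheet"/"loop")
#'   and `length` (residues, >= 1), in chain order.
#' @param sequence optional 1-letter sequence (length = total residues);
#'   poly-alanine when NULL.
#' @param box optional length-3 box (Angstrom); auto-sized to the chain
#'   extent plus `padding` when NULL. An explicit box too small for the
#'   chain is an error.
#' @param padding box padding (Angstrom) in auto mode.
#' @return An [md_trajectory()] with one frame; coordinates shifted into
#'   the positive octant of the box.
#' @export
generate_toy_protein <- function(segments, sequence = NULL, box = NULL,
                                 padding = 12) {
  nres <- sum(segments$length)
  if (any(segments$length < 1)) stop("segment lengths must be >= 1")
  cls <- rep(segments$class, segments$length)
  if (is.null(sequence)) sequence <- rep("A", nres)
  if (length(sequence) != nres) stop("sequence length must equal total residues")
  phi <- psi <- numeric(nres)
  for (i in seq_len(nres)) {
    d <- .class_dihedrals(cls[i])
    phi[i] <- d["phi"]; psi[i] <- d["psi"]
  }
  # bond lengths / angles: standard peptide geometry
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aCNCA <- 121.7; aNCAC <- 111.2; aCACN <- 116.2; aCACO <- 120.8
  N <- CA <- C <- O <- matrix(0, nres, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  th <- aNCAC * pi / 180
  C[1, ] <- CA[1, ] + bCAC * c(-cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    if (i > 1) {
      N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCN, aCACN,
                            psi[i - 1])
      CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bNCA, aCNCA, 180)
      C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], bCAC, aNCAC, phi[i])
    }
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], bCO, aCACO, psi[i] + 180)
  }
  xyz <- matrix(0, 4 * nres, 3)
  xyz[seq(1, 4 * nres, 4), ] <- N
  xyz[seq(2, 4 * nres, 4), ] <- CA
  xyz[seq(3, 4 * nres, 4), ] <- C
  xyz[seq(4, 4 * nres, 4), ] <- O
  ext <- apply(xyz, 2, function(x) diff(range(x)))
  if (is.null(box)) {
    box <- ext + 2 * padding
  } else if (any(box < ext)) {
    stop("box too small to contain the chain (extent ",
         paste(sprintf("%.1f", ext), collapse = " x "), " A)")
  }
  xyz <- sweep(xyz, 2, apply(xyz, 2, min)) # to origin
  xyz <- sweep(xyz, 2, (box - ext) / 2, "+") # center
  resname <- aa1to3(sequence)
  topo <- topology(
    atom_name = rep(c("N", "CA", "C", "O"), nres),
    element = rep(c("N", "C", "C", "O"), nres),
    resid = rep(seq_len(nres), each = 4),
    resname = rep(resname, each = 4),
    mol_class = rep("protein", 4 * nres))
  md_trajectory(topo, list(md_frame(xyz, box, time = 0)))
}

#' Segment layout of the toy hydrolase fixture
#'
#' A 392-residue helix/sheet/loop layout whose loop segments are exactly
#' the six candidate loops of the screening study system: residues 67-76,
#' 82-107, 176-181, 254-261, 320-333 and 381-392.
#'
#' @return data.frame with columns `class`, `length`.
#' @export
toy_hydrolase_layout <- function() {
  data.frame(
    class = c("helix", "loop", "helix", "loop", "helix", "sheet", "loop",
              "helix", "sheet", "loop", "helix", "loop", "sheet", "loop"),
    length = c(66,      10,     5,       26,     33,      35,      6,
               39,      33,     8,       58,     14,      47,      12),
    stringsAsFactors = FALSE)
}

#' Wild-type sequence of the toy hydrolase fixture
#'
#' A deterministic 392-residue sequence with the screening study's
#' wild-type identities fixed at the mutated positions (H68, K70, A178,
#' A321, S325, Q332); all other positions are drawn once from a fixed
#' internal seed and never change.
#'
#' @return Character vector of 392 one-letter codes.
#' @export
toy_hydrolase_sequence <- function() {
  aa <- rownames(aa_properties())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(392001)
  seq <- sample(aa, 392, replace = TRUE)
  seq[68] <- "H"; seq[70] <- "K"; seq[178] <- "A"
  seq[321] <- "A"; seq[325] <- "S"; seq[332] <- "Q"
  seq
}

#' Generate a Gaussian region-volume series with a prescribed beta_T
#'
#' Inverts the fluctuation relation: draws volumes from a normal
#' distribution whose variance is `beta_T * k_B * T * V0` (unit chain as in
#' [beta_t()]), so the compressibility estimator should recover the target.
#'
#' @param target_beta_t target compressibility, bar^-1 (>= 0; zero yields a
#'   constant series).
#' @param mean_volume mean region volume V0, Angstrom^3.
#' @param n number of samples.
#' @param temperature K.
#' @param seed integer seed.
#' @param dt sampling interval, ns.
#' @param region_name series label.
#' @param condition optional [condition()] attached to the series (its
#'   temperature overrides `temperature`).
#' @return A [volume_series()].
#' @export
generate_volume_series <- function(target_beta_t, mean_volume = 1000,
                                   n = 100, temperature = 313, seed = 1,
                                   dt = 1, region_name = "region",
                                   condition = NULL) {
  stopifnot(target_beta_t >= 0, mean_volume > 0, n >= 2)
  if (target_beta_t == 0) {
    return(volume_series(region_name, seq(0, by = dt, length.out = n),
                         rep(mean_volume, n), condition))
  }
  if (!is.null(condition)) temperature <- condition$temperature
  # bar^-1 -> Pa^-1 is 1e-5; A^3 -> m^3 is 1e-30; m^6 -> A^6 is 1e60
  var_A6 <- (target_beta_t * 1e-5) * KB_JOULE_PER_K * temperature *
    (mean_volume * 1e-30) * 1e60
  sigma <- sqrt(var_A6)
  if (sigma / mean_volume >= 0.2) {
    stop("target not achievable: sigma_V/<V> = ",
         sprintf("%.2f", sigma / mean_volume), " >= 0.2")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- stats::rnorm(n, mean_volume, sigma)
  volume_series(region_name, seq(0, by = dt, length.out = n), v, condition)
}

#' Generate a breathing trajectory with prescribed per-region beta_T
#'
#' Starting from a base frame, each target region's heavy-atom Voronoi
#' volume is steered along a Gaussian series (variance from the fluctuation
#' relation) by isotropically scaling the region's coordinates about its
#' centroid; all other atoms stay fixed. This injects volume fluctuations
#' geometrically -- the estimator, not the physics, is what such a
#' trajectory is for.
#'
#' @param traj single-frame [md_trajectory()] (e.g. from
#'   [generate_toy_protein()]).
#' @param partition a [region_partition()].
#' @param targets named numeric vector: region name -> target beta_T
#'   (bar^-1).
#' @param n_frames number of frames to generate.
#' @param dt frame spacing, ns.
#' @param temperature K.
#' @param seed integer seed.
#' @return An [md_trajectory()] with `n_frames` frames at times 0, dt, ...
#' @export
generate_volume_trajectory <- function(traj, partition, targets,
                                       n_frames = 30, dt = 1,
                                       temperature = 313, seed = 1) {
  stopifnot(length(targets) >= 1, !is.null(names(targets)))
  topo <- traj$topology
  base <- traj$frames[[1]]
  ids <- lapply(names(targets), function(rn) {
    region_atoms(partition, topo, rn, scope = "heavy-atom")
  })
  if (length(ids) > 1) {
    for (i in seq_along(ids)[-1]) {
      if (length(intersect(ids[[i]], unlist(ids[seq_len(i - 1)]))) > 0) {
        stop("target regions overlap: cannot scale independently")
      }
    }
  }
  base_vols <- voronoi_cell_volumes(base)
  v0 <- vapply(ids, function(ii) sum(base_vols[ii]), numeric(1))
  # Linear-response calibration: a region's measured Voronoi volume responds
  # to coordinate scaling with less than the naive s^3 gain, because cell
  # faces shared with non-scaled neighbours move only halfway. Probe the
  # response once and amplify the injected scaling accordingly.
  gain <- vapply(seq_along(targets), function(k) {
    s_probe <- 1.02
    xyz <- base$xyz
    cen <- colMeans(xyz[ids[[k]], , drop = FALSE])
    centered <- sweep(xyz[ids[[k]], , drop = FALSE], 2, cen)
    xyz[ids[[k]], ] <- sweep(centered * s_probe, 2, cen, "+")
    v_probe <- sum(voronoi_cell_volumes(md_frame(xyz, base$box))[ids[[k]]])
    (v_probe - v0[k]) / (v0[k] * (s_probe^3 - 1))
  }, numeric(1))
  if (any(gain <= 0)) stop("region volume does not respond to scaling")
  series <- lapply(seq_along(targets), function(k) {
    generate_volume_series(targets[k], v0[k], n_frames, temperature,
                           seed = seed + k, dt = dt,
                           region_name = names(targets)[k])$volumes
  })
  frames <- lapply(seq_len(n_frames), function(f) {
    xyz <- base$xyz
    for (k in seq_along(targets)) {
      dv <- (series[[k]][f] - v0[k]) / gain[k]
      s <- (1 + dv / v0[k])^(1 / 3)
      cen <- colMeans(xyz[ids[[k]], , drop = FALSE])
      centered <- sweep(xyz[ids[[k]], , drop = FALSE], 2, cen)
      xyz[ids[[k]], ] <- sweep(centered * s, 2, cen, "+")
    }
    md_frame(xyz, base$box, time = (f - 1) * dt)
  })
  md_trajectory(topo, frames)
}

.water_template <- function() {
  # O-H 0.96 A, H-O-H 104.5 deg
  rbind(O = c(0, 0, 0),
        H1 = c(0.96, 0, 0),
        H2 = 0.96 * c(cos(104.5 * pi / 180), sin(104.5 * pi / 180), 0))
}

.ethanol_template <- function() {
  # 3 heavy-atom pseudo-molecule: CH3-CH2-OH backbone, 1.5 A bonds
  rbind(C1 = c(0, 0, 0), C2 = c(1.5, 0, 0), O = c(2.2, 1.2, 0))
}

# random rotation matrix from three uniforms (Arvo)
.random_rotation <- function() {
  u <- stats::runif(3)
  th <- 2 * pi * u[1]; ph <- 2 * pi * u[2]; z <- u[3]
  V <- c(cos(ph) * sqrt(z), sin(ph) * sqrt(z), sqrt(1 - z))
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  (2 * V %o% V - diag(3)) %*% R
}

#' Solvate a protein frame with pseudo-molecule water and ethanol
#'
#' Places 3-atom water and 3-heavy-atom ethanol pseudo-molecules into the
#' frame's box: shell placements first (exact counts within stated distance
#' bands of named site atoms), then bulk molecules at random positions. All
#' placements keep at least `min_sep` between any new atom and every
#' existing atom (minimum image); bulk molecules also stay clear of the
#' shell bands so shell counts remain exact. Deterministic given the seed.
#'
#' @param traj single-frame [md_trajectory()] of the solute.
#' @param n_water,n_ethanol total molecule counts (shell placements
#'   included).
#' @param shells optional list of shell specs, each a list with `type`
#'   ("water"/"ethanol"), `count`, `site_atoms` (atom ids), `dmin`, `dmax`
#'   (Angstrom band around the site).
#' @param seed integer seed.
#' @param min_sep minimum atom separation, Angstrom (default 2).
#' @param max_tries placement retries per molecule before failing.
#' @return A single-frame [md_trajectory()] with solvent appended.
#' @export
generate_solvated_box <- function(traj, n_water = 0, n_ethanol = 0,
                                  shells = NULL, seed = 1, min_sep = 2,
                                  max_tries = 2000) {
  topo <- traj$topology
  frame <- traj$frames[[1]]
  box <- frame$box
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  placed_xyz <- frame$xyz
  new_atoms <- list()
  counts <- c(water = 0L, ethanol = 0L)
  wanted <- c(water = as.integer(n_water), ethanol = as.integer(n_ethanol))
  tmpl <- list(water = .water_template(), ethanol = .ethanol_template())
  min_ok <- function(mol_xyz) {
    for (i in seq_len(nrow(mol_xyz))) {
      if (any(.min_image_dist2(placed_xyz, mol_xyz[i, ], box) < min_sep^2)) {
        return(FALSE)
      }
    }
    TRUE
  }
  add_mol <- function(type, mol_xyz) {
    counts[type] <<- counts[type] + 1L
    nm <- if (type == "water") c("OW", "HW1", "HW2") else c("C1", "C2", "OE")
    el <- if (type == "water") c("O", "H", "H") else c("C", "C", "O")
    rn <- if (type == "water") "SOL" else "ETH"
    new_atoms[[length(new_atoms) + 1L]] <<- list(
      xyz = mol_xyz, name = nm, element = el, resname = rn, class = type,
      resid = counts[type])
    placed_xyz <<- rbind(placed_xyz, mol_xyz)
  }
  place_at <- function(type, center) {
    mol <- tmpl[[type]] %*% t(.random_rotation())
    sweep(mol, 2, center - colMeans(mol), "+")
  }
  shell_sites <- list()
  for (sh in shells) {
    stopifnot(sh$type %in% c("water", "ethanol"), sh$count >= 1,
              sh$dmax > sh$dmin, sh$dmin > 0)
    shell_sites[[length(shell_sites) + 1L]] <-
      list(atoms = sh$site_atoms, dmax = sh$dmax)
    for (m in seq_len(sh$count)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        s <- sample(sh$site_atoms, 1)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        d <- stats::runif(1, sh$dmin + 0.5, sh$dmax - 0.5)
        center <- frame$xyz[s, ] + d * dir
        mol <- place_at(sh$type, center)
        if (min_ok(mol)) { add_mol(sh$type, mol); ok <- TRUE; break }
      }
      if (!ok) stop("failed to place shell ", sh$type, " after ",
                    max_tries, " tries")
    }
    if (counts[sh$type] > wanted[sh$type]) {
      stop("shell placements exceed requested n_", sh$type)
    }
  }
  for (type in c("water", "ethanol")) {
    while (counts[type] < wanted[type]) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        center <- stats::runif(3) * box
        clear <- TRUE
        for (ss in shell_sites) {
          d2 <- .min_image_dist2(frame$xyz[ss$atoms, , drop = FALSE],
                                 center, box)
          if (any(d2 < (ss$dmax + 2.5)^2)) { clear <- FALSE; break }
        }
        if (!clear) next
        mol <- place_at(type, center)
        if (min_ok(mol)) { add_mol(type, mol); ok <- TRUE; break }
      }
      if (!ok) stop("failed to place bulk ", type, " after ", max_tries,
                    " tries (box too crowded?)")
    }
  }
  if (length(new_atoms) == 0) return(traj)
  sxyz <- do.call(rbind, lapply(new_atoms, `[[`, "xyz"))
  stopo <- topology(
    atom_name = unlist(lapply(new_atoms, `[[`, "name")),
    element = unlist(lapply(new_atoms, `[[`, "element")),
    resid = unlist(lapply(new_atoms, function(a) rep(a$resid, 3))),
    resname = unlist(lapply(new_atoms, function(a) rep(a$resname, 3))),
    mol_class = unlist(lapply(new_atoms, function(a) rep(a$class, 3))))
  all_topo <- topology(
    atom_name = c(topo$atom_name, stopo$atom_name),
    element = c(topo$element, stopo$element),
    resid = c(topo$resid, stopo$resid),
    resname = c(topo$resname, stopo$resname),
    mol_class = c(topo$mol_class, stopo$mol_class),
    radius = c(topo$radius, stopo$radius),
    polarity = c(topo$polarity, stopo$polarity))
  md_trajectory(all_topo,
                list(md_frame(rbind(frame$xyz, sxyz), box, frame$time)))
}

#' Generate a noisy Michaelis-Menten dataset
#'
#' `v = Vmax * S / (Km + S) * (1 + eps)`, `eps ~ N(0, noise_cv^2)`, seeded.
#'
#' @param Km Michaelis constant, mM.
#' @param Vmax maximal rate.
#' @param levels substrate levels (mM), within (0, 300].
#' @param noise_cv multiplicative noise coefficient of variation.
#' @param seed integer seed.
#' @return data.frame with columns `substrate_mM`, `rate`.
#' @export
generate_kinetics_dataset <- function(Km, Vmax,
                                      levels = c(5, 10, 20, 40, 80, 120,
                                                 200, 300),
                                      noise_cv = 0, seed = 1) {
  stopifnot(Km > 0, Vmax > 0, all(levels > 0), all(levels <= 300))
  v <- Vmax * levels / (Km + levels)
  if (noise_cv > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    v <- v * (1 + stats::rnorm(length(levels), 0, noise_cv))
    v <- pmax(v, 0)
  }
  data.frame(substrate_mM = levels, rate = v)
}

#' Synthetic dual-predictor score table with a prescribed stabilizing set
#'
#' Assigns seeded score magnitudes to every candidate but fixes the signs
#' so that exactly the named mutants satisfy the consensus criterion
#' (ddg_a < 0 and ddg_b > 0). Used to test set-membership logic of the
#' consensus filter against a known outcome.
#'
#' @param candidates data.frame from [enumerate_saturation()].
#' @param stabilizing_labels character vector of labels ("H68A" style) that
#'   must be the exact stabilizing subset.
#' @param seed integer seed for the magnitudes.
#' @return data.frame with columns `position`, `wt`, `mut`, `ddg_a`,
#'   `ddg_b`.
#' @export
ddg_fixture_table <- function(candidates, stabilizing_labels, seed = 1) {
  labels <- paste0(candidates$wt, candidates$position, candidates$mut)
  missing <- setdiff(stabilizing_labels, labels)
  if (length(missing) > 0) {
    stop("stabilizing labels not among candidates: ",
         paste(missing, collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- nrow(candidates)
  mag_a <- stats::runif(n, 0.2, 2.5)
  mag_b <- stats::runif(n, 0.2, 2.5)
  fail_mode <- sample(1:3, n, replace = TRUE) # (+,+), (-,-), (+,-)
  stab <- labels %in% stabilizing_labels
  ddg_a <- ifelse(stab, -mag_a,
                  ifelse(fail_mode == 2, -mag_a, mag_a))
  ddg_b <- ifelse(stab, mag_b,
                  ifelse(fail_mode == 1, mag_b, -mag_b))
  data.frame(position = candidates$position, wt = candidates$wt,
             mut = candidates$mut, ddg_a = ddg_a, ddg_b = ddg_b,
             stringsAsFactors = FALSE)
}
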