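# minimum-image displacement of each row of `a` from point `b` (orthorhombic)
.min_image_dist2 <- function(a, b, box) {
  d <- sweep(a, 2, b)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  rowSums(d^2)
}

#' Count solvent molecules near a site
#'
#' A water or ethanol molecule is counted once if any of its atoms lies
#' within `cutoff` of any site atom, using minimum-image periodic distances.
#' Counts are of whole molecules (grouped by residue index within molecule
#' class), never of atoms.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param site_atoms integer vector of atom ids defining the site.
#' @param cutoff distance cutoff in Angstrom (> 0); default 5.
#' @return A list of class `"solvation_count"` with `n_water`, `n_ethanol`,
#'   `cutoff`, `site_atoms`.
#' @export
count_solvent_near <- function(frame, topology, site_atoms, cutoff = 5) {
  stopifnot(cutoff > 0, length(site_atoms) >= 1)
  solv <- topology$mol_class %in% c("water", "ethanol")
  n_w <- 0L
  n_e <- 0L
  if (any(solv)) {
    molid <- paste(topology$mol_class, topology$resid)
    hit <- rep(FALSE, nrow(topology))
    xyz <- frame$xyz
    c2 <- cutoff^2
    solv_idx <- which(solv)
    for (s in site_atoms) {
      d2 <- .min_image_dist2(xyz[solv_idx, , drop = FALSE], xyz[s, ], frame$box)
      hit[solv_idx[d2 <= c2]] <- TRUE
    }
    mols <- unique(molid[hit])
    cls <- vapply(strsplit(mols, " "), `[[`, character(1), 1)
    # a molecule's atoms must share one class
    for (m in mols) {
      atoms <- which(molid == m)
      if (length(unique(topology$mol_class[atoms])) != 1) {
        stop("solvent molecule split across molecule classes: ", m)
      }
    }
    n_w <- sum(cls == "water")
    n_e <- sum(cls == "ethanol")
  }
  structure(list(n_water = as.integer(n_w), n_ethanol = as.integer(n_e),
                 cutoff = cutoff, site_atoms = site_atoms),
            class = "solvation_count")
}

#' Sweep the solvent-count cutoff
#'
#' @inheritParams count_solvent_near
#' @param cutoffs vector of cutoffs (Angstrom), default 3..8.
#' @return data.frame with columns `cutoff`, `n_water`, `n_ethanol`.
#' @export
solvent_count_sweep <- function(frame, topology, site_atoms,
                                cutoffs = seq(3, 8, by = 1)) {
  rows <- lapply(cutoffs, function(cc) {
    sc <- count_solvent_near(frame, topology, site_atoms, cc)
    data.frame(cutoff = cc, n_water = sc$n_water, n_ethanol = sc$n_ethanol)
  })
  do.call(rbind, rows)
}

# n roughly evenly distributed points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, test points on the sphere of radius `r_vdw + probe` are
#' kept if they fall outside every neighbour's expanded sphere; the exposed
#' fraction times the sphere area is the atom's SASA. Totals are split into
#' hydrophilic (polar atoms: N, O, S and their hydrogens) and hydrophobic
#' (apolar: C and its hydrogens) by the topology's polarity field.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param subset integer atom ids to include (default: all protein atoms).
#'   Occlusion is computed within the subset.
#' @param probe_radius probe radius in Angstrom (water: 1.4).
#' @param n_sphere_points test points per atom (default 960).
#' @return A list of class `"surface_area"` with `total`, `hydrophilic`,
#'   `hydrophobic` (Angstrom^2), `per_atom`, `probe_radius`.
#' @export
sasa <- function(frame, topology, subset = NULL, probe_radius = 1.4,
                 n_sphere_points = 960) {
  if (is.null(subset)) subset <- select_atoms(topology, "protein")
  if (length(subset) == 0) stop("empty atom subset")
  r <- topology$radius[subset]
  if (anyNA(r)) stop("missing vdW radius in subset")
  xyz <- frame$xyz[subset, , drop = FALSE]
  rr <- r + probe_radius
  sp <- .sphere_points(n_sphere_points)
  n <- length(subset)
  per_atom <- numeric(n)
  # neighbour lists from pairwise distances
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cut <- (rr[i] + rr)^2
    nb <- which(d2[i, ] < cut)
    nb <- nb[nb != i]
    pts <- sweep(sp * rr[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj <- sweep(pts[exposed, , drop = FALSE], 2, xyz[j, ])
      exposed[exposed] <- rowSums(dj^2) >= rr[j]^2
    }
    per_atom[i] <- 4 * pi * rr[i]^2 * sum(exposed) / n_sphere_points
  }
  polar <- topology$polarity[subset] == "polar"
  structure(list(total = sum(per_atom),
                 hydrophilic = sum(per_atom[polar]),
                 hydrophobic = sum(per_atom[!polar]),
                 per_atom = stats::setNames(per_atom, subset),
                 probe_radius = probe_radius), class = "surface_area")
}

#' @export
print.surface_area <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 (hydrophilic %.1f, hydrophobic %.1f; probe %.2f A)\n",
              x$total, x$hydrophilic, x$hydrophobic, x$probe_radius))
  invisible(x)
}

#' Geometric hydrogen-bond detection
#'
#' A bond donor-H...acceptor is reported when the donor-acceptor distance is
#' at most `max_da_distance` and the D-H...A angle deviates from linearity
#' (180 degrees) by at most `max_dha_angle`. Donor hydrogens are located as
#' H atoms of the same residue within 1.25 Angstrom of the donor heavy atom;
#' donors without such a hydrogen are skipped with a warning.
#'
#' @param frame an [md_frame()].
#' @param topology the matching [topology()].
#' @param donors integer atom ids of donor heavy atoms (N/O/S).
#' @param acceptors integer atom ids of acceptor heavy atoms.
#' @param max_da_distance donor-acceptor cutoff, Angstrom (default 3.5).
#' @param max_dha_angle maximum deviation from linearity, degrees
#'   (default 30).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle_deviation`.
#' @export
detect_hbonds <- function(frame, topology, donors, acceptors,
                          max_da_distance = 3.5, max_dha_angle = 30) {
  xyz <- frame$xyz
  is_h <- toupper(topology$element) == "H"
  out <- list()
  for (d in donors) {
    hs <- which(is_h & topology$resid == topology$resid[d] &
                topology$mol_class == topology$mol_class[d])
    if (length(hs) > 0) {
      dh <- sqrt(.min_image_dist2(xyz[hs, , drop = FALSE], xyz[d, ], frame$box))
      hs <- hs[dh <= 1.25]
    }
    if (length(hs) == 0) {
      warning("donor atom ", d, " has no attached hydrogen; skipped")
      next
    }
    for (a in acceptors) {
      if (a == d) next
      da <- sqrt(sum((xyz[a, ] - xyz[d, ])^2))
      if (da > max_da_distance) next
      for (h in hs) {
        v1 <- xyz[d, ] - xyz[h, ]
        v2 <- xyz[a, ] - xyz[h, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        dev <- 180 - ang
        if (dev <= max_dha_angle) {
          out[[length(out) + 1]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a,
            distance = da, angle_deviation = dev)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle_deviation = numeric(0)))
  }
  do.call(rbind, out)
}
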