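#' Select atom indices by a simple predicate
#'
#' @param topology a [topology()] object.
#' @param selection `"ca"` (protein C-alpha atoms), `"heavy"` (protein
#'   non-hydrogen), `"protein"` (all protein atoms), `"all"`, or an integer
#'   vector of atom ids taken as-is.
#' @return Integer vector of atom ids.
#' @export
select_atoms <- function(topology, selection = "ca") {
  if (is.numeric(selection)) {
    sel <- as.integer(selection)
    if (any(sel < 1 | sel > nrow(topology))) stop("atom id out of range")
    return(sel)
  }
  switch(selection,
         ca = topology$atom_id[topology$mol_class == "protein" &
                               topology$atom_name == "CA"],
         heavy = topology$atom_id[topology$mol_class == "protein" &
                                  toupper(topology$element) != "H"],
         protein = topology$atom_id[topology$mol_class == "protein"],
         all = topology$atom_id,
         stop("unknown selection: ", selection))
}

#' Superpose trajectory frames onto a reference
#'
#' Least-squares rigid-body fit (Kabsch, via [bio3d::fit.xyz()]) of every
#' frame onto the reference frame over the selected atoms. Rotations are
#' proper: handedness is preserved.
#'
#' @param traj an [md_trajectory()] object.
#' @param reference index of the reference frame (default 1, the first).
#' @param selection passed to [select_atoms()]; default C-alpha atoms.
#' @return A new `md_trajectory` with all atoms moved by each frame's fitted
#'   rigid transform, plus attributes `reference` and `selection`.
#' @export
superpose <- function(traj, reference = 1, selection = "ca") {
  sel <- select_atoms(traj$topology, selection)
  if (length(sel) < 3) stop("need at least 3 selected atoms to superpose")
  ref_xyz <- traj$frames[[reference]]$xyz[sel, , drop = FALSE]
  if (qr(sweep(ref_xyz, 2, colMeans(ref_xyz)))$rank < 2) {
    stop("selected reference atoms are collinear: rotation undefined")
  }
  xyz_inds <- as.vector(t(cbind(3 * sel - 2, 3 * sel - 1, 3 * sel)))
  fixed <- as.vector(t(traj$frames[[reference]]$xyz))
  mobile <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f$xyz))))
  fitted <- bio3d::fit.xyz(fixed = fixed, mobile = mobile,
                           fixed.inds = xyz_inds, mobile.inds = xyz_inds)
  frames <- lapply(seq_along(traj$frames), function(k) {
    md_frame(matrix(fitted[k, ], ncol = 3, byrow = TRUE),
             traj$frames[[k]]$box, traj$frames[[k]]$time)
  })
  out <- md_trajectory(traj$topology, frames)
  attr(out, "reference") <- reference
  attr(out, "selection") <- selection
  out
}

#' Per-frame RMSD to a reference frame
#'
#' Root-mean-square deviation over the selected atoms, after optional
#' superposition.
#'
#' @inheritParams superpose
#' @param fit superpose before measuring (default TRUE).
#' @return data.frame with columns `frame`, `time`, `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1, selection = "ca", fit = TRUE) {
  if (fit) traj <- superpose(traj, reference, selection)
  sel <- select_atoms(traj$topology, selection)
  ref <- traj$frames[[reference]]$xyz[sel, , drop = FALSE]
  rmsd <- vapply(traj$frames, function(f) {
    d <- f$xyz[sel, , drop = FALSE] - ref
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  data.frame(frame = seq_along(traj$frames),
             time = vapply(traj$frames, `[[`, numeric(1), "time"),
             rmsd = rmsd)
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation of each residue about its time-mean position,
#' computed on already-superposed frames. The mean over frames is the
#' population mean (divide by the number of frames). Residues without
#' selected atoms are absent from the output, not zero.
#'
#' @param traj a superposed [md_trajectory()] (see [superpose()]).
#' @param selection passed to [select_atoms()].
#' @param representative `"CA-only"` reports the C-alpha fluctuation;
#'   `"all-atom-mean"` averages the per-atom RMSF over the residue's selected
#'   atoms.
#' @return data.frame with columns `resid`, `rmsf` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = "ca",
                         representative = c("CA-only", "all-atom-mean")) {
  representative <- match.arg(representative)
  if (length(traj$frames) < 2) stop("need at least 2 frames for RMSF")
  sel <- select_atoms(traj$topology, selection)
  if (representative == "CA-only") {
    ca <- select_atoms(traj$topology, "ca")
    sel <- intersect(sel, ca)
    if (length(sel) == 0) stop("no C-alpha atoms in selection")
  }
  nf <- length(traj$frames)
  coords <- array(0, dim = c(nf, length(sel), 3))
  for (k in seq_len(nf)) coords[k, , ] <- traj$frames[[k]]$xyz[sel, , drop = FALSE]
  mean_pos <- apply(coords, c(2, 3), mean)
  dev2 <- matrix(0, nf, length(sel))
  for (k in seq_len(nf)) {
    d <- coords[k, , , drop = FALSE][1, , ] - mean_pos
    dev2[k, ] <- rowSums(matrix(d, ncol = 3)^2)
  }
  atom_rmsf <- sqrt(colMeans(dev2))
  res <- traj$topology$resid[sel]
  agg <- tapply(atom_rmsf, res, mean)
  data.frame(resid = as.integer(names(agg)), rmsf = as.numeric(agg),
             row.names = NULL)
}
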