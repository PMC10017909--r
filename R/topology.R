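#' Default van der Waals radii by element
#'
#' Bondi-style radii used when a topology is built without an explicit
#' radius table. Values in Angstrom.
#'
#' @return Named numeric vector of radii (Angstrom).
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, NA. = 2.27, P = 1.80)
}

.radius_for_element <- function(element, radii = default_vdw_radii()) {
  key <- ifelse(toupper(element) == "NA", "NA.", toupper(element))
  r <- unname(radii[key])
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  r
}

#' Construct an annotated topology
#'
#' A topology is the static description of the simulated system: one row per
#' atom carrying its name, element, 1-based residue index and name, molecule
#' class (protein, water, ethanol or ion), van der Waals radius and polarity
#' class. Hydrogens inherit the polarity of the preceding heavy atom of the
#' same residue, so amide H count as polar and aliphatic H as apolar.
#'
#' @param atom_name character vector of atom names (e.g. "CA", "N", "OW").
#' @param element character vector of element symbols.
#' @param resid integer vector of 1-based residue indices, non-decreasing
#'   within a molecule class.
#' @param resname character vector of residue names (3-letter codes for
#'   protein, "SOL"/"ETH"/"ION" style for solvent).
#' @param mol_class character vector, each one of "protein", "water",
#'   "ethanol", "ion".
#' @param radius optional numeric vector of vdW radii (Angstrom); derived
#'   from `element` via `radii` when NULL.
#' @param polarity optional character vector ("polar"/"apolar"); derived from
#'   element (N, O, S polar; C apolar; H inherits) when NULL.
#' @param radii named radius table used when `radius` is NULL.
#'
#' @return A data.frame of class `"topology"` with columns `atom_id`,
#'   `atom_name`, `element`, `resid`, `resname`, `mol_class`, `radius`,
#'   `polarity`.
#' @export
topology <- function(atom_name, element, resid, resname, mol_class,
                     radius = NULL, polarity = NULL,
                     radii = default_vdw_radii()) {
  n <- length(atom_name)
  stopifnot(length(element) == n, length(resid) == n,
            length(resname) == n, length(mol_class) == n)
  classes <- c("protein", "water", "ethanol", "ion")
  if (!all(mol_class %in% classes)) {
    stop("mol_class must be one of: ", paste(classes, collapse = ", "))
  }
  for (cl in unique(mol_class)) {
    r <- resid[mol_class == cl]
    if (is.unsorted(r)) stop("resid must be non-decreasing within molecule class '", cl, "'")
  }
  if (is.null(radius)) radius <- .radius_for_element(element, radii)
  if (any(radius <= 0)) stop("all vdW radii must be positive")
  if (is.null(polarity)) {
    polarity <- ifelse(toupper(element) %in% c("N", "O", "S"), "polar", "apolar")
    # hydrogens take the class of the last heavy atom seen in the same residue
    is_h <- toupper(element) == "H"
    if (any(is_h)) {
      last_heavy <- "apolar"
      last_res <- NA
      for (i in seq_len(n)) {
        if (!is_h[i]) {
          last_heavy <- polarity[i]
          last_res <- resid[i]
        } else if (identical(resid[i], last_res)) {
          polarity[i] <- last_heavy
        }
      }
    }
  }
  if (!all(polarity %in% c("polar", "apolar"))) stop("polarity must be 'polar' or 'apolar'")
  out <- data.frame(
    atom_id = seq_len(n), atom_name = as.character(atom_name),
    element = as.character(element), resid = as.integer(resid),
    resname = as.character(resname), mol_class = as.character(mol_class),
    radius = as.numeric(radius), polarity = as.character(polarity),
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology", "data.frame")
  out
}

#' Construct a coordinate frame
#'
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @param box numeric length-3 vector of orthorhombic box edges (Angstrom).
#' @param time frame time in ns.
#'
#' @return A list of class `"md_frame"` with elements `xyz`, `box`, `time`.
#' @export
md_frame <- function(xyz, box, time = 0) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be 3 positive orthorhombic edge lengths (Angstrom)")
  }
  structure(list(xyz = unname(xyz), box = box, time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory (topology + ordered frames)
#'
#' @param topology a [topology()] object.
#' @param frames list of [md_frame()] objects, each with as many rows as the
#'   topology has atoms.
#' @return A list of class `"md_trajectory"`.
#' @export
md_trajectory <- function(topology, frames) {
  stopifnot(inherits(topology, "topology"), length(frames) >= 1)
  n <- nrow(topology)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (!inherits(f, "md_frame")) stop("frames[[", k, "]] is not an md_frame")
    if (nrow(f$xyz) != n) {
      stop("frame ", k, " has ", nrow(f$xyz), " atoms; topology has ", n)
    }
  }
  structure(list(topology = topology, frames = frames), class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d frames, %d atoms (%d protein residues)\n",
              length(x$frames), nrow(x$topology),
              length(unique(x$topology$resid[x$topology$mol_class == "protein"]))))
  invisible(x)
}

#' Construct a simulation condition
#'
#' One point of the pressure x ethanol-fraction grid at a fixed temperature.
#'
#' @param pressure pressure in bar (> 0).
#' @param ethanol_fraction ethanol volume fraction in `[0, 1]`.
#' @param temperature absolute temperature in K (> 0).
#' @return A list of class `"sim_condition"`.
#' @export
condition <- function(pressure, ethanol_fraction = 0, temperature = 313) {
  stopifnot(pressure > 0, temperature > 0,
            ethanol_fraction >= 0, ethanol_fraction <= 1)
  structure(list(pressure = pressure, ethanol_fraction = ethanol_fraction,
                 temperature = temperature), class = "sim_condition")
}

#' @export
format.sim_condition <- function(x, ...) {
  sprintf("%gbar_%g%%EtOH_%gK", x$pressure, 100 * x$ethanol_fraction, x$temperature)
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' One-letter protein sequence from a topology
#'
#' @param topology a [topology()] object.
#' @return Character vector of 1-letter codes, one per protein residue, in
#'   residue-index order.
#' @export
topology_sequence <- function(topology) {
  prot <- topology[topology$mol_class == "protein", ]
  if (nrow(prot) == 0) return(character(0))
  res <- prot[!duplicated(prot$resid), ]
  aa3to1(res$resname)
}

#' Convert between 3-letter and 1-letter amino-acid codes
#'
#' @param x character vector of codes.
#' @return Converted character vector; unknown codes raise an error.
#' @export
aa3to1 <- function(x) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V")
  out <- unname(map[toupper(x)])
  if (anyNA(out)) stop("unknown residue name(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}

#' @rdname aa3to1
#' @export
aa1to3 <- function(x) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- unname(map[toupper(x)])
  if (anyNA(out)) stop("unknown amino acid(s): ",
                       paste(unique(x[is.na(out)]), collapse = ", "))
  out
}
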