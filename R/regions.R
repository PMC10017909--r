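#' Construct a secondary-structure region partition
#'
#' Named contiguous residue segments labelled helix / sheet / loop. Segment
#' names follow the `class_start-end` convention (e.g. `loop_67-76` for
#' residues 67..76 inclusive, 10 residues).
#'
#' @param segments data.frame with columns `class` ("helix"/"sheet"/"loop"),
#'   `start`, `end` (1-based, inclusive); a `name` column is generated when
#'   absent.
#' @return data.frame of class `"region_partition"`, sorted by `start`.
#' @export
region_partition <- function(segments) {
  seg <- as.data.frame(segments, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "start", "end") %in% names(seg)))
  if (!all(seg$class %in% c("helix", "sheet", "loop"))) {
    stop("segment class must be helix, sheet or loop")
  }
  seg$start <- as.integer(seg$start)
  seg$end <- as.integer(seg$end)
  if (any(seg$end < seg$start)) stop("segment end before start")
  seg <- seg[order(seg$start), , drop = FALSE]
  if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
    stop("segments overlap")
  }
  if (is.null(seg$name)) {
    seg$name <- sprintf("%s_%d-%d", seg$class, seg$start, seg$end)
  }
  if (anyDuplicated(seg$name)) stop("segment names must be unique")
  seg <- seg[, c("name", "class", "start", "end")]
  rownames(seg) <- NULL
  class(seg) <- c("region_partition", "data.frame")
  seg
}

# Dihedral angle (degrees) of points p1-p2-p3-p4 (each a length-3 vector)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedrals
#'
#' @param topology a [topology()] object with backbone N, CA, C atoms for
#'   every protein residue.
#' @param frame an [md_frame()].
#' @return data.frame with columns `resid`, `phi`, `psi` (degrees; NA at
#'   chain termini).
#' @export
backbone_dihedrals <- function(topology, frame) {
  prot <- topology[topology$mol_class == "protein", ]
  resids <- sort(unique(prot$resid))
  idx <- function(r, name) {
    i <- prot$atom_id[prot$resid == r & prot$atom_name == name]
    if (length(i) != 1) NA_integer_ else i
  }
  N <- vapply(resids, idx, integer(1), name = "N")
  CA <- vapply(resids, idx, integer(1), name = "CA")
  C <- vapply(resids, idx, integer(1), name = "C")
  miss <- resids[is.na(N) | is.na(CA) | is.na(C)]
  if (length(miss) > 0) {
    stop("missing backbone N/CA/C atoms for residue(s): ",
         paste(miss, collapse = ", "))
  }
  xyz <- frame$xyz
  n <- length(resids)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- .dihedral(xyz[C[i - 1], ], xyz[N[i], ], xyz[CA[i], ], xyz[C[i], ])
    }
    if (i < n) {
      psi[i] <- .dihedral(xyz[N[i], ], xyz[CA[i], ], xyz[C[i], ], xyz[N[i + 1], ])
    }
  }
  data.frame(resid = resids, phi = phi, psi = psi)
}

.class_from_phipsi <- function(phi, psi) {
  if (is.na(phi) || is.na(psi)) return(NA_character_)
  if (phi >= -90 && phi <= -30 && psi >= -77 && psi <= -17) return("helix")
  if (phi >= -170 && phi <= -90 && ((psi >= 90 && psi <= 180) || psi <= -170)) {
    return("sheet")
  }
  "loop"
}

#' Assign secondary structure and build a region partition
#'
#' Either maps an external one-letter-per-residue assignment file
#' (`H`/`E`/`C`, DSSP-reduced alphabet) or applies a phi/psi dihedral-window
#' heuristic (P-SEA style) to the backbone geometry. Contiguous runs of equal
#' class are merged into segments; helix runs shorter than `min_helix` and
#' sheet runs shorter than `min_sheet` are reclassified as loop. Chain-end
#' residues with an undefined phi or psi inherit their neighbour's class.
#'
#' @param topology a [topology()] object.
#' @param frame an [md_frame()] (heuristic mode).
#' @param method `"external-file"` or `"dihedral-heuristic"`.
#' @param ss_file path to a text file with lines `residue<TAB>letter`
#'   (external mode).
#' @param min_helix,min_sheet minimum run lengths (residues) for a helix /
#'   sheet segment.
#' @return A [region_partition()] covering every protein residue.
#' @export
assign_secondary_structure <- function(topology, frame = NULL,
                                       method = c("dihedral-heuristic",
                                                  "external-file"),
                                       ss_file = NULL,
                                       min_helix = 4, min_sheet = 3) {
  method <- match.arg(method)
  if (method == "external-file") {
    if (is.null(ss_file)) stop("external-file mode needs `ss_file`")
    tab <- utils::read.delim(ss_file, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    resids <- as.integer(tab[[1]])
    letter <- toupper(trimws(tab[[2]]))
    if (!all(letter %in% c("H", "E", "C"))) stop("class letters must be H, E or C")
    cls <- c(H = "helix", E = "sheet", C = "loop")[letter]
    ord <- order(resids)
    resids <- resids[ord]; cls <- cls[ord]
  } else {
    if (is.null(frame)) stop("dihedral-heuristic mode needs a frame")
    dh <- backbone_dihedrals(topology, frame)
    resids <- dh$resid
    cls <- mapply(.class_from_phipsi, dh$phi, dh$psi)
    # termini: inherit neighbour class
    for (i in seq_along(cls)) {
      if (is.na(cls[i])) {
        cls[i] <- if (i == 1) cls[2] else cls[i - 1]
      }
    }
  }
  # merge runs, then demote short helix/sheet runs to loop
  r <- rle(cls)
  short <- (r$values == "helix" & r$lengths < min_helix) |
           (r$values == "sheet" & r$lengths < min_sheet)
  r$values[short] <- "loop"
  cls <- inverse.rle(r)
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  region_partition(data.frame(class = r$values,
                              start = resids[starts], end = resids[ends],
                              stringsAsFactors = FALSE))
}

#' Atoms belonging to a named region
#'
#' @param partition a [region_partition()].
#' @param topology a [topology()] object.
#' @param region_name segment name, e.g. `"loop_67-76"`.
#' @param scope `"heavy-atom"` (default) or `"all-atom"`.
#' @return Integer vector of atom ids.
#' @export
region_atoms <- function(partition, topology, region_name,
                         scope = c("heavy-atom", "all-atom")) {
  scope <- match.arg(scope)
  row <- partition[partition$name == region_name, ]
  if (nrow(row) != 1) stop("unknown region name: ", region_name)
  sel <- topology$mol_class == "protein" &
    topology$resid >= row$start & topology$resid <= row$end
  if (scope == "heavy-atom") sel <- sel & toupper(topology$element) != "H"
  ids <- topology$atom_id[sel]
  if (length(ids) == 0) {
    stop("region ", region_name, " matches no atoms (residues out of range?)")
  }
  ids
}
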