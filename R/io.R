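#' Read a coordinate trajectory
#'
#' Reads a multi-model PDB or a concatenated GRO series into a topology plus
#' ordered frames. Coordinates are stored internally in Angstrom; GRO input
#' (nm) is converted on read. Only orthorhombic boxes are supported.
#'
#' @param path path to the trajectory file.
#' @param format `"pdb-multimodel"` or `"gro-series"`.
#' @param box optional length-3 box (Angstrom) used when the file carries no
#'   box record (PDB without CRYST1).
#' @param radii named vdW radius table passed to [topology()].
#'
#' @return An [md_trajectory()] object. Frame times are taken from the file
#'   when present (GRO `t=` tags), else 0, 1, 2, ... ns.
#' @export
read_trajectory <- function(path, format = c("pdb-multimodel", "gro-series"),
                            box = NULL, radii = default_vdw_radii()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "pdb-multimodel" = .read_pdb_multimodel(path, box, radii),
         "gro-series" = .read_gro_series(path, radii))
}

.mol_class_from_resname <- function(resname) {
  up <- toupper(resname)
  ifelse(up %in% c("SOL", "HOH", "WAT", "TIP3", "SPC"), "water",
  ifelse(up %in% c("ETH", "EOH", "ETL", "ETOH"), "ethanol",
  ifelse(up %in% c("NA", "NA+", "CL", "CL-", "ION", "SOD", "CLA", "K", "K+"), "ion",
         "protein")))
}

.element_from_atom <- function(atom_name, resname) {
  nm <- gsub("[0-9'\"]", "", toupper(atom_name))
  cls <- .mol_class_from_resname(resname)
  el <- substr(nm, 1, 1)
  el[cls == "ion" & nm %in% c("NA", "SOD")] <- "NA"
  known <- c("C", "N", "O", "S", "H", "P", "NA")
  if (!all(el %in% known)) {
    bad <- which(!(el %in% known))[1]
    stop("unknown element for atom '", atom_name[bad], "' (residue ",
         resname[bad], ")")
  }
  el
}

.parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  f <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33), substr(cl[1], 34, 40),
                    substr(cl[1], 41, 47), substr(cl[1], 48, 54)))
  if (any(abs(f[4:6] - 90) > 1e-3)) {
    stop("triclinic box in CRYST1 record: only orthorhombic boxes are supported")
  }
  f[1:3]
}

.read_pdb_multimodel <- function(path, box, radii) {
  lines <- readLines(path)
  fbox <- .parse_cryst1(lines)
  if (is.null(fbox)) fbox <- box
  if (is.null(fbox)) stop("no CRYST1 record in ", path, " and no `box` given")
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(trimws(elem) == "")) {
    elem <- .element_from_atom(at$elety, at$resid)
  } else {
    elem <- trimws(elem)
    miss <- is.na(elem) | elem == ""
    if (any(miss)) elem[miss] <- .element_from_atom(at$elety[miss], at$resid[miss])
    elem <- toupper(elem)
  }
  topo <- topology(atom_name = at$elety, element = elem, resid = at$resno,
                   resname = at$resid,
                   mol_class = .mol_class_from_resname(at$resid),
                   radii = radii)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topo)) {
    stop("atom-count mismatch between models in ", path)
  }
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    md_frame(matrix(xyz[k, ], ncol = 3, byrow = TRUE), fbox, time = k - 1)
  })
  md_trajectory(topo, frames)
}

#' Write a trajectory
#'
#' @param traj an [md_trajectory()] object.
#' @param path output file path.
#' @param format `"pdb-multimodel"` or `"gro-series"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("pdb-multimodel", "gro-series")) {
  format <- match.arg(format)
  if (format == "pdb-multimodel") .write_pdb_multimodel(traj, path)
  else .write_gro_series(traj, path)
  invisible(path)
}

.write_pdb_multimodel <- function(traj, path) {
  topo <- traj$topology
  xyz <- do.call(rbind, lapply(traj$frames, function(f) as.vector(t(f$xyz))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = topo$resid,
                   resid = topo$resname, elety = topo$atom_name,
                   chain = rep("A", nrow(topo)))
  box <- traj$frames[[1]]$box
  cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                   box[1], box[2], box[3], 90, 90, 90)
  lines <- readLines(path)
  writeLines(c(cryst, lines), path)
}

# GRO fixed-width format; coordinates and box in nm (converted to/from
# Angstrom here). A series is frames concatenated in one file.
.read_gro_series <- function(path, radii) {
  lines <- readLines(path)
  frames <- list()
  topo <- NULL
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO atom-count line at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines)) stop("truncated GRO frame at line ", i)
    rec <- lines[(i + 2L):(i + 1L + nat)]
    resno <- as.integer(substr(rec, 1, 5))
    resnm <- trimws(substr(rec, 6, 10))
    atnm <- trimws(substr(rec, 11, 15))
    x <- as.numeric(substr(rec, 21, 28)) * 10
    y <- as.numeric(substr(rec, 29, 36)) * 10
    z <- as.numeric(substr(rec, 37, 44)) * 10
    boxline <- strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]]
    boxv <- as.numeric(boxline)
    if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9)) {
      stop("triclinic GRO box: only orthorhombic boxes are supported")
    }
    box <- boxv[1:3] * 10
    tm <- k
    tmatch <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    if (length(tmatch) == 1) tm <- as.numeric(sub("t=\\s*", "", tmatch))
    if (is.null(topo)) {
      elem <- .element_from_atom(atnm, resnm)
      topo <- topology(atom_name = atnm, element = elem, resid = resno,
                       resname = resnm,
                       mol_class = .mol_class_from_resname(resnm),
                       radii = radii)
    } else if (nat != nrow(topo)) {
      stop("atom-count mismatch between GRO frames: ", nat, " vs ", nrow(topo))
    }
    frames[[length(frames) + 1L]] <- md_frame(cbind(x, y, z), box, time = tm)
    i <- i + 2L + nat + 1L
    k <- k + 1L
  }
  if (is.null(topo)) stop("no frames found in ", path)
  md_trajectory(topo, frames)
}

.write_gro_series <- function(traj, path) {
  topo <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(sprintf("generated frame t= %.4f", f$time), con)
    writeLines(sprintf("%5d", nrow(topo)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       topo$resid %% 100000, substr(topo$resname, 1, 5),
                       substr(topo$atom_name, 1, 5),
                       topo$atom_id %% 100000,
                       f$xyz[, 1] / 10, f$xyz[, 2] / 10, f$xyz[, 3] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       f$box[1] / 10, f$box[2] / 10, f$box[3] / 10), con)
  }
}

#' Read a dual-predictor folding free-energy table
#'
#' Consumes tab-separated exports of external stability predictors. The two
#' score columns follow opposite sign conventions: column A (FoldX-style)
#' counts negative values as stabilizing, column B (I-Mutant-style) counts
#' positive values as stabilizing. Missing scores stay `NA` (absent, not
#' zero).
#'
#' @param path TSV file with header columns `position`, `wt`, `mut`,
#'   `ddg_foldx_kcal_mol`, `ddg_imutant_kcal_mol`.
#' @param sequence optional 1-letter wild-type sequence; when given, the
#'   table's `wt` letters are checked against it.
#'
#' @return A data.frame with columns `position`, `wt`, `mut`, `ddg_a`,
#'   `ddg_b`, one row per (position, mut).
#' @export
read_ddg_table <- function(path, sequence = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  need <- c("position", "wt", "mut", "ddg_foldx_kcal_mol", "ddg_imutant_kcal_mol")
  if (!all(need %in% names(df))) {
    stop("ddG table must have columns: ", paste(need, collapse = ", "))
  }
  key <- paste(df$position, df$mut)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate rows for (position, mut) = (", d, ")")
  }
  if (!is.null(sequence)) {
    bad <- which(df$wt != sequence[df$position])
    if (length(bad) > 0) {
      stop("wt letter disagrees with sequence at position ",
           df$position[bad[1]], ": table says ", df$wt[bad[1]],
           ", sequence has ", sequence[df$position[bad[1]]])
    }
  }
  data.frame(position = as.integer(df$position), wt = df$wt, mut = df$mut,
             ddg_a = as.numeric(df$ddg_foldx_kcal_mol),
             ddg_b = as.numeric(df$ddg_imutant_kcal_mol),
             stringsAsFactors = FALSE)
}

#' Write a dual-predictor score table
#'
#' @param scores data.frame with columns `position`, `wt`, `mut`, `ddg_a`,
#'   `ddg_b`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ddg_table <- function(scores, path) {
  out <- data.frame(position = scores$position, wt = scores$wt,
                    mut = scores$mut,
                    ddg_foldx_kcal_mol = scores$ddg_a,
                    ddg_imutant_kcal_mol = scores$ddg_b)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
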