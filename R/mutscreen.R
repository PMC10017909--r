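#' Amino-acid property table
#'
#' Per-residue descriptors used by the surrogate stability scorer:
#' Kyte-Doolittle hydropathy, residue volume (Angstrom^3, Zamyatnin) and
#' helix propensity (kcal/mol, Pace-Scholtz scale; alanine = 0).
#'
#' @return data.frame with rownames the 20 one-letter codes and columns
#'   `hydropathy`, `volume`, `helix_propensity`.
#' @export
aa_properties <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  hyd <- c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
           3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2)
  vol <- c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2, 166.7,
           166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8, 193.6, 140.0)
  hel <- c(0.00, 0.21, 0.65, 0.69, 0.68, 0.39, 0.40, 1.00, 0.61, 0.41,
           0.21, 0.26, 0.24, 0.54, 3.16, 0.50, 0.66, 0.49, 0.53, 0.61)
  data.frame(hydropathy = hyd, volume = vol, helix_propensity = hel,
             row.names = aa)
}

#' Enumerate virtual saturation mutants over regions
#'
#' Every position of every region gets all 19 non-identity substitutions
#' among the standard amino acids, in deterministic order (position, then
#' alphabetical mutant letter).
#'
#' @param sequence character vector of 1-letter wild-type codes (1-based
#'   positions).
#' @param regions a [region_partition()] or any data.frame with `start` and
#'   `end` columns (1-based, inclusive).
#' @return data.frame with columns `position`, `wt`, `mut`.
#' @export
enumerate_saturation <- function(sequence, regions) {
  aa <- sort(rownames(aa_properties()))
  positions <- sort(unique(unlist(
    lapply(seq_len(nrow(regions)),
           function(i) seq(regions$start[i], regions$end[i])))))
  if (any(positions < 1 | positions > length(sequence))) {
    stop("region positions outside the sequence (length ", length(sequence), ")")
  }
  wt <- sequence[positions]
  if (!all(wt %in% aa)) {
    stop("non-standard wild-type residue at position(s): ",
         paste(positions[!(wt %in% aa)], collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(positions), function(i) {
    muts <- setdiff(aa, wt[i])
    data.frame(position = positions[i], wt = wt[i], mut = muts,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Surrogate dual stability scores for a mutant
#'
#' A deterministic heuristic stand-in that lets the screening pipeline run
#' end to end without external predictor binaries: scores are weighted
#' differences of hydropathy, residue volume and helix propensity between
#' mutant and wild type, plus seeded Gaussian noise. Slot A follows the
#' FoldX sign convention (negative = stabilizing), slot B the I-Mutant
#' convention (positive = stabilizing). This is NOT a reimplementation of
#' either predictor and carries no physical meaning beyond exercising the
#' filter.
#'
#' @param sequence 1-letter wild-type sequence.
#' @param position 1-based position.
#' @param mut_aa mutant 1-letter code.
#' @param seed integer seed; the same (candidate, seed) always yields the
#'   same scores, independent of call order.
#' @return Named numeric vector `c(ddg_a = ..., ddg_b = ...)` (kcal/mol).
#' @export
surrogate_scorer <- function(sequence, position, mut_aa, seed = 1) {
  props <- aa_properties()
  wt <- sequence[position]
  if (is.na(wt) || !(wt %in% rownames(props))) {
    stop("invalid wild-type residue at position ", position)
  }
  if (!(mut_aa %in% rownames(props))) stop("invalid mutant residue: ", mut_aa)
  if (mut_aa == wt) stop("synonymous substitution ", wt, position, mut_aa)
  dhyd <- (props[mut_aa, "hydropathy"] - props[wt, "hydropathy"]) / 4.5
  dvol <- (props[mut_aa, "volume"] - props[wt, "volume"]) / 100
  dhel <- props[mut_aa, "helix_propensity"] - props[wt, "helix_propensity"]
  sub_seed <- (abs(seed) * 7919 + position * 131 +
               match(mut_aa, rownames(props)) * 17) %% 2147483647
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed)
  noise <- stats::rnorm(2, 0, 0.3)
  base <- 0.5 * dvol - 0.4 * dhyd + 0.6 * dhel
  c(ddg_a = base + noise[1], ddg_b = -base + noise[2])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Attach surrogate scores to enumerated candidates
#'
#' @param candidates data.frame from [enumerate_saturation()].
#' @param sequence 1-letter wild-type sequence.
#' @param seed passed per candidate to [surrogate_scorer()].
#' @return `candidates` with `ddg_a`, `ddg_b` columns.
#' @export
score_candidates <- function(candidates, sequence, seed = 1) {
  sc <- t(mapply(function(p, m) surrogate_scorer(sequence, p, m, seed),
                 candidates$position, candidates$mut))
  candidates$ddg_a <- sc[, "ddg_a"]
  candidates$ddg_b <- sc[, "ddg_b"]
  candidates
}

#' Merge external scores onto candidates
#'
#' @param candidates data.frame from [enumerate_saturation()].
#' @param scores data.frame from [read_ddg_table()].
#' @return `candidates` with `ddg_a`, `ddg_b` (NA where the table has no
#'   row: absent, not zero).
#' @export
attach_scores <- function(candidates, scores) {
  key <- paste(candidates$position, candidates$mut)
  skey <- paste(scores$position, scores$mut)
  i <- match(key, skey)
  candidates$ddg_a <- scores$ddg_a[i]
  candidates$ddg_b <- scores$ddg_b[i]
  candidates
}

#' Dual-predictor consensus stability filter
#'
#' A mutant is called stabilizing only when both predictors agree, each
#' under its own sign convention: `ddg_a < 0` (FoldX style) AND `ddg_b > 0`
#' (I-Mutant style), both inequalities strict. A candidate missing either
#' score is `incomplete` and excluded from the stabilizing subset.
#'
#' @param scored data.frame with columns `position`, `wt`, `mut`, `ddg_a`,
#'   `ddg_b`.
#' @return `scored` with a `verdict` column ("stabilizing" /
#'   "not-stabilizing" / "incomplete") and a `label` column (e.g. "H68A").
#' @export
consensus_filter <- function(scored) {
  stopifnot(all(c("ddg_a", "ddg_b") %in% names(scored)))
  verdict <- ifelse(is.na(scored$ddg_a) | is.na(scored$ddg_b), "incomplete",
                    ifelse(scored$ddg_a < 0 & scored$ddg_b > 0,
                           "stabilizing", "not-stabilizing"))
  scored$verdict <- verdict
  scored$label <- paste0(scored$wt, scored$position, scored$mut)
  scored
}

#' Stabilizing subset of a filtered candidate table
#'
#' @param filtered output of [consensus_filter()].
#' @return Character vector of labels (e.g. "H68A"), in table order.
#' @export
stabilizing_subset <- function(filtered) {
  filtered$label[filtered$verdict == "stabilizing"]
}

#' Positions-by-residue score matrix (heat-map layout)
#'
#' Serializable analogue of the dual-predictor mutation heat map: one row
#' per position, one column per amino acid, each cell carrying the paired
#' (ddg_a, ddg_b) scores; wild-type cells are null.
#'
#' @param scored output of [consensus_filter()] (or any scored candidate
#'   table).
#' @return A list of class `"ddg_heatmap"` with `positions`, `wt`,
#'   `amino_acids`, matrices `ddg_a` and `ddg_b` (NA at wt cells), and a
#'   logical `stabilizing` matrix.
#' @export
heatmap_matrix <- function(scored) {
  if (is.null(scored$verdict)) scored <- consensus_filter(scored)
  positions <- sort(unique(scored$position))
  aa <- sort(rownames(aa_properties()))
  mk <- function() matrix(NA_real_, length(positions), length(aa),
                          dimnames = list(positions, aa))
  A <- mk(); B <- mk()
  S <- matrix(FALSE, length(positions), length(aa),
              dimnames = list(positions, aa))
  i <- match(scored$position, positions)
  j <- match(scored$mut, aa)
  A[cbind(i, j)] <- scored$ddg_a
  B[cbind(i, j)] <- scored$ddg_b
  S[cbind(i, j)] <- scored$verdict == "stabilizing"
  wt <- vapply(positions,
               function(p) scored$wt[scored$position == p][1], character(1))
  structure(list(positions = positions, wt = wt, amino_acids = aa,
                 ddg_a = A, ddg_b = B, stabilizing = S),
            class = "ddg_heatmap")
}

#' Serialize / restore a heat map through JSON
#'
#' @param hm a `"ddg_heatmap"` from [heatmap_matrix()].
#' @param path output JSON file.
#' @return `heatmap_to_json` returns `path` invisibly; `heatmap_from_json`
#'   returns the restored `"ddg_heatmap"`.
#' @export
heatmap_to_json <- function(hm, path) {
  jsonlite::write_json(
    list(positions = hm$positions, wt = hm$wt, amino_acids = hm$amino_acids,
         ddg_a = hm$ddg_a, ddg_b = hm$ddg_b, stabilizing = hm$stabilizing),
    path, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname heatmap_to_json
#' @export
heatmap_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  dn <- list(x$positions, x$amino_acids)
  structure(list(positions = as.integer(x$positions), wt = x$wt,
                 amino_acids = x$amino_acids,
                 ddg_a = matrix(as.numeric(t(x$ddg_a)),
                                nrow = length(x$positions), byrow = TRUE,
                                dimnames = dn),
                 ddg_b = matrix(as.numeric(t(x$ddg_b)),
                                nrow = length(x$positions), byrow = TRUE,
                                dimnames = dn),
                 stabilizing = matrix(as.logical(t(x$stabilizing)),
                                      nrow = length(x$positions), byrow = TRUE,
                                      dimnames = dn)),
            class = "ddg_heatmap")
}
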