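#' Boltzmann constant (exact SI), J/K
#' @export
KB_JOULE_PER_K <- 1.380649e-23

#' Isothermal compressibility from volume fluctuations
#'
#' Estimates beta_T from the statistical-mechanical fluctuation relation
#' `<dV^2> = k_B * T * <V> * beta_T`: the variance of the region volume over
#' sampled frames, divided by k_B T times the mean volume. The variance is
#' the population variance (divide by n), following the ensemble-average
#' convention; set `variance = "sample"` for the n-1 estimator.
#'
#' Unit chain: volumes in Angstrom^3 (1 A^3 = 1e-30 m^3) give beta_T in
#' Pa^-1, reported in bar^-1 (1 Pa^-1 = 1e5 bar^-1).
#'
#' @param series a [volume_series()] with a condition carrying the
#'   temperature, or a bare numeric vector of volumes (Angstrom^3).
#' @param temperature absolute temperature (K); defaults to the series
#'   condition's temperature.
#' @param variance `"population"` (default) or `"sample"`.
#' @param unit `"bar"` (default) or `"Pa"` for the reciprocal pressure unit.
#' @return A list of class `"compressibility_estimate"` with fields
#'   `region`, `condition`, `mean_volume` (A^3), `volume_variance` (A^6),
#'   `beta_t` (bar^-1 or Pa^-1), `unit`, `n_samples`.
#' @export
beta_t <- function(series, temperature = NULL,
                   variance = c("population", "sample"),
                   unit = c("bar", "Pa")) {
  variance <- match.arg(variance)
  unit <- match.arg(unit)
  if (inherits(series, "volume_series")) {
    v <- series$volumes
    region <- series$region
    cond <- series$condition
    if (is.null(temperature)) {
      if (is.null(cond)) stop("no temperature: series has no condition")
      temperature <- cond$temperature
    }
  } else {
    v <- as.numeric(series)
    region <- NA_character_
    cond <- NULL
    if (is.null(temperature)) stop("temperature required for a bare series")
  }
  n <- length(v)
  if (n < 2) stop("need at least 2 volume samples")
  mv <- mean(v)
  if (mv <= 0) stop("non-positive mean volume")
  vv <- if (variance == "population") mean((v - mv)^2) else stats::var(v)
  # A^6 -> m^6 is 1e-60; A^3 -> m^3 is 1e-30; Pa^-1 -> bar^-1 is 1e5
  bt_pa <- (vv * 1e-60) / (KB_JOULE_PER_K * temperature * mv * 1e-30)
  bt <- if (unit == "bar") bt_pa * 1e5 else bt_pa
  structure(list(region = region, condition = cond, mean_volume = mv,
                 volume_variance = vv, beta_t = bt, unit = unit,
                 temperature = temperature, n_samples = n),
            class = "compressibility_estimate")
}

#' @export
print.compressibility_estimate <- function(x, ...) {
  cat(sprintf("beta_T[%s] = %.4g %s^-1 (<V> = %.4g A^3, n = %d%s)\n",
              x$region, x$beta_t, x$unit, x$mean_volume, x$n_samples,
              if (is.null(x$condition)) "" else paste0(", ", format(x$condition))))
  invisible(x)
}

#' Compressibility grid over regions and conditions
#'
#' @param series_list list of [volume_series()] objects, each carrying a
#'   condition.
#' @param ... passed to [beta_t()].
#' @return data.frame with columns `region`, `pressure`, `ethanol_fraction`,
#'   `temperature`, `mean_volume`, `beta_t`, `n_samples`.
#' @export
beta_t_grid <- function(series_list, ...) {
  rows <- lapply(series_list, function(s) {
    est <- beta_t(s, ...)
    data.frame(region = est$region,
               pressure = s$condition$pressure,
               ethanol_fraction = s$condition$ethanol_fraction,
               temperature = s$condition$temperature,
               mean_volume = est$mean_volume, beta_t = est$beta_t,
               n_samples = est$n_samples, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank regions by compressibility sensitivity across conditions
#'
#' A region's sensitivity score is the absolute range of its beta_T over the
#' condition grid (max minus min, bar^-1): regions whose compressibility
#' swings most across pressure/ethanol conditions are the "sensitive
#' fluctuation" regions targeted for mutagenesis. Ties break
#' alphabetically by region name. Regions missing from some conditions are
#' scored on the conditions they have, with a warning.
#'
#' @param grid data.frame as returned by [beta_t_grid()] (needs columns
#'   `region`, `beta_t`).
#' @param relative score by range/mean instead of absolute range.
#' @return data.frame of class `"sensitivity_ranking"` with columns
#'   `region`, `score`, `n_conditions`, sorted descending by score.
#' @export
sensitivity_ranking <- function(grid, relative = FALSE) {
  stopifnot(all(c("region", "beta_t") %in% names(grid)))
  n_cond <- tapply(grid$beta_t, grid$region, length)
  if (length(unique(n_cond)) > 1) {
    warning("regions cover different numbers of conditions; ",
            "scoring each on its available conditions")
  }
  if (any(n_cond < 2)) {
    stop("every region needs estimates under at least 2 conditions")
  }
  rng <- tapply(grid$beta_t, grid$region, function(b) max(b) - min(b))
  if (relative) rng <- rng / tapply(grid$beta_t, grid$region, mean)
  out <- data.frame(region = names(rng), score = as.numeric(rng),
                    n_conditions = as.integer(n_cond[names(rng)]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$region), ]
  rownames(out) <- NULL
  class(out) <- c("sensitivity_ranking", "data.frame")
  out
}

#' Top-k sensitive regions
#'
#' @param ranking a [sensitivity_ranking()].
#' @param k number of regions to keep.
#' @return Character vector of region names.
#' @export
top_regions <- function(ranking, k = 3) {
  utils::head(ranking$region, k)
}
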