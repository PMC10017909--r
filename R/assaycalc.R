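#' Enzyme activity from a colorimetric ammonia assay
#'
#' Activity (U, micromol product per minute) from the absorbance difference
#' at 625 nm between sample and blank: `dOD625 * n * k / t`, with `n` the
#' dilution factor of the enzyme solution, `k` the inverse slope of the
#' standard curve (micromol per absorbance unit) and `t` the reaction time
#' in minutes (15 in the standard assay).
#'
#' @param delta_od625 absorbance difference (>= 0; a negative value means
#'   the blank exceeded the sample and is an error).
#' @param dilution_n dilution multiple of the enzyme solution (>= 1).
#' @param slope_inverse_k inverse slope of the standard curve.
#' @param reaction_time reaction time in minutes (default 15).
#' @return Activity in U.
#' @export
activity <- function(delta_od625, dilution_n, slope_inverse_k,
                     reaction_time = 15) {
  stopifnot(is.finite(delta_od625), is.finite(dilution_n),
            is.finite(slope_inverse_k), reaction_time > 0, dilution_n >= 1)
  if (delta_od625 < 0) stop("negative delta OD625: blank exceeded sample")
  delta_od625 * dilution_n * slope_inverse_k / reaction_time
}

#' Fit the Michaelis-Menten equation
#'
#' Nonlinear least squares of `v = Vmax * S / (Km + S)` via
#' [minpack.lm::nlsLM()]. Start values: `Vmax0 = max(v)`, `Km0` the
#' substrate level whose rate is nearest half-maximal.
#'
#' @param substrate_mM substrate concentrations (mM), at least 4 levels
#'   spanning below and above Km.
#' @param rate observed rates (same unit as Vmax), non-negative.
#' @return A list of class `"kinetics_fit"` with `Km` (mM), `Vmax`,
#'   `Km_se`, `Vmax_se`, `fitted`, `reliable` (FALSE when Km falls outside
#'   (0, 10 * max S)), and the `nls` object as `fit`.
#' @export
fit_michaelis_menten <- function(substrate_mM, rate) {
  stopifnot(length(substrate_mM) == length(rate))
  keep <- substrate_mM > 0
  S <- substrate_mM[keep]
  v <- rate[keep]
  if (length(unique(S)) < 4) stop("need at least 4 non-zero substrate levels")
  if (any(v < 0)) stop("rates must be non-negative")
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S),
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 1e-12, Km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Michaelis-Menten fit failed to converge: ",
                             conditionMessage(e)))
  co <- summary(fit)$coefficients
  km <- co["Km", "Estimate"]
  out <- list(Km = km, Vmax = co["Vmax", "Estimate"],
              Km_se = co["Km", "Std. Error"],
              Vmax_se = co["Vmax", "Std. Error"],
              fitted = stats::fitted(fit),
              reliable = km > 0 && km < 10 * max(S),
              fit = fit)
  class(out) <- "kinetics_fit"
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Km = %.4g +/- %.2g mM, Vmax = %.4g +/- %.2g%s\n",
              x$Km, x$Km_se, x$Vmax, x$Vmax_se,
              if (x$reliable) "" else "  [Km flagged unreliable]"))
  invisible(x)
}

#' Turnover number from Vmax and enzyme concentration
#'
#' `kcat = Vmax / [E]`, converted from per-minute to per-second.
#'
#' @param vmax maximal rate (micromol substrate per minute per unit of
#'   enzyme amount).
#' @param enzyme_molar_conc enzyme molar concentration in the same amount
#'   unit (> 0).
#' @return kcat in s^-1.
#' @export
kcat <- function(vmax, enzyme_molar_conc) {
  stopifnot(vmax > 0)
  if (enzyme_molar_conc <= 0) stop("enzyme concentration must be positive")
  vmax / enzyme_molar_conc / 60
}

#' Catalytic efficiency on the reporting scale
#'
#' The ratio kcat (s^-1) over Km expressed in mM, matching how kinetic
#' tables commonly print kcat/Km for this assay (the printed unit label may
#' say s^-1 M^-1; numerically the tabulated values are the per-mM ratio,
#' and both scales are returned).
#'
#' @param kcat_s turnover number, s^-1.
#' @param km_mM Michaelis constant, mM.
#' @return Named numeric vector with `per_mM` (the printed scale) and
#'   `per_M` (kcat/Km with Km in molar).
#' @export
efficiency <- function(kcat_s, km_mM) {
  stopifnot(kcat_s > 0, km_mM > 0)
  c(per_mM = kcat_s / km_mM, per_M = kcat_s / (km_mM / 1000))
}

#' Fold change between two measurements
#'
#' @param value measurement of interest.
#' @param reference reference measurement (> 0).
#' @param digits rounding for reporting (default 2, the convention in
#'   kinetics tables).
#' @return `value / reference`, rounded to `digits`.
#' @export
fold_change <- function(value, reference, digits = 2) {
  if (reference <= 0) stop("reference must be positive")
  round(value / reference, digits)
}

#' Relative activity as a percentage of the maximum
#'
#' @param value activity measurement.
#' @param max_value the maximal activity in the series (> 0).
#' @param digits rounding for reporting (default 2).
#' @return Percentage.
#' @export
relative_activity <- function(value, max_value, digits = 2) {
  if (max_value <= 0) stop("max_value must be positive")
  round(100 * value / max_value, digits)
}
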