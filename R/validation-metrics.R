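# Assay-validation statistics: CV, LOD/LOQ, cross-method agreement.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of
#' replicate responses. Dimensionless; scale-invariant for positive scaling.
#'
#' @param values Numeric vector of >= 2 replicate responses, mean != 0.
#' @return The CV as a ratio (not a percentage).
#' @export
cv <- function(values) {
  if (!is.numeric(values) || length(values) < 2L || any(!is.finite(values)))
    dpph_error("cv needs >= 2 finite replicate values", "dpph_insufficient_replicates")
  m <- mean(values)
  if (m == 0)
    dpph_error("cv undefined for zero mean", "dpph_undefined_cv")
  stats::sd(values) / m
}

#' Limits of detection and quantitation
#'
#' The blank-noise convention: `LOD = 3.3 * sigma / slope` and
#' `LOQ = 10 * sigma / slope`, where `sigma` is the standard deviation of
#' the blank response and `slope` the sensitivity of the response-versus-
#' concentration calibration. Their ratio is 10/3.3 by construction.
#'
#' @param sigma Response noise (>= 0), in response units.
#' @param slope Calibration slope (> 0), response units per concentration
#'   unit. Pass the magnitude for signals that decrease with concentration.
#' @return List with `lod` and `loq`, in concentration units.
#' @export
lod_loq <- function(sigma, slope) {
  if (!is_number(sigma) || sigma < 0)
    dpph_error("sigma must be >= 0", "dpph_invalid_parameter")
  if (!is_number(slope) || slope <= 0)
    dpph_error("slope must be > 0", "dpph_invalid_slope")
  list(lod = 3.3 * sigma / slope, loq = 10 * sigma / slope)
}

#' Estimate response noise and calibration slope
#'
#' Feeds [lod_loq()]: `sigma` is the sample standard deviation of replicate
#' blank responses; `slope` is the ordinary-least-squares slope of mean
#' response versus concentration over the supplied (low-concentration,
#' assumed linear) levels.
#'
#' @param concentrations Concentrations of >= 3 distinct calibration levels.
#' @param responses Mean responses at those levels (same length).
#' @param blanks >= 2 replicate blank responses.
#' @return List with `sigma` and `slope` (signed; take `abs()` for
#'   decreasing signals before [lod_loq()]).
#' @export
response_noise_and_slope <- function(concentrations, responses, blanks) {
  if (!is.numeric(blanks) || length(blanks) < 2L)
    dpph_error("need >= 2 blank replicates", "dpph_insufficient_replicates")
  if (length(concentrations) != length(responses))
    dpph_error("concentrations and responses must have equal length",
               "dpph_invalid_parameter")
  if (length(unique(concentrations)) < 3L)
    dpph_error("need >= 3 distinct calibration levels", "dpph_design_error")
  if (stats::var(concentrations) == 0)
    dpph_error("zero variance in concentrations", "dpph_design_error")
  fit <- stats::lm(responses ~ concentrations)
  list(sigma = stats::sd(blanks), slope = unname(stats::coef(fit)[2]))
}

#' Agreement between two half-maximal estimate sets
#'
#' Ordinary least squares of the colorimetric estimates (CSC50) on the
#' spectrophotometric ones (SC50) across analytes, summarised by slope,
#' intercept and the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot`. Perfect method agreement gives slope 1,
#' intercept 0, R^2 = 1.
#'
#' @param pairs Data frame (or 2-column matrix) with columns `sc50` and
#'   `csc50`; >= 3 finite pairs, non-constant `sc50`.
#' @return An object of class `agreement_result`: `n`, `slope`, `intercept`,
#'   `r_squared`, and the `pairs` used.
#' @export
method_agreement <- function(pairs) {
  if (is.matrix(pairs)) pairs <- as.data.frame(pairs)
  if (!all(c("sc50", "csc50") %in% names(pairs))) {
    if (ncol(pairs) == 2L) names(pairs) <- c("sc50", "csc50")
    else dpph_error("pairs must have columns sc50 and csc50", "dpph_schema_error")
  }
  keep <- is.finite(pairs$sc50) & is.finite(pairs$csc50)
  pairs <- pairs[keep, c("sc50", "csc50"), drop = FALSE]
  if (nrow(pairs) < 3L)
    dpph_error("method agreement needs >= 3 finite pairs", "dpph_insufficient_data")
  if (stats::var(pairs$sc50) == 0)
    dpph_error("zero variance in sc50: regression undefined", "dpph_degenerate_regression")
  fit <- stats::lm(csc50 ~ sc50, data = pairs)
  res <- stats::residuals(fit)
  sstot <- sum((pairs$csc50 - mean(pairs$csc50))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(res^2) / sstot
  structure(list(n = nrow(pairs),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, pairs = pairs),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> n = %d: csc50 = %.4g * sc50 + %.4g, R^2 = %.4f\n",
              x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Validation report for one or more analytes
#'
#' Driver combining [cv()], [response_noise_and_slope()] and [lod_loq()]
#' per analyte: `sigma` from replicate blank responses, the slope from the
#' `n_low_levels` lowest concentrations of the reaction records (slope
#' magnitude is used, so decreasing absorbance calibrations are handled),
#' and the CV as the mean over concentration levels of the per-level
#' replicate CV (levels with < 2 replicates are skipped).
#'
#' @param measurements Data frame with `sample_id, concentration, replicate,
#'   role` and the response column named by `basis`.
#' @param blanks Data frame with `sample_id` and the response column, or a
#'   numeric vector of pooled blank responses applied to every analyte.
#' @param basis `"colour_value"` or `"absorbance"`.
#' @param n_low_levels Number of lowest concentrations for the calibration
#'   slope (>= 3).
#' @return Data frame (class `validation_report`) with one row per analyte:
#'   `analyte, basis, sigma, slope, lod, loq, cv`.
#' @export
validate_assay <- function(measurements, blanks,
                           basis = c("colour_value", "absorbance"),
                           n_low_levels = 3L) {
  basis <- match.arg(basis)
  if (!basis %in% names(measurements))
    dpph_error(paste("measurements lack response column", basis), "dpph_schema_error")
  rx <- measurements[measurements$role == "reaction", , drop = FALSE]
  out <- lapply(split(rx, rx$sample_id), function(d) {
    bl <- if (is.data.frame(blanks)) blanks[[basis]][blanks$sample_id == d$sample_id[1]]
          else blanks
    levels <- sort(unique(d$concentration))
    low <- levels[seq_len(min(n_low_levels, length(levels)))]
    means <- vapply(low, function(ci) mean(d[[basis]][d$concentration == ci]), 0)
    ns <- response_noise_and_slope(low, means, bl)
    ll <- lod_loq(ns$sigma, abs(ns$slope))
    cvs <- vapply(levels, function(ci) {
      v <- d[[basis]][d$concentration == ci]
      if (length(v) >= 2L && mean(v) != 0) cv(v) else NA_real_
    }, 0)
    data.frame(analyte = d$sample_id[1], basis = basis,
               sigma = ns$sigma, slope = ns$slope,
               lod = ll$lod, loq = ll$loq,
               cv = mean(cvs, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("validation_report", "data.frame")
  rep
}
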