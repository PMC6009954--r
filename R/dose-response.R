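# Dose-response curves and half-maximal estimators.
#
# Two read-outs share one curve container: absorbance at 517 nm (decreasing
# with antioxidant concentration as DPPH is scavenged) and spot colour value
# (mean grey, increasing as the dark radical spot fades towards the plate).
# SC50 halves the initial absorbance; CSC50 is the concentration at half the
# colour-value rise, located either by linear interpolation (half-maximum
# method) or as the steepest point of the curve (first-derivative method).

HALF_MAX_STATUSES <- c("ok", "censored_low", "censored_high",
                       "non_monotone_warning", "tie_warning")

#' Aggregate replicate measurements into a dose-response curve
#'
#' Groups `role == "reaction"` records by concentration and computes the
#' per-level mean, sample standard deviation (n - 1 denominator; 0 when
#' n = 1) and replicate count, sorted by increasing concentration. The
#' zero-scavenging reference (`blank_response`) is the mean response of
#' `role == "reagent_blank"` records when present. For colour curves
#' `max_response` — the response at complete DPPH reduction — defaults to
#' the largest observed mean, flagged as an observed plateau because it
#' biases CSC50 low when the plateau is unreached.
#'
#' @param measurements Data frame with columns `sample_id, concentration,
#'   unit, replicate, role` and the response column named by `response_kind`
#'   (`colour_value` or `absorbance`), e.g. from [quantify_plate()] or
#'   [read_absorbance_csv()].
#' @param response_kind `"colour_value"` or `"absorbance"`.
#' @param max_response Optional known complete-reduction response.
#' @param blank_response Optional explicit zero-scavenging response,
#'   overriding reagent-blank records.
#' @return An object of class `dose_response_curve`: fields `sample_id`,
#'   `response_kind`, `unit`, `points` (data frame `concentration, response,
#'   sd, n`), `blank_response`, `max_response`, `max_response_observed`,
#'   `corrections`.
#' @export
aggregate_curve <- function(measurements,
                            response_kind = c("colour_value", "absorbance"),
                            max_response = NULL, blank_response = NULL) {
  response_kind <- match.arg(response_kind)
  need <- c("sample_id", "concentration", "unit", "replicate", "role", response_kind)
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    dpph_error(paste("measurements missing column(s):", paste(miss, collapse = ", ")),
               "dpph_schema_error")
  units <- unique(measurements$unit)
  if (length(units) > 1L)
    dpph_error(paste("mixed concentration units in one curve:",
                     paste(units, collapse = ", ")), "dpph_unit_error")
  sid <- unique(measurements$sample_id)
  if (length(sid) > 1L)
    dpph_error("aggregate_curve expects a single sample_id", "dpph_schema_error")
  rx <- measurements[measurements$role == "reaction", , drop = FALSE]
  if (length(unique(rx$concentration)) < 2L)
    dpph_error("need >= 2 distinct reaction concentrations", "dpph_insufficient_data")
  resp <- rx[[response_kind]]
  pts <- do.call(rbind, lapply(split(seq_len(nrow(rx)), rx$concentration), function(idx) {
    v <- resp[idx]
    data.frame(concentration = rx$concentration[idx[1]], response = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0, n = length(v))
  }))
  pts <- pts[order(pts$concentration), , drop = FALSE]
  rownames(pts) <- NULL
  if (is.null(blank_response)) {
    bl <- measurements[measurements$role == "reagent_blank", response_kind]
    blank_response <- if (length(bl)) mean(bl) else NA_real_
  }
  observed <- is.null(max_response)
  if (observed) max_response <- max(pts$response)
  structure(list(sample_id = sid, response_kind = response_kind,
                 unit = units, points = pts,
                 blank_response = blank_response,
                 max_response = max_response,
                 max_response_observed = observed,
                 corrections = character()),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("<dose_response_curve> %s, %s, %d level(s) [%s]\n",
              x$sample_id, x$response_kind, nrow(x$points), x$unit))
  print(x$points, ...)
  invisible(x)
}

#' Correct a colour curve for the extract's own colour
#'
#' Coloured extracts darken their spots even without DPPH. The correction
#' model is additive: with `b(c)` the colour value of a sample+solvent-only
#' drop at concentration `c` and `baseline` the clean-plate grey, the
#' corrected reaction response is `response - (b(c) - baseline)`. A single
#' pooled blank value may be supplied instead of per-level blanks.
#'
#' @param curve A colour-value [aggregate_curve()] result.
#' @param extract_blanks Either one number (pooled blank colour value) or a
#'   data frame with columns `concentration` and `colour_value` covering
#'   every curve concentration.
#' @param baseline Clean-plate background grey value.
#' @return The corrected curve; the correction is recorded in
#'   `curve$corrections`.
#' @export
blank_correct_extract <- function(curve, extract_blanks, baseline) {
  if (curve$response_kind != "colour_value")
    dpph_error("extract-blank correction applies to colour-value curves",
               "dpph_invalid_parameter")
  if (!is_number(baseline))
    dpph_error("baseline must be a single finite number", "dpph_invalid_parameter")
  if (is.numeric(extract_blanks) && length(extract_blanks) == 1L) {
    corr <- rep(extract_blanks - baseline, nrow(curve$points))
    mode <- "pooled"
  } else {
    if (!is.data.frame(extract_blanks) ||
        !all(c("concentration", "colour_value") %in% names(extract_blanks)))
      dpph_error("extract_blanks must be a number or a data frame with concentration and colour_value",
                 "dpph_schema_error")
    idx <- match(curve$points$concentration, extract_blanks$concentration)
    if (anyNA(idx))
      dpph_error(sprintf("missing extract blank for concentration %g",
                         curve$points$concentration[which(is.na(idx))[1]]),
                 "dpph_missing_blank")
    corr <- extract_blanks$colour_value[idx] - baseline
    mode <- "per-level"
  }
  curve$points$response <- curve$points$response - corr
  if (curve$max_response_observed) curve$max_response <- max(curve$points$response)
  curve$corrections <- c(curve$corrections,
                         sprintf("extract_blank:%s baseline=%g", mode, baseline))
  curve
}

#' Percent scavenging at one concentration
#'
#' `100 * (a_control - a_sample) / a_control`: the percentage of the initial
#' DPPH absorbance removed by the sample.
#'
#' @param a_control Control (no antioxidant) absorbance, > 0.
#' @param a_sample Sample absorbance.
#' @return Percentage (vectorised over `a_sample`).
#' @export
percent_scavenging <- function(a_control, a_sample) {
  if (!is_number(a_control) || a_control <= 0)
    dpph_error("control absorbance must be > 0", "dpph_invalid_control")
  100 * (a_control - a_sample) / a_control
}

half_max_result <- function(sample_id, method, value, unit, bracketing_points,
                            status, target = NA_real_, diagnostics = list()) {
  stopifnot(status %in% HALF_MAX_STATUSES)
  structure(list(sample_id = sample_id, method = method, value = value,
                 unit = unit, bracketing_points = bracketing_points,
                 status = status, target = target, diagnostics = diagnostics),
            class = "half_max_result")
}

#' @export
print.half_max_result <- function(x, ...) {
  cat(sprintf("<half_max_result> %s: %s = %s %s (%s)\n", x$sample_id, x$method,
              if (is.na(x$value)) "NA" else format(x$value), x$unit, x$status))
  invisible(x)
}

# Shared crossing finder: first adjacent pair (scanning from low
# concentration) whose mean responses bracket `target`, linear interpolation
# on the linear concentration axis. `direction` is the expected sign of the
# response trend (+1 increasing, -1 decreasing), used for censoring sides
# and the monotonicity warning.
interpolate_crossing <- function(curve, target, direction, method) {
  pts <- curve$points
  r <- pts$response; cc <- pts$concentration
  monotone <- if (direction > 0) !is.unsorted(r) else !is.unsorted(rev(r))
  hit <- which(r == target)
  if (length(hit)) {
    i <- hit[1]
    return(half_max_result(curve$sample_id, method, cc[i], curve$unit,
                           pts[i, , drop = FALSE],
                           if (monotone) "ok" else "non_monotone_warning",
                           target))
  }
  cross <- which((r[-length(r)] - target) * (r[-1] - target) < 0)
  if (length(cross) == 0L) {
    # no crossing: censored on the side the trend would have reached
    above <- all(r > target)
    status <- if (direction > 0) {
      if (above) "censored_low" else "censored_high"
    } else {
      if (above) "censored_high" else "censored_low"
    }
    return(half_max_result(curve$sample_id, method, NA_real_, curve$unit,
                           pts[0, , drop = FALSE], status, target))
  }
  i <- cross[1]
  value <- cc[i] + (target - r[i]) / (r[i + 1] - r[i]) * (cc[i + 1] - cc[i])
  half_max_result(curve$sample_id, method, value, curve$unit,
                  pts[c(i, i + 1), , drop = FALSE],
                  if (monotone) "ok" else "non_monotone_warning", target)
}

#' SC50 from an absorbance curve
#'
#' The sample concentration halving the initial DPPH absorbance `A0` (the
#' reagent-blank response). The target `A0 / 2` is located on the mean
#' curve by linear interpolation between the first bracketing pair of
#' adjacent concentrations, scanning from the lowest concentration. When the
#' target lies outside the observed responses the result is censored
#' (`censored_low` / `censored_high`); a non-monotone mean curve yields
#' `non_monotone_warning` with the first crossing.
#'
#' @param curve An absorbance [aggregate_curve()] result with
#'   `blank_response` (A0) known.
#' @return A `half_max_result` with method `"sc50_absorbance"`.
#' @export
sc50_from_absorbance <- function(curve) {
  if (curve$response_kind != "absorbance")
    dpph_error("sc50_from_absorbance needs an absorbance curve", "dpph_invalid_parameter")
  a0 <- curve$blank_response
  if (!is_number(a0))
    dpph_error("initial absorbance A0 (reagent blank) is missing", "dpph_missing_blank")
  interpolate_crossing(curve, a0 / 2, direction = -1, method = "sc50_absorbance")
}

#' CSC50 by the half-maximum method
#'
#' The sample concentration raising the spot colour value halfway from the
#' zero-scavenging reference (`blank_response`, the dark unscavenged spot)
#' to `max_response` (the colour at complete DPPH reduction). The target
#' `blank + (max - blank) / 2` is located by the same first-crossing linear
#' interpolation as [sc50_from_absorbance()].
#'
#' @param curve A colour-value [aggregate_curve()] result.
#' @param blank_response,max_response Optional overrides of the curve fields.
#' @return A `half_max_result` with method `"csc50_halfmax"`.
#' @export
csc50_halfmax <- function(curve, blank_response = NULL, max_response = NULL) {
  if (curve$response_kind != "colour_value")
    dpph_error("csc50_halfmax needs a colour-value curve", "dpph_invalid_parameter")
  blank <- if (is.null(blank_response)) curve$blank_response else blank_response
  mx <- if (is.null(max_response)) curve$max_response else max_response
  if (!is_number(blank))
    dpph_error("zero-scavenging blank response is missing", "dpph_missing_blank")
  if (!is_number(mx) || mx <= blank)
    dpph_error("max_response must exceed blank_response", "dpph_degenerate_range")
  res <- interpolate_crossing(curve, blank + (mx - blank) / 2,
                              direction = +1, method = "csc50_halfmax")
  res$diagnostics$max_response_observed <- curve$max_response_observed
  res
}

#' First-derivative curve of a dose-response curve
#'
#' Forward finite differences of the mean responses between consecutive
#' concentrations, each assigned to the arithmetic midpoint of its
#' concentration pair: the discrete version of plotting
#' d(colour value)/d(concentration) against concentration. No smoothing is
#' applied by default; an optional moving-average hook (`smooth_window`, odd
#' width in points) exists but changes the estimator and is off by default.
#'
#' @param curve An [aggregate_curve()] result with >= 3 points.
#' @param smooth_window 1 (no smoothing, default) or an odd window width for
#'   a moving average of the mean responses before differencing.
#' @return An object of class `derivative_curve`: `sample_id`, `points`
#'   (data frame `concentration` (midpoints), `slope`), and the source pairs.
#' @export
derivative_curve <- function(curve, smooth_window = 1L) {
  pts <- curve$points
  if (nrow(pts) < 3L)
    dpph_error("derivative curve needs >= 3 points", "dpph_insufficient_data")
  if (!is_count(smooth_window) || smooth_window %% 2 == 0)
    dpph_error("smooth_window must be an odd positive integer", "dpph_invalid_parameter")
  r <- pts$response
  if (smooth_window > 1L) {
    k <- min(smooth_window, nrow(pts) - (1 - nrow(pts) %% 2))
    r <- stats::filter(r, rep(1 / k, k), sides = 2)
    # keep the endpoints unsmoothed rather than dropping them
    r[is.na(r)] <- pts$response[is.na(r)]
    r <- as.numeric(r)
  }
  cc <- pts$concentration
  n <- length(cc)
  structure(list(sample_id = curve$sample_id, unit = curve$unit,
                 points = data.frame(
                   concentration = (cc[-n] + cc[-1]) / 2,
                   slope = diff(r) / diff(cc)),
                 pairs = data.frame(c_lo = cc[-n], c_hi = cc[-1],
                                    r_lo = r[-n], r_hi = r[-1])),
            class = "derivative_curve")
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat(sprintf("<derivative_curve> %s, %d interval(s)\n", x$sample_id, nrow(x$points)))
  print(x$points, ...)
  invisible(x)
}

#' CSC50 by the first-derivative method
#'
#' The concentration showing the highest increment of colour value per unit
#' concentration: the midpoint concentration of the steepest interval of the
#' dose-response curve. Ties (equal maximal slopes) are broken towards the
#' lowest concentration and flagged with status `tie_warning`.
#'
#' @inheritParams derivative_curve
#' @return A `half_max_result` with method `"csc50_derivative"`;
#'   `bracketing_points` records the winning concentration pair.
#' @export
csc50_derivative <- function(curve, smooth_window = 1L) {
  if (curve$response_kind != "colour_value")
    dpph_error("csc50_derivative needs a colour-value curve", "dpph_invalid_parameter")
  dc <- derivative_curve(curve, smooth_window)
  sl <- dc$points$slope
  mx <- max(sl)
  tol <- 1e-9 * max(1, abs(mx))
  winners <- which(sl >= mx - tol)
  i <- winners[1]
  half_max_result(curve$sample_id, "csc50_derivative",
                  dc$points$concentration[i], curve$unit,
                  dc$pairs[i, , drop = FALSE],
                  if (length(winners) > 1L) "tie_warning" else "ok",
                  diagnostics = list(max_slope = mx))
}
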