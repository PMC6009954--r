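# Ground-truth generator: scavenging model, absorbance simulation,
# plate-image rendering, end-to-end recovery harness.
#
# The generative story: a fraction f(c) of the DPPH radical is scavenged at
# antioxidant concentration c. The spectrophotometric branch reads
# A(c) = A0 * (1 - f(c)); the plate branch renders a drop whose interior
# grey is background - depth * (1 - f(c)) (the unscavenged purple radical
# darkens the spot; as it is reduced the spot fades into the plate), then
# applies an affine scanner brightness/contrast transform and sensor noise.

#' Scavenging model
#'
#' The functional form of the scavenged fraction is a simulation choice (the
#' assay reads its curves graphically and implies none):
#' * `logistic_log` (default): a Hill curve,
#'   `f(c) = c^h / (c^h + c50^h)` — logistic in log concentration, with
#'   `f(0) = 0` and `f(c50) = 1/2` exactly.
#' * `logistic_linear`: a logistic in linear concentration centred at `c50`
#'   with rate `4 h / c50`, so `f(c50) = 1/2` exactly and `f(0)` is small
#'   for slopes `h >= 1.2`.
#'
#' @param true_c50 Concentration at half-maximal scavenging (> 0).
#' @param hill Slope parameter h (> 0); default 2, a typical steepness for
#'   antioxidant dose-response curves.
#' @param form `"logistic_log"` or `"logistic_linear"`.
#' @return An object of class `scavenging_model`.
#' @export
scavenging_model <- function(true_c50, hill = 2,
                             form = c("logistic_log", "logistic_linear")) {
  form <- match.arg(form)
  if (!is_number(true_c50) || true_c50 <= 0)
    dpph_error("true_c50 must be > 0", "dpph_invalid_parameter")
  if (!is_number(hill) || hill <= 0)
    dpph_error("hill must be > 0", "dpph_invalid_parameter")
  structure(list(true_c50 = true_c50, hill = hill, form = form),
            class = "scavenging_model")
}

#' Fraction of DPPH scavenged at a concentration
#'
#' @param model A [scavenging_model()].
#' @param c Concentrations (>= 0, vectorised).
#' @return Scavenged fractions in \[0, 1\].
#' @export
fraction_scavenged <- function(model, c) {
  if (any(!is.finite(c)) || any(c < 0))
    dpph_error("concentrations must be finite and >= 0", "dpph_domain_error")
  with(model, switch(form,
    logistic_log = ifelse(c == 0, 0, c^hill / (c^hill + true_c50^hill)),
    logistic_linear = 1 / (1 + exp(-(4 * hill / true_c50) * (c - true_c50)))))
}

#' Simulate a spectrophotometric absorbance series
#'
#' `A(c) = a0 * (1 - f(c)) + e`, `e ~ N(0, noise_sd)`, truncated at 0, for
#' every (level, replicate) of the dilution ladder, plus reagent-blank
#' records at `A = a0 + e` (concentration 0). Reproducible for a given seed;
#' the caller's RNG state is untouched.
#'
#' @param model A [scavenging_model()].
#' @param series A [dilution_series()].
#' @param a0 Initial (unscavenged) absorbance; default 0.9, a typical 517 nm
#'   reading of the diluted DPPH working solution in a 1 cm cuvette.
#' @param noise_sd Absorbance noise standard deviation.
#' @param n_replicates Replicates per level.
#' @param n_blank_replicates Reagent-blank replicates.
#' @param seed Integer RNG seed.
#' @param sample_id Identifier stamped on the records.
#' @return Data frame with columns `sample_id, concentration, unit,
#'   replicate, absorbance, role`.
#' @export
simulate_absorbance_series <- function(model, series, a0 = 0.9, noise_sd = 0,
                                       n_replicates = 3, n_blank_replicates = 3,
                                       seed = 1, sample_id = "analyte") {
  if (!is_number(a0) || a0 <= 0)
    dpph_error("a0 must be > 0", "dpph_invalid_parameter")
  conc <- series$concentrations
  f <- fraction_scavenged(model, conc)
  rec <- data.frame(
    sample_id = sample_id,
    concentration = rep(conc, each = n_replicates),
    unit = series$unit,
    replicate = rep(seq_len(n_replicates), times = length(conc)),
    absorbance = rep(a0 * (1 - f), each = n_replicates),
    role = "reaction", stringsAsFactors = FALSE)
  bl <- data.frame(sample_id = sample_id, concentration = 0, unit = series$unit,
                   replicate = seq_len(n_blank_replicates), absorbance = a0,
                   role = "reagent_blank", stringsAsFactors = FALSE)
  out <- rbind(rec, bl)
  if (noise_sd > 0)
    out$absorbance <- with_seed(seed, pmax(0, out$absorbance +
                                              stats::rnorm(nrow(out), 0, noise_sd)))
  out
}

#' Rendering configuration for synthetic plate images
#'
#' @param layout A [plate_layout()]; wells may be pre-assigned or filled by
#'   [render_plate()].
#' @param background_grey Clean-plate grey level; default 200 (pale silica
#'   under a darkened scan).
#' @param dpph_dark_depth Grey units by which a fully unscavenged spot falls
#'   below the background; the spot interior is
#'   `background - depth * (1 - f(c))`. Default 140.
#' @param extract_self_depth Grey units of the extract's own colour below
#'   background, used for `extract_blank` wells; 0 = colourless sample.
#' @param noise_sd Per-pixel Gaussian sensor noise, grey units; default 2.
#' @param edge_softness Raised-cosine edge half-width in pixels; partial-
#'   volume pixels at the spot rim exercise the ROI mean realistically.
#' @param scan_brightness,scan_contrast Affine acquisition transform
#'   `g' = contrast * (g - 128) + 128 + brightness`, clipped to \[0, 255\];
#'   defaults (0, 1) are the identity. A scanner profile like brightness
#'   -100 / contrast 85 (a vendor 0-100 scale, not a calibrated gain) can be
#'   emulated by choosing an offset/gain pair.
#' @param noise_before_scan Apply noise before the scan transform instead of
#'   after (default `FALSE`: scanner-referred signal, sensor-dominated noise).
#' @param seed Integer RNG seed; fully determines the render.
#' @return An object of class `render_config`.
#' @export
render_config <- function(layout, background_grey = 200, dpph_dark_depth = 140,
                          extract_self_depth = 0, noise_sd = 2,
                          edge_softness = 2, scan_brightness = 0,
                          scan_contrast = 1, noise_before_scan = FALSE,
                          seed = 1) {
  if (!inherits(layout, "plate_layout"))
    dpph_error("layout must be a plate_layout", "dpph_invalid_parameter")
  if (background_grey < 0 || background_grey > 255)
    dpph_error("background_grey must be in [0, 255]", "dpph_invalid_parameter")
  if (noise_sd < 0 || edge_softness < 0 || scan_contrast <= 0)
    dpph_error("noise_sd, edge_softness >= 0 and scan_contrast > 0 required",
               "dpph_invalid_parameter")
  structure(list(layout = layout, background_grey = background_grey,
                 dpph_dark_depth = dpph_dark_depth,
                 extract_self_depth = extract_self_depth,
                 noise_sd = noise_sd, edge_softness = edge_softness,
                 scan_brightness = scan_brightness,
                 scan_contrast = scan_contrast,
                 noise_before_scan = isTRUE(noise_before_scan),
                 seed = as.integer(seed)),
            class = "render_config")
}

#' Affine scanner brightness/contrast transform
#'
#' `g' = contrast * (g - 128) + 128 + brightness`, clipped to \[0, 255\].
#' With contrast 1 and brightness 0 it is the identity on unclipped values.
#'
#' @param g Grey values (vectorised).
#' @param brightness Additive offset.
#' @param contrast Multiplicative gain about mid-grey 128.
#' @return Transformed grey values.
#' @export
scan_transform <- function(g, brightness = 0, contrast = 1) {
  clip255(contrast * (g - 128) + 128 + brightness)
}

# Raised-cosine radial weight: 1 inside radius - s, 0 outside radius + s.
edge_weight <- function(r, radius, s) {
  if (s <= 0) return(as.numeric(r <= radius))
  w <- numeric(length(r))
  w[r <= radius - s] <- 1
  taper <- r > radius - s & r < radius + s
  w[taper] <- 0.5 * (1 + cos(pi * (r[taper] - (radius - s)) / (2 * s)))
  w
}

#' Render a synthetic plate image with known ground truth
#'
#' Draws each assigned well as a soft-edged disc whose interior grey encodes
#' the scavenged fraction, applies the scanner transform, then per-pixel
#' noise, and quantises to 8-bit. The ground-truth table records each spot's
#' mean grey over its ROI disc on the noiseless, scan-transformed, quantised
#' image — exactly what an ideal quantifier should recover.
#'
#' Roles: `reaction` spots use `f(c)` from the model; `reagent_blank` and
#' `solvent_control` spots are fully unscavenged (`f = 0`); `extract_blank`
#' spots show only the extract's own colour (`extract_self_depth`).
#'
#' @param model A [scavenging_model()].
#' @param config A [render_config()].
#' @param series,n_replicates,sample_id,n_reagent_blanks Used to populate
#'   the layout via [layout_to_wells()] when `config$layout` has no wells.
#' @return List (class `synthetic_plate`) with `image` (a [plate_image()]),
#'   `truth` (data frame: well columns plus `centre_x, centre_y, radius,
#'   true_mean_grey`), `layout`, and `config`.
#' @export
render_plate <- function(model, config, series = NULL, n_replicates = 3,
                         sample_id = "analyte", n_reagent_blanks = 3) {
  layout <- config$layout
  if (nrow(layout$wells) == 0L) {
    if (is.null(series))
      dpph_error("layout has no wells and no series was supplied", "dpph_layout_error")
    layout <- layout_to_wells(layout, series, sample_id, n_replicates,
                              n_reagent_blanks = n_reagent_blanks)
  }
  wells <- layout$wells
  width <- as.integer(ceiling(layout$origin[["x"]] + (layout$n_cols - 1) * layout$pitch_x +
                                layout$origin[["x"]]))
  height <- as.integer(ceiling(layout$origin[["y"]] + (layout$n_rows - 1) * layout$pitch_y +
                                 layout$origin[["y"]]))
  canvas <- matrix(config$background_grey, nrow = height, ncol = width)
  centres <- spot_centres(layout)
  f <- fraction_scavenged(model, wells$concentration)
  depth <- ifelse(wells$role == "reaction", config$dpph_dark_depth * (1 - f),
           ifelse(wells$role == "extract_blank", config$extract_self_depth,
                  config$dpph_dark_depth))  # reagent blank / solvent control: f = 0
  R <- layout$spot_radius; s <- config$edge_softness
  for (i in seq_len(nrow(wells))) {
    cx <- centres$x[i]; cy <- centres$y[i]
    half <- R + s
    r0 <- max(1L, as.integer(ceiling(cy - half))); r1 <- min(height, as.integer(floor(cy + half)))
    c0 <- max(1L, as.integer(ceiling(cx - half))); c1 <- min(width, as.integer(floor(cx + half)))
    rows <- r0:r1; cols <- c0:c1
    rad <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
    w <- edge_weight(rad, R, s)
    canvas[rows, cols] <- canvas[rows, cols] - w * depth[i]
  }
  noiseless <- scan_transform(canvas, config$scan_brightness, config$scan_contrast)
  truth_img <- clip255(round_half_up(noiseless))
  truth <- cbind(wells,
                 centre_x = centres$x, centre_y = centres$y, radius = R,
                 true_mean_grey = vapply(seq_len(nrow(wells)), function(i) {
                   d <- disc_mask(centres$x[i], centres$y[i], R, width, height)
                   mean(truth_img[d$rows, d$cols, drop = FALSE][d$mask])
                 }, 0))
  final <- if (config$noise_sd > 0) {
    noisy <- with_seed(config$seed, {
      e <- matrix(stats::rnorm(height * width, 0, config$noise_sd), height, width)
      if (config$noise_before_scan)
        scan_transform(canvas + e, config$scan_brightness, config$scan_contrast)
      else noiseless + e
    })
    clip255(round_half_up(noisy))
  } else truth_img
  structure(list(image = plate_image(final, source_path = "synthetic"),
                 truth = truth, layout = layout, config = config),
            class = "synthetic_plate")
}

#' @export
print.synthetic_plate <- function(x, ...) {
  cat(sprintf("<synthetic_plate> %d x %d px, %d spot(s), seed %d\n",
              x$image$width, x$image$height, nrow(x$truth), x$config$seed))
  invisible(x)
}

#' End-to-end parameter-recovery harness
#'
#' For each analyte (one true c50 per entry) the harness runs both assay
#' branches from the same generative model: the spectrophotometric branch
#' ([simulate_absorbance_series()] then [sc50_from_absorbance()]) and the
#' plate branch ([render_plate()], [quantify_plate()], then both CSC50
#' estimators), and summarises the cross-method agreement with
#' [method_agreement()].
#'
#' Each analyte's two-fold ladder starts at `top_multiple * true_c50` so the
#' c50 is bracketed; with 9 levels and `top_multiple = 16` the ladder spans
#' 16x down to x/16 around the c50.
#'
#' @param true_c50 Numeric vector (>= 3) of true half-scavenging
#'   concentrations.
#' @param hill,form Passed to [scavenging_model()].
#' @param n_levels,dilution_factor,top_multiple Ladder design.
#' @param n_replicates Replicates per level in both branches.
#' @param a0,absorbance_noise_sd Spectrophotometric branch parameters.
#' @param pixel_noise_sd Per-pixel grey noise of the rendered plates.
#' @param spot_radius,pitch Plate geometry (pixels); small defaults keep a
#'   9-level triplicate plate around 440 x 140 px.
#' @param seed Master seed; per-analyte sub-seeds are drawn from it.
#' @param unit Concentration unit label.
#' @return List (class `recovery_report`): `estimates` (data frame per
#'   analyte: `sample_id, true_c50, sc50, csc50_halfmax, csc50_derivative`,
#'   statuses and biases), `agreement_halfmax`, `agreement_derivative`.
#' @export
end_to_end_recovery <- function(true_c50, hill = 2, form = "logistic_log",
                                n_levels = 9, dilution_factor = 2,
                                top_multiple = 16, n_replicates = 3,
                                a0 = 0.9, absorbance_noise_sd = 0,
                                pixel_noise_sd = 2, spot_radius = 10,
                                pitch = 28, seed = 1, unit = "uM") {
  k <- length(true_c50)
  if (k < 3L)
    dpph_error("end_to_end_recovery needs >= 3 analytes", "dpph_insufficient_data")
  sub_seeds <- with_seed(seed, sample.int(2147483646L, 2L * k))
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    sid <- sprintf("analyte_%02d", i)
    model <- scavenging_model(true_c50[i], hill = hill, form = form)
    series <- dilution_series(top_multiple * true_c50[i], dilution_factor,
                              n_levels, unit)
    # spectrophotometric branch
    abs_rec <- simulate_absorbance_series(model, series, a0 = a0,
                                          noise_sd = absorbance_noise_sd,
                                          n_replicates = n_replicates,
                                          seed = sub_seeds[2 * i - 1],
                                          sample_id = sid)
    sc50 <- sc50_from_absorbance(aggregate_curve(abs_rec, "absorbance"))
    # plate branch
    layout <- plate_layout(n_rows = n_replicates, n_cols = n_levels + 1,
                           origin = c(x = pitch / 2 + spot_radius,
                                      y = pitch / 2 + spot_radius),
                           pitch_x = pitch, pitch_y = pitch,
                           spot_radius = spot_radius)
    layout <- layout_to_wells(layout, series, sid, n_replicates,
                              fill_order = "col-major",
                              n_reagent_blanks = n_replicates)
    cfg <- render_config(layout, noise_sd = pixel_noise_sd,
                         seed = sub_seeds[2 * i])
    plate <- render_plate(model, cfg)
    meas <- quantify_plate(plate$image, plate$layout, refine = TRUE)
    curve <- aggregate_curve(meas, "colour_value")
    half <- csc50_halfmax(curve)
    deriv <- csc50_derivative(curve)
    rows[[i]] <- data.frame(
      sample_id = sid, true_c50 = true_c50[i],
      sc50 = sc50$value, sc50_status = sc50$status,
      csc50_halfmax = half$value, halfmax_status = half$status,
      csc50_derivative = deriv$value, derivative_status = deriv$status,
      stringsAsFactors = FALSE)
  }
  est <- do.call(rbind, rows)
  est$bias_halfmax <- est$csc50_halfmax - est$true_c50
  est$bias_derivative <- est$csc50_derivative - est$true_c50
  structure(list(
    estimates = est,
    agreement_halfmax = method_agreement(
      data.frame(sc50 = est$sc50, csc50 = est$csc50_halfmax)),
    agreement_derivative = method_agreement(
      data.frame(sc50 = est$sc50, csc50 = est$csc50_derivative))),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d analyte(s)\n", nrow(x$estimates)))
  print(x$estimates[c("sample_id", "true_c50", "sc50", "csc50_halfmax",
                      "csc50_derivative")], ...)
  cat(sprintf("  half-max  agreement R^2 = %.4f\n", x$agreement_halfmax$r_squared))
  cat(sprintf("  derivative agreement R^2 = %.4f\n", x$agreement_derivative$r_squared))
  invisible(x)
}
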