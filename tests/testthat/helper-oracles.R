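# Independent oracles and fixture builders used across the suite.

# Brute-force pixel-loop mean over a disc: deliberately naive double loop,
# independent of the vectorised disc_mask code path.
brute_force_disc_mean <- function(pixels, cx, cy, radius) {
  vals <- c()
  for (r in seq_len(nrow(pixels))) {
    for (cc in seq_len(ncol(pixels))) {
      if ((cc - cx)^2 + (r - cy)^2 <= radius^2)
        vals <- c(vals, pixels[r, cc])
    }
  }
  list(colour_value = mean(vals), n_pixels = length(vals))
}

# Independent crossing finder: piecewise-linear interpolant of the mean
# curve, first bracketing segment solved by uniroot (numeric root-finding,
# not the package's algebraic interpolation).
uniroot_crossing <- function(conc, resp, target, tol = 1e-10) {
  hit <- which(resp == target)
  if (length(hit)) return(conc[hit[1]])
  fn <- stats::approxfun(conc, resp - target)
  for (i in seq_len(length(conc) - 1L)) {
    if ((resp[i] - target) * (resp[i + 1] - target) < 0)
      return(stats::uniroot(fn, c(conc[i], conc[i + 1]), tol = tol)$root)
  }
  NA_real_
}

# Random strictly monotone curve on a random concentration grid.
random_monotone_curve <- function(increasing = TRUE, n = NULL) {
  if (is.null(n)) n <- sample(4:9, 1)
  conc <- sort(stats::runif(n, 1, 1000))
  steps <- stats::runif(n - 1, 0.05, 1)
  resp <- cumsum(c(stats::runif(1, 0, 10), steps))
  if (!increasing) resp <- rev(resp)
  list(conc = conc, resp = resp)
}

# Wrap a bare (concentration, response) table as a dose_response_curve via
# the public constructor path.
make_curve <- function(conc, resp, kind = "colour_value", sample_id = "s1",
                       unit = "uM", blank = NULL, maxr = NULL) {
  df <- data.frame(sample_id = sample_id, concentration = conc, unit = unit,
                   replicate = 1L, role = "reaction")
  df[[kind]] <- resp
  aggregate_curve(df, kind, max_response = maxr, blank_response = blank)
}

# Small populated layout + noiseless render used by several tests.
demo_plate <- function(noise_sd = 0, seed = 1, true_c50 = 200, n_levels = 9,
                       n_replicates = 3, edge_softness = 2, ...) {
  series <- dilution_series(16 * true_c50, 2, n_levels, "uM")
  layout <- plate_layout(n_replicates, n_levels + 1,
                         origin = c(x = 18, y = 18), pitch_x = 28, pitch_y = 28,
                         spot_radius = 10)
  layout <- layout_to_wells(layout, series, "s1", n_replicates,
                            fill_order = "col-major",
                            n_reagent_blanks = n_replicates)
  model <- scavenging_model(true_c50)
  cfg <- render_config(layout, noise_sd = noise_sd, seed = seed,
                       edge_softness = edge_softness, ...)
  render_plate(model, cfg)
}
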