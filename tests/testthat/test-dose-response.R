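test_that("aggregate_curve computes per-level mean, sample sd and n", {
  df <- data.frame(sample_id = "s1",
                   concentration = c(100, 100, 100, 50, 50, 50, 0),
                   unit = "uM", replicate = c(1:3, 1:3, 1),
                   role = c(rep("reaction", 6), "reagent_blank"),
                   colour_value = c(90, 100, 110, 40, 50, 60, 20))
  curve <- aggregate_curve(df, "colour_value")
  expect_equal(curve$points$concentration, c(50, 100))
  expect_equal(curve$points$response, c(50, 100))
  expect_equal(curve$points$sd, c(10, 10))  # sample sd of (90,100,110) is 10
  expect_equal(curve$points$n, c(3, 3))
  expect_equal(curve$blank_response, 20)
  expect_equal(curve$max_response, 100)
  expect_true(curve$max_response_observed)
})

test_that("aggregate_curve sorts, handles singles, and validates input", {
  df <- data.frame(sample_id = "s1", concentration = c(200, 50),
                   unit = "uM", replicate = 1L, role = "reaction",
                   absorbance = c(0.2, 0.8))
  curve <- aggregate_curve(df, "absorbance")
  expect_equal(curve$points$concentration, c(50, 200))
  expect_equal(curve$points$sd, c(0, 0))
  expect_equal(curve$points$n, c(1, 1))

  one <- df[1, ]
  expect_error(aggregate_curve(one, "absorbance"), class = "dpph_insufficient_data")
  mixed <- df; mixed$unit <- c("uM", "ug/mL")
  expect_error(aggregate_curve(mixed, "absorbance"), class = "dpph_unit_error")
})

test_that("extract-blank correction subtracts the sample's own colour", {
  curve <- make_curve(c(10, 20, 40), c(50, 80, 120), blank = 30)
  # colourless sample: blank equals baseline everywhere -> unchanged
  same <- blank_correct_extract(curve, 200, baseline = 200)
  expect_equal(same$points$response, curve$points$response)
  # constant self-colour 10 grey below... i.e. blank 10 above baseline
  shifted <- blank_correct_extract(curve, 210, baseline = 200)
  expect_equal(shifted$points$response, curve$points$response - 10)
  # per-level blanks: hand-computed subtraction
  eb <- data.frame(concentration = c(10, 20, 40), colour_value = c(202, 205, 211))
  per <- blank_correct_extract(curve, eb, baseline = 200)
  expect_equal(per$points$response, c(50 - 2, 80 - 5, 120 - 11))
  # missing level
  expect_error(blank_correct_extract(curve, eb[-2, ], baseline = 200),
               class = "dpph_missing_blank")
})

test_that("percent_scavenging is the relative absorbance drop", {
  expect_equal(percent_scavenging(1.0, 0.5), 50)
  expect_equal(percent_scavenging(1.0, 1.0), 0)
  expect_equal(percent_scavenging(0.8, 0.0), 100)
  expect_error(percent_scavenging(0, 0.5), class = "dpph_invalid_control")
  # inverse identity over the full range
  p <- seq(0, 100, by = 2.5)
  expect_equal(percent_scavenging(0.9, 0.9 * (1 - p / 100)), p)
})

test_that("sc50_from_absorbance interpolates the A0/2 crossing", {
  curve <- make_curve(c(50, 100), c(0.6, 0.2), kind = "absorbance", blank = 1.0)
  res <- sc50_from_absorbance(curve)
  expect_equal(res$value, 62.5)  # 50 + ((0.6-0.5)/(0.6-0.2)) * 50
  expect_equal(res$status, "ok")
  expect_equal(nrow(res$bracketing_points), 2)

  # exact hit needs no interpolation
  hit <- make_curve(c(40, 80, 160), c(0.9, 0.5, 0.1), kind = "absorbance",
                    blank = 1.0)
  expect_equal(sc50_from_absorbance(hit)$value, 80)

  # all responses above A0/2: censored high, value absent
  cen <- make_curve(c(50, 100), c(0.9, 0.7), kind = "absorbance", blank = 1.0)
  res_c <- sc50_from_absorbance(cen)
  expect_equal(res_c$status, "censored_high")
  expect_true(is.na(res_c$value))

  # all responses below A0/2: crossing happened below the observed range
  lo <- make_curve(c(50, 100), c(0.3, 0.1), kind = "absorbance", blank = 1.0)
  expect_equal(sc50_from_absorbance(lo)$status, "censored_low")

  no_blank <- make_curve(c(50, 100), c(0.6, 0.2), kind = "absorbance")
  expect_error(sc50_from_absorbance(no_blank), class = "dpph_missing_blank")
})

test_that("csc50_halfmax interpolates the colour half-rise", {
  lin <- make_curve(c(0, 100, 200), c(0, 50, 100), blank = 0, maxr = 100)
  expect_equal(csc50_halfmax(lin)$value, 100)

  crv <- make_curve(c(25, 50, 100, 200, 400), c(5, 20, 60, 95, 100),
                    blank = 0, maxr = 100)
  res <- csc50_halfmax(crv)
  expect_equal(res$value, 87.5)  # 50 + ((50-20)/(60-20)) * (100-50)
  expect_equal(res$status, "ok")

  flat <- make_curve(c(10, 20, 40), c(5, 5, 5), blank = 5, maxr = 100)
  expect_equal(csc50_halfmax(flat)$status, "censored_high")

  expect_error(csc50_halfmax(make_curve(c(1, 2), c(3, 4), blank = 10, maxr = 5)),
               class = "dpph_degenerate_range")
})

test_that("status=ok implies the estimate lies inside the observed range", {
  set.seed(51)
  for (i in 1:30) {
    m <- random_monotone_curve(increasing = TRUE)
    blank <- min(m$resp) - runif(1, 0, 1)
    maxr <- max(m$resp) + runif(1, 0, 1)
    res <- csc50_halfmax(make_curve(m$conc, m$resp, blank = blank, maxr = maxr))
    if (res$status == "ok")
      expect_true(res$value >= min(m$conc) && res$value <= max(m$conc))
  }
})

test_that("non-monotone mean curves warn and use the first crossing", {
  crv <- make_curve(c(10, 20, 40, 80), c(10, 60, 40, 90), blank = 0, maxr = 100)
  res <- csc50_halfmax(crv)
  expect_equal(res$status, "non_monotone_warning")
  # first upward crossing of 50 is between 10 and 20
  expect_true(res$value > 10 && res$value < 20)
})

test_that("derivative_curve takes midpoint-assigned forward differences", {
  crv <- make_curve(c(0, 100, 200, 300), c(0, 10, 60, 70))
  dc <- derivative_curve(crv)
  expect_equal(dc$points$concentration, c(50, 150, 250))
  expect_equal(dc$points$slope, c(0.1, 0.5, 0.1))
  expect_equal(nrow(dc$points), nrow(crv$points) - 1)

  # linear curve: constant slope
  lin <- make_curve(c(10, 30, 70, 150), c(5, 15, 35, 75))
  expect_equal(unique(round(derivative_curve(lin)$points$slope, 12)), 0.5)

  expect_error(derivative_curve(make_curve(c(1, 2), c(1, 2))),
               class = "dpph_insufficient_data")
})

test_that("csc50_derivative picks the steepest midpoint and flags ties", {
  crv <- make_curve(c(0, 100, 200, 300), c(0, 10, 60, 70))
  res <- csc50_derivative(crv)
  expect_equal(res$value, 150)
  expect_equal(res$status, "ok")
  expect_equal(unlist(res$bracketing_points[c("c_lo", "c_hi")]),
               c(c_lo = 100, c_hi = 200))

  tie <- make_curve(c(0, 10, 20, 30), c(0, 5, 10, 12))
  res_t <- csc50_derivative(tie)
  expect_equal(res_t$value, 5)   # lower of the two equal-slope midpoints
  expect_equal(res_t$status, "tie_warning")
})

test_that("derivative and half-max agree on dense symmetric logistic data", {
  model <- scavenging_model(500, hill = 1.5, form = "logistic_linear")
  conc <- seq(0, 1000, by = 20)
  resp <- 100 * fraction_scavenged(model, conc)
  crv <- make_curve(conc, resp, blank = 0, maxr = 100)
  h <- csc50_halfmax(crv)$value
  d <- csc50_derivative(crv)$value
  expect_lte(abs(h - d), 20)  # within one grid step
  expect_lte(abs(h - 500), 20)
})

test_that("both interpolators match the uniroot crossing oracle", {
  set.seed(52)
  for (i in 1:25) {
    up <- random_monotone_curve(increasing = TRUE)
    blank <- min(up$resp); maxr <- max(up$resp)
    mine <- csc50_halfmax(make_curve(up$conc, up$resp, blank = blank, maxr = maxr))
    oracle <- uniroot_crossing(up$conc, up$resp, blank + (maxr - blank) / 2)
    expect_equal(mine$value, oracle, tolerance = 1e-7)

    down <- random_monotone_curve(increasing = FALSE)
    a0 <- 2 * max(down$resp) * runif(1, 0.55, 0.9)
    mine2 <- sc50_from_absorbance(make_curve(down$conc, down$resp,
                                             kind = "absorbance", blank = a0))
    oracle2 <- uniroot_crossing(down$conc, down$resp, a0 / 2)
    if (is.na(oracle2)) expect_true(is.na(mine2$value))
    else expect_equal(mine2$value, oracle2, tolerance = 1e-7)
  }
})

test_that("rescaling concentrations rescales both CSC50 estimates alike", {
  crv <- make_curve(c(25, 50, 100, 200, 400), c(5, 20, 60, 95, 100),
                    blank = 0, maxr = 100)
  for (k in c(0.5, 3, 10)) {
    scaled <- make_curve(k * c(25, 50, 100, 200, 400), c(5, 20, 60, 95, 100),
                         blank = 0, maxr = 100)
    expect_equal(csc50_halfmax(scaled)$value, k * csc50_halfmax(crv)$value)
    expect_equal(csc50_derivative(scaled)$value, k * csc50_derivative(crv)$value)
  }
})
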