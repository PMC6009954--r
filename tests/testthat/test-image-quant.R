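grey_img <- function(m) plate_image(m)

test_that("to_grey applies luminance weights with half-up rounding", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)
  px[1, 2, ] <- c(0, 0, 0)
  px[1, 3, ] <- c(255, 0, 0)
  g <- to_grey(plate_image(px))
  # 0.299 * 255 = 76.245 -> 76 after half-up rounding
  expect_equal(as.vector(g$pixels), c(255, 0, 76))
  # idempotent on grey input
  expect_identical(to_grey(g), g)
})

test_that("to_grey matches an independent pixel-wise computation", {
  set.seed(21)
  px <- array(sample(0:255, 12 * 15 * 3, replace = TRUE), dim = c(12, 15, 3))
  g <- to_grey(plate_image(px))
  for (idx in sample(12 * 15, 20)) {
    r <- (idx - 1) %% 12 + 1; cc <- (idx - 1) %/% 12 + 1
    expected <- floor(0.299 * px[r, cc, 1] + 0.587 * px[r, cc, 2] +
                        0.114 * px[r, cc, 3] + 0.5)
    expect_equal(g$pixels[r, cc], expected)
  }
})

test_that("plate_image rejects malformed rasters", {
  expect_error(plate_image(array(0, dim = c(4, 4, 2))),
               class = "dpph_unsupported_image")
  expect_error(plate_image(matrix(-1, 4, 4)), class = "dpph_unsupported_image")
  expect_error(plate_image(matrix(300, 4, 4)), class = "dpph_unsupported_image")
})

test_that("mean_grey_value handles constant and split images", {
  img <- grey_img(matrix(200, 40, 40))
  m <- mean_grey_value(img, c(20, 20), 8)
  expect_equal(m$colour_value, 200)

  # half 0 / half 255 split between columns 20 and 21; ROI centred on the
  # boundary x = 20.5 sees both halves symmetrically
  px <- cbind(matrix(0, 40, 20), matrix(255, 40, 20))
  m2 <- mean_grey_value(grey_img(px), c(20.5, 20), 8)
  expect_equal(m2$colour_value, 127.5)
})

test_that("mean_grey_value equals the brute-force pixel-loop mean", {
  set.seed(31)
  for (i in 1:20) {
    h <- sample(25:45, 1); w <- sample(25:45, 1)
    px <- matrix(sample(0:255, h * w, replace = TRUE), h, w)
    radius <- runif(1, 2, 8)
    cx <- runif(1, radius + 1, w - radius)
    cy <- runif(1, radius + 1, h - radius)
    fast <- mean_grey_value(grey_img(px), c(cx, cy), radius)
    slow <- brute_force_disc_mean(px, cx, cy, radius)
    expect_identical(fast$n_pixels, slow$n_pixels)
    expect_identical(fast$colour_value, slow$colour_value)
  }
})

test_that("mean_grey_value is translation invariant and shift-linear", {
  set.seed(32)
  px <- matrix(sample(0:200, 30 * 30, replace = TRUE), 30, 30)
  big <- matrix(0, 60, 60)
  big[1:30, 1:30] <- px
  big[21:50, 25:54] <- px  # translated copy
  a <- mean_grey_value(grey_img(big), c(15, 15), 6)
  b <- mean_grey_value(grey_img(big), c(15 + 24, 15 + 20), 6)
  expect_equal(b$colour_value, a$colour_value)
  expect_equal(b$n_pixels, a$n_pixels)

  # brightening every pixel by +k moves the mean by exactly +k (no clipping)
  k <- 40
  a2 <- mean_grey_value(grey_img(pmin(big + k, 255)), c(15, 15), 6)
  expect_equal(a2$colour_value, a$colour_value + k)
})

test_that("out-of-bounds ROIs are rejected", {
  img <- grey_img(matrix(100, 20, 20))
  expect_error(mean_grey_value(img, c(3, 10), 5), class = "dpph_roi_error")
  expect_error(mean_grey_value(img, c(10, 19), 5), class = "dpph_roi_error")
})

test_that("refine_spot_centres recovers exact and shifted spot positions", {
  plate <- demo_plate(noise_sd = 0)
  ref <- refine_spot_centres(plate$image, plate$layout)
  nom <- spot_centres(plate$layout)
  on_grid <- !ref$fallback
  expect_true(any(on_grid))
  expect_true(all(abs(ref$x[on_grid] - nom$x[on_grid]) <= 0.5))
  expect_true(all(abs(ref$y[on_grid] - nom$y[on_grid]) <= 0.5))

  # shift every spot by (+3, -2): render on a layout whose origin is offset,
  # quantify against the nominal grid
  true_layout <- plate$layout
  shifted <- true_layout
  shifted$origin <- c(x = true_layout$origin[["x"]] + 3,
                      y = true_layout$origin[["y"]] - 2)
  model <- scavenging_model(200)
  cfg <- render_config(shifted, noise_sd = 0, seed = 1)
  img <- render_plate(model, cfg)$image
  ref2 <- refine_spot_centres(img, true_layout, search_radius = 5)
  ok <- !ref2$fallback
  expect_true(mean(ok) > 0.7)  # fully faded spots legitimately fall back
  expect_true(all(abs(ref2$x[ok] - (nom$x[ok] + 3)) <= 1))
  expect_true(all(abs(ref2$y[ok] - (nom$y[ok] - 2)) <= 1))
})

test_that("refinement on a featureless image falls back to nominal centres", {
  layout <- demo_plate()$layout
  img <- grey_img(matrix(180, 200, 400))
  ref <- refine_spot_centres(img, layout)
  expect_true(all(ref$fallback))
  nom <- spot_centres(layout)
  expect_equal(ref$x, nom$x)
  expect_equal(ref$y, nom$y)
})

test_that("quantify_plate round-trips the simulator ground truth", {
  plate <- demo_plate(noise_sd = 0)
  meas <- quantify_plate(plate$image, plate$layout, refine = FALSE)
  expect_equal(nrow(meas), nrow(plate$truth))
  expect_true(all(abs(meas$colour_value - plate$truth$true_mean_grey) <= 0.5))
})

test_that("quantify_plate propagates ROI errors with the well named", {
  plate <- demo_plate(noise_sd = 0)
  crop <- plate_image(plate$image$pixels[, 1:30])
  expect_error(quantify_plate(crop, plate$layout, refine = FALSE),
               "row .*, col ", class = "dpph_roi_error")
})

test_that("quantify_plate on an empty layout returns an empty table", {
  img <- grey_img(matrix(100, 50, 50))
  empty <- plate_layout(2, 2, pitch_x = 20, pitch_y = 20, spot_radius = 5)
  out <- quantify_plate(img, empty)
  expect_s3_class(out, "spot_measurements")
  expect_equal(nrow(out), 0)
})

test_that("PNG image round-trip is exact; JPEG close", {
  set.seed(41)
  px <- matrix(sample(0:255, 50 * 60, replace = TRUE), 50, 60)
  p_png <- withr::local_tempfile(fileext = ".png")
  write_plate_image(plate_image(px), p_png)
  back <- read_plate_image(p_png)
  expect_equal(back$pixels, px)

  smooth <- matrix(round(seq(40, 210, length.out = 50)), 50, 60)
  p_jpg <- withr::local_tempfile(fileext = ".jpg")
  write_plate_image(plate_image(smooth), p_jpg)
  backj <- read_plate_image(p_jpg)
  expect_lt(mean(abs(backj$pixels - smooth)), 2)

  expect_error(read_plate_image("missing.png"), class = "dpph_io_error")
  p_tif <- withr::local_tempfile(fileext = ".tiff")
  file.create(p_tif)
  expect_error(read_plate_image(p_tif), class = "dpph_unsupported_image")
})
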