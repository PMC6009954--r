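# Image quantification: greyscale conversion, circular-ROI mean grey value,
# grid-constrained spot-centre refinement.

#' Plate image container
#'
#' Holds an 8-bit raster as stored integers: a numeric matrix (greyscale,
#' values 0..255, matrix cell `[r, c]` = pixel centred at `(x = c, y = r)`)
#' or an H x W x 3 array (RGB).
#'
#' @param pixels Numeric matrix or H x W x 3 array with values in 0..255.
#' @param source_path Optional provenance string.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, source_path = NA_character_) {
  if (is.array(pixels) && length(dim(pixels)) == 3L) {
    if (dim(pixels)[3] != 3L)
      dpph_error("multi-channel images must have exactly 3 (RGB) channels",
                 "dpph_unsupported_image")
  } else if (!is.matrix(pixels)) {
    dpph_error("pixels must be a matrix (grey) or H x W x 3 array (RGB)",
               "dpph_unsupported_image")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
    dpph_error("pixel values must lie in [0, 255]", "dpph_unsupported_image")
  structure(list(pixels = pixels,
                 width = ncol_img(pixels), height = nrow_img(pixels),
                 source_path = source_path),
            class = "plate_image")
}

nrow_img <- function(p) dim(p)[1]
ncol_img <- function(p) dim(p)[2]

is_grey_image <- function(image) is.matrix(image$pixels)

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px, %s%s\n", x$width, x$height,
              if (is_grey_image(x)) "greyscale" else "RGB",
              if (is.na(x$source_path)) "" else paste0(", from ", x$source_path)))
  invisible(x)
}

#' Read / write a plate image
#'
#' Supports 8-bit PNG and JPEG. Decoded channel values are mapped back to
#' stored 0..255 integers (exact for PNG). An alpha channel, if present, is
#' dropped. TIFF is not supported in this build (no TIFF codec available);
#' requesting it raises an unsupported-format error.
#'
#' @param path Image file path; format chosen by extension.
#' @return A [plate_image()].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path))
    dpph_error(paste("image file not found:", path), "dpph_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    tif = ,
    tiff = dpph_error("TIFF is not supported in this build; convert to PNG",
                      "dpph_unsupported_image"),
    dpph_error(paste0("unsupported image format '.", ext, "' (use PNG or JPEG)"),
               "dpph_unsupported_image"))
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] >= 4L) raw <- raw[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(raw)[3] == 1L) raw <- raw[, , 1]
    if (length(dim(raw)) == 3L && dim(raw)[3] == 2L) raw <- raw[, , 1]  # grey+alpha
  }
  plate_image(round_half_up(raw * 255), source_path = path)
}

#' @param image A [plate_image()].
#' @param force Overwrite an existing file.
#' @rdname read_plate_image
#' @export
write_plate_image <- function(image, path, force = FALSE) {
  check_overwrite(path, force)
  ext <- tolower(tools::file_ext(path))
  v <- image$pixels / 255
  switch(ext,
    png = png::writePNG(v, target = path),
    jpg = ,
    jpeg = jpeg::writeJPEG(v, target = path, quality = 0.95),
    dpph_error(paste0("unsupported output format '.", ext, "' (use PNG or JPEG)"),
               "dpph_unsupported_image"))
  invisible(path)
}

#' Convert an image to greyscale
#'
#' RGB is collapsed with the standard luminance weights
#' `0.299 R + 0.587 G + 0.114 B` and rounded half-up to an integer grey in
#' 0..255 — the same stored-integer greys a typical image-analysis tool
#' averages. Greyscale input is returned unchanged (idempotent).
#'
#' @param image A [plate_image()].
#' @return A greyscale [plate_image()].
#' @export
to_grey <- function(image) {
  if (!inherits(image, "plate_image"))
    dpph_error("expected a plate_image", "dpph_unsupported_image")
  if (is_grey_image(image)) return(image)
  p <- image$pixels
  g <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  dim(g) <- dim(p)[1:2]  # single-row/column slices drop to vectors
  plate_image(clip255(round_half_up(g)), source_path = image$source_path)
}

# Logical disc mask over a bounding box; pixel-centre-in-disc membership.
# Returns list(rows, cols, mask) where mask is over the box grid.
disc_mask <- function(centre_x, centre_y, radius, width, height) {
  r0 <- max(1L, as.integer(ceiling(centre_y - radius)))
  r1 <- min(height, as.integer(floor(centre_y + radius)))
  c0 <- max(1L, as.integer(ceiling(centre_x - radius)))
  c1 <- min(width, as.integer(floor(centre_x + radius)))
  rows <- r0:r1; cols <- c0:c1
  m <- outer((rows - centre_y)^2, (cols - centre_x)^2, "+") <= radius^2
  list(rows = rows, cols = cols, mask = m)
}

#' Mean grey value of a circular region of interest
#'
#' The spot's "colour value": the arithmetic mean of all pixels whose centre
#' lies within Euclidean distance `radius` of `centre`. Membership is
#' pixel-centre-in-disc with no partial-pixel weighting, so `n_pixels` is a
#' reproducible integer count.
#'
#' @param image A greyscale [plate_image()].
#' @param centre Numeric `c(x, y)` in pixel coordinates (may be fractional).
#' @param radius ROI radius in pixels (> 0). The full disc must lie inside
#'   the image.
#' @return List with `colour_value` (mean grey, in \[0, 255\]) and `n_pixels`.
#' @export
mean_grey_value <- function(image, centre, radius) {
  if (!is_grey_image(image))
    dpph_error("mean_grey_value needs a greyscale image; call to_grey() first",
               "dpph_unsupported_image")
  cx <- unname(centre[1]); cy <- unname(centre[2])
  if (!is_number(cx) || !is_number(cy) || !is_number(radius) || radius <= 0)
    dpph_error("centre must be finite c(x, y) and radius > 0", "dpph_roi_error")
  if (cx - radius < 0.5 || cx + radius > image$width + 0.5 ||
      cy - radius < 0.5 || cy + radius > image$height + 0.5)
    dpph_error(sprintf("ROI (centre %.1f, %.1f, radius %.1f) exceeds image bounds %d x %d",
                       cx, cy, radius, image$width, image$height),
               "dpph_roi_error")
  d <- disc_mask(cx, cy, radius, image$width, image$height)
  vals <- image$pixels[d$rows, d$cols, drop = FALSE][d$mask]
  if (length(vals) == 0L)
    dpph_error("ROI contains no pixel centres", "dpph_roi_error")
  list(colour_value = mean(vals), n_pixels = length(vals))
}

#' Refine spot centres against the image
#'
#' For each assigned well, the nominal grid centre is moved to the
#' darkness-weighted centroid of the strongest dark deviations within a
#' square search window: with `b` a high-quantile background estimate of the
#' window, pixels with deviation `b - g` of at least half the maximum
#' deviation are averaged, weighted by their deviation. The refined centre
#' never moves farther than `search_radius`; wells with no usable contrast
#' (maximum deviation below `min_contrast`) keep the nominal centre and are
#' flagged. Spots are assumed darker than their local background, the
#' polarity of an unscavenged DPPH drop on a pale plate.
#'
#' @param image A greyscale [plate_image()].
#' @param layout A [plate_layout()] with wells assigned.
#' @param search_radius Half-width of the search window in pixels; must be
#'   less than half the smaller pitch. Default: `spot_radius / 2`.
#' @param min_contrast Minimum dark deviation (grey levels) to accept.
#' @return Data frame `row, col, x, y, fallback` (one line per well;
#'   `fallback` is `TRUE` where no contrast was found).
#' @export
refine_spot_centres <- function(image, layout, search_radius = NULL,
                                min_contrast = 2) {
  if (!is_grey_image(image)) image <- to_grey(image)
  if (is.null(search_radius)) search_radius <- layout$spot_radius / 2
  if (search_radius >= min(layout$pitch_x, layout$pitch_y) / 2)
    dpph_error("search_radius must be < min pitch / 2", "dpph_invalid_parameter")
  nom <- spot_centres(layout)
  out <- nom
  out$fallback <- FALSE
  # window covers the whole spot but never reaches a neighbour's centre
  half <- min(layout$spot_radius + search_radius,
              min(layout$pitch_x, layout$pitch_y) / 2 - 0.5)
  for (i in seq_len(nrow(nom))) {
    cx <- nom$x[i]; cy <- nom$y[i]
    r0 <- max(1L, as.integer(ceiling(cy - half)))
    r1 <- min(image$height, as.integer(floor(cy + half)))
    c0 <- max(1L, as.integer(ceiling(cx - half)))
    c1 <- min(image$width, as.integer(floor(cx + half)))
    win <- image$pixels[r0:r1, c0:c1, drop = FALSE]
    bg <- stats::quantile(win, 0.9, names = FALSE)
    dev <- bg - win
    dmax <- max(dev)
    if (!is.finite(dmax) || dmax < min_contrast) {
      out$fallback[i] <- TRUE
      next
    }
    keep <- dev >= dmax / 2
    w <- dev * keep
    xs <- matrix(c0:c1, nrow = nrow(win), ncol = ncol(win), byrow = TRUE)
    ys <- matrix(r0:r1, nrow = nrow(win), ncol = ncol(win))
    nx <- sum(w * xs) / sum(w)
    ny <- sum(w * ys) / sum(w)
    # clamp the displacement to the search radius
    dx <- nx - cx; dy <- ny - cy
    dist <- sqrt(dx^2 + dy^2)
    if (dist > search_radius) {
      s <- search_radius / dist
      nx <- cx + dx * s; ny <- cy + dy * s
    }
    out$x[i] <- nx; out$y[i] <- ny
  }
  out
}

#' Quantify every assigned spot on a plate image
#'
#' The plate-level driver: converts to greyscale, optionally refines spot
#' centres, and measures the mean grey value of each well's circular ROI.
#'
#' @param image A [plate_image()] (RGB or greyscale).
#' @param layout A [plate_layout()] with wells assigned.
#' @param refine Refine centres with [refine_spot_centres()] before measuring.
#' @param search_radius Passed to [refine_spot_centres()].
#' @return A `spot_measurements` data frame with columns `sample_id,
#'   concentration, unit, replicate, role, row, col, centre_x, centre_y,
#'   radius, n_pixels, colour_value`, one row per well.
#' @export
quantify_plate <- function(image, layout, refine = TRUE, search_radius = NULL) {
  grey <- to_grey(image)
  wells <- layout$wells
  if (nrow(wells) == 0L) return(empty_measurements())
  centres <- if (isTRUE(refine))
    refine_spot_centres(grey, layout, search_radius)
  else spot_centres(layout)
  res <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    m <- tryCatch(
      mean_grey_value(grey, c(centres$x[i], centres$y[i]), layout$spot_radius),
      dpph_roi_error = function(e)
        dpph_error(sprintf("well (row %d, col %d): %s",
                           wells$row[i], wells$col[i], conditionMessage(e)),
                   "dpph_roi_error"))
    res[[i]] <- data.frame(
      sample_id = wells$sample_id[i], concentration = wells$concentration[i],
      unit = wells$unit[i], replicate = wells$replicate[i], role = wells$role[i],
      row = wells$row[i], col = wells$col[i],
      centre_x = centres$x[i], centre_y = centres$y[i],
      radius = layout$spot_radius, n_pixels = m$n_pixels,
      colour_value = m$colour_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  class(out) <- c("spot_measurements", "data.frame")
  out
}

empty_measurements <- function() {
  out <- data.frame(sample_id = character(), concentration = numeric(),
                    unit = character(), replicate = integer(), role = character(),
                    row = integer(), col = integer(), centre_x = numeric(),
                    centre_y = numeric(), radius = numeric(),
                    n_pixels = integer(), colour_value = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("spot_measurements", "data.frame")
  out
}
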