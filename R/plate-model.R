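# Domain types: plate geometry, dilution ladders, well assignments.

#' Describe the spot grid of a scanned plate
#'
#' A plate layout fixes where spot centres sit in image pixel coordinates:
#' an `n_rows` by `n_cols` grid whose first spot centre is at `origin`, with
#' `pitch_x`/`pitch_y` pixels between adjacent centres and a circular region
#' of interest of `spot_radius` pixels per spot. Pixel coordinates follow the
#' raster convention: x runs along columns, y along rows, and the pixel in
#' matrix cell `[r, c]` has centre `(x = c, y = r)`.
#'
#' @param n_rows,n_cols Grid dimensions (counts, >= 1).
#' @param origin Numeric `c(x, y)`: centre of the spot at grid cell (1, 1).
#' @param pitch_x,pitch_y Pixels between adjacent spot centres (> 0).
#' @param spot_radius Radius in pixels of the circular ROI (>= 1). ROIs must
#'   not overlap: `2 * spot_radius < min(pitch_x, pitch_y)`.
#' @param wells Optional well-assignment data frame as produced by
#'   [layout_to_wells()], with columns `row, col, sample_id, concentration,
#'   unit, replicate, role`.
#' @return An object of class `plate_layout`.
#' @seealso [layout_to_wells()], [spot_centres()], [write_plate_layout()]
#' @export
plate_layout <- function(n_rows, n_cols, origin = c(x = 24, y = 24),
                         pitch_x = 40, pitch_y = 40, spot_radius = 12,
                         wells = NULL) {
  if (!is_count(n_rows) || !is_count(n_cols))
    dpph_error("n_rows and n_cols must be integers >= 1", "dpph_invalid_parameter")
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin)))
    dpph_error("origin must be numeric c(x, y)", "dpph_invalid_parameter")
  if (!is_number(pitch_x) || !is_number(pitch_y) || pitch_x <= 0 || pitch_y <= 0)
    dpph_error("pitches must be positive", "dpph_invalid_parameter")
  if (!is_number(spot_radius) || spot_radius < 1)
    dpph_error("spot_radius must be >= 1 pixel", "dpph_invalid_parameter")
  if (2 * spot_radius >= min(pitch_x, pitch_y))
    dpph_error("ROIs overlap: need 2*spot_radius < min(pitch_x, pitch_y)",
               "dpph_invalid_parameter")
  layout <- structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         origin = c(x = unname(origin[1]), y = unname(origin[2])),
         pitch_x = pitch_x, pitch_y = pitch_y, spot_radius = spot_radius,
         wells = empty_wells()),
    class = "plate_layout")
  if (!is.null(wells)) layout$wells <- validate_wells(wells, layout)
  layout
}

empty_wells <- function() {
  data.frame(row = integer(), col = integer(), sample_id = character(),
             concentration = numeric(), unit = character(),
             replicate = integer(), role = character(),
             stringsAsFactors = FALSE)
}

validate_wells <- function(wells, layout) {
  need <- c("row", "col", "sample_id", "concentration", "unit", "replicate", "role")
  miss <- setdiff(need, names(wells))
  if (length(miss))
    dpph_error(paste("well table missing column(s):", paste(miss, collapse = ", ")),
               "dpph_schema_error")
  wells <- wells[need]
  wells$row <- as.integer(wells$row); wells$col <- as.integer(wells$col)
  wells$replicate <- as.integer(wells$replicate)
  wells$sample_id <- as.character(wells$sample_id)
  wells$unit <- as.character(wells$unit)
  wells$role <- as.character(wells$role)
  if (any(wells$row < 1 | wells$row > layout$n_rows |
          wells$col < 1 | wells$col > layout$n_cols))
    dpph_error("well assignment outside the grid", "dpph_layout_error")
  if (anyDuplicated(wells[c("row", "col")]))
    dpph_error("duplicate well assignment at one grid cell", "dpph_layout_error")
  if (any(!wells$role %in% well_roles))
    dpph_error(paste0("unknown role '", setdiff(wells$role, well_roles)[1],
                      "'; valid roles: ", paste(well_roles, collapse = ", ")),
               "dpph_schema_error")
  if (any(!is.finite(wells$concentration)) || any(wells$concentration < 0))
    dpph_error("concentrations must be finite and >= 0", "dpph_invalid_parameter")
  rownames(wells) <- NULL
  wells
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %d x %d grid, pitch (%g, %g) px, spot radius %g px\n",
              x$n_rows, x$n_cols, x$pitch_x, x$pitch_y, x$spot_radius))
  cat(sprintf("  origin (%g, %g); %d well(s) assigned\n",
              x$origin[["x"]], x$origin[["y"]], nrow(x$wells)))
  invisible(x)
}

#' Pixel coordinates of spot centres
#'
#' @param layout A [plate_layout()].
#' @param rows,cols Grid indices (vectorised, recycled); default all assigned
#'   wells, or the full grid when no wells are assigned.
#' @return Data frame with columns `row, col, x, y`.
#' @export
spot_centres <- function(layout, rows = NULL, cols = NULL) {
  if (is.null(rows) || is.null(cols)) {
    if (nrow(layout$wells) > 0L) {
      rows <- layout$wells$row; cols <- layout$wells$col
    } else {
      g <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
      rows <- g$row; cols <- g$col
    }
  }
  data.frame(row = as.integer(rows), col = as.integer(cols),
             x = layout$origin[["x"]] + (cols - 1) * layout$pitch_x,
             y = layout$origin[["y"]] + (rows - 1) * layout$pitch_y)
}

#' Serial-dilution concentration ladder
#'
#' Level `k` (k = 0 .. `n_levels` - 1) has concentration `top / factor^k`.
#' A "1:1" serial dilution in assay parlance is `factor = 2`: each level is
#' an equal-volume mix of the previous level and solvent.
#'
#' @param top Highest concentration (> 0), in `unit`.
#' @param factor Dilution factor between adjacent levels (> 1).
#' @param n_levels Number of levels (>= 2).
#' @return Numeric vector of `n_levels` strictly decreasing concentrations.
#' @examples
#' build_serial_dilution(3000, 2, 9)  # the classic two-fold nine-step ladder
#' @export
build_serial_dilution <- function(top, factor = 2, n_levels = 9) {
  if (!is_number(top) || top <= 0)
    dpph_error("top concentration must be > 0", "dpph_invalid_parameter")
  if (!is_number(factor) || factor <= 1)
    dpph_error("dilution factor must be > 1", "dpph_invalid_parameter")
  if (!is_count(n_levels) || n_levels < 2)
    dpph_error("n_levels must be an integer >= 2", "dpph_invalid_parameter")
  top / factor^(seq_len(n_levels) - 1)
}

#' Dilution-series descriptor
#'
#' Bundles the ladder parameters with their unit. Units are opaque labels
#' (e.g. `"uM"`, `"ug/mL"`); no conversion is attempted, and mixing units
#' within one curve is an error downstream.
#'
#' @inheritParams build_serial_dilution
#' @param unit Concentration unit label.
#' @return An object of class `dilution_series` with a `concentrations` field.
#' @export
dilution_series <- function(top, factor = 2, n_levels = 9, unit = "uM") {
  structure(list(top_concentration = top, dilution_factor = factor,
                 n_levels = as.integer(n_levels), unit = as.character(unit),
                 concentrations = build_serial_dilution(top, factor, n_levels)),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> %g %s, 1/%g per step, %d levels\n",
              x$top_concentration, x$unit, x$dilution_factor, x$n_levels))
  invisible(x)
}

#' Assign a dilution ladder to grid cells
#'
#' Places `n_levels * n_replicates` reaction wells, then `n_reagent_blanks`
#' reagent-blank wells (concentration 0), then, if requested, one
#' extract-blank well per level, onto the grid in `fill_order`. Levels are
#' enumerated from the top concentration down, replicates adjacent, so a
#' row-major fill mirrors the usual bench arrangement of triplicate drops.
#'
#' @param layout A [plate_layout()] (existing wells are replaced).
#' @param series A [dilution_series()].
#' @param sample_id Sample identifier recorded in every assignment.
#' @param n_replicates Replicates per concentration (>= 1).
#' @param fill_order `"row-major"` (default) or `"col-major"`.
#' @param n_reagent_blanks Reagent-blank wells to append (concentration 0).
#' @param include_extract_blanks Add one sample+solvent blank per level.
#' @return The layout with its `wells` table populated.
#' @export
layout_to_wells <- function(layout, series, sample_id, n_replicates = 3,
                            fill_order = c("row-major", "col-major"),
                            n_reagent_blanks = 0, include_extract_blanks = FALSE) {
  fill_order <- match.arg(fill_order)
  if (!is_count(n_replicates))
    dpph_error("n_replicates must be an integer >= 1", "dpph_invalid_parameter")
  conc <- series$concentrations
  n_lv <- length(conc)
  asg <- data.frame(
    sample_id = sample_id,
    concentration = rep(conc, each = n_replicates),
    unit = series$unit,
    replicate = rep(seq_len(n_replicates), times = n_lv),
    role = "reaction", stringsAsFactors = FALSE)
  if (n_reagent_blanks > 0)
    asg <- rbind(asg, data.frame(sample_id = sample_id, concentration = 0,
                                 unit = series$unit,
                                 replicate = seq_len(n_reagent_blanks),
                                 role = "reagent_blank"))
  if (isTRUE(include_extract_blanks))
    asg <- rbind(asg, data.frame(sample_id = sample_id, concentration = conc,
                                 unit = series$unit, replicate = 1L,
                                 role = "extract_blank"))
  capacity <- layout$n_rows * layout$n_cols
  if (nrow(asg) > capacity)
    dpph_error(sprintf("layout capacity exceeded: %d assignments on a %d x %d grid",
                       nrow(asg), layout$n_rows, layout$n_cols),
               "dpph_layout_error")
  cells <- if (fill_order == "row-major") {
    g <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
    g[order(g$row, g$col), c("row", "col")]
  } else {
    g <- expand.grid(row = seq_len(layout$n_rows), col = seq_len(layout$n_cols))
    g[order(g$col, g$row), c("row", "col")]
  }
  cells <- cells[seq_len(nrow(asg)), , drop = FALSE]
  wells <- cbind(cells, asg)
  layout$wells <- validate_wells(wells, layout)
  layout
}

#' Assay-protocol metadata
#'
#' Records the wet-lab constants of the assay run. These are provenance
#' metadata only; no computation in the pipeline depends on them. Defaults
#' are the standard protocol: 2000 uM methanolic DPPH, 15 uL drops, 60 min
#' incubation, 1/20 post-incubation dilution for the spectrophotometric
#' branch, absorbance read at 517 nm.
#'
#' @param dpph_concentration DPPH working concentration, uM.
#' @param drop_volume Volume dropped per spot, uL.
#' @param incubation_minutes Incubation time before reading, minutes.
#' @param post_incubation_dilution Dilution ratio before absorbance reading.
#' @param wavelength Absorbance wavelength, nm.
#' @return An object of class `assay_protocol`.
#' @export
assay_protocol <- function(dpph_concentration = 2000, drop_volume = 15,
                           incubation_minutes = 60,
                           post_incubation_dilution = 1 / 20,
                           wavelength = 517) {
  vals <- c(dpph_concentration, drop_volume, incubation_minutes,
            post_incubation_dilution, wavelength)
  if (any(!is.finite(vals)) || any(vals <= 0))
    dpph_error("all protocol constants must be positive", "dpph_invalid_parameter")
  structure(list(dpph_concentration = dpph_concentration,
                 drop_volume = drop_volume,
                 incubation_minutes = incubation_minutes,
                 post_incubation_dilution = post_incubation_dilution,
                 wavelength = wavelength),
            class = "assay_protocol")
}

# ---- layout file format (JSON, versioned) ----

LAYOUT_FORMAT_VERSION <- "1.0"

#' Write / read a plate layout file
#'
#' The layout file is JSON with a `format_version` key, the geometry fields
#' of [plate_layout()], and a `wells` array. Round-trips are exact at double
#' precision.
#'
#' @param layout A [plate_layout()].
#' @param path File path (`.json`).
#' @param force Overwrite an existing file.
#' @return `write_plate_layout()` returns `path` invisibly;
#'   `read_plate_layout()` returns a [plate_layout()].
#' @export
write_plate_layout <- function(layout, path, force = FALSE) {
  check_overwrite(path, force)
  obj <- list(format_version = LAYOUT_FORMAT_VERSION,
              n_rows = layout$n_rows, n_cols = layout$n_cols,
              origin = list(x = layout$origin[["x"]], y = layout$origin[["y"]]),
              pitch_x = layout$pitch_x, pitch_y = layout$pitch_y,
              spot_radius = layout$spot_radius,
              wells = layout$wells)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_plate_layout
#' @export
read_plate_layout <- function(path) {
  if (!file.exists(path))
    dpph_error(paste("layout file not found:", path), "dpph_io_error")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version))
    dpph_error("layout file lacks format_version", "dpph_schema_error")
  wells <- if (is.data.frame(obj$wells) && nrow(obj$wells) > 0) obj$wells else NULL
  plate_layout(obj$n_rows, obj$n_cols,
               origin = c(x = obj$origin$x, y = obj$origin$y),
               pitch_x = obj$pitch_x, pitch_y = obj$pitch_y,
               spot_radius = obj$spot_radius, wells = wells)
}

check_overwrite <- function(path, force) {
  if (file.exists(path) && !isTRUE(force))
    dpph_error(paste0("refusing to overwrite '", path, "' (use force = TRUE / --force)"),
               "dpph_io_error")
  invisible(TRUE)
}
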