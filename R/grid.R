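#' Gridded daily temperature field
#'
#' A light container for a lon x lat x [depth] x time temperature array
#' with land masked as `NA`, plus per-cell horizontal areas. Cell centres
#' are given by `lon`/`lat`; `depth` (positive down, metres) is optional
#' and, when present, is accompanied by layer interfaces so that
#' depth averaging can weight by layer thickness.
#'
#' @param lon,lat Numeric vectors of cell-centre coordinates, degrees
#'   east / north, strictly increasing.
#' @param time Vector of daily dates (`Date` or coercible).
#' @param values Numeric array, `lon x lat x time` or
#'   `lon x lat x depth x time`, degrees C, `NA` over land (the mask must
#'   not change over time).
#' @param depth Optional numeric vector of layer mid-depths, metres,
#'   increasing.
#' @param depth_bounds Optional numeric vector of `length(depth) + 1` layer
#'   interfaces starting at the surface; defaults to interfaces midway
#'   between successive mid-depths, starting at 0.
#' @param cell_area Optional `lon x lat` matrix of cell areas, km^2. When
#'   omitted, areas are computed for a regular spherical grid as
#'   R^2 dlambda dphi cos(lat) with R = 6371.0088 km.
#' @param units Temperature units; only `"degC"` is supported.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(lon, lat, time, values, depth = NULL,
                          depth_bounds = NULL, cell_area = NULL,
                          units = "degC") {
  if (!identical(units, "degC")) {
    abort(sprintf('Unsupported temperature units "%s": expected "degC".', units))
  }
  lon <- as.numeric(lon); lat <- as.numeric(lat)
  if (is.unsorted(lon, strictly = TRUE) || is.unsorted(lat, strictly = TRUE)) {
    abort("`lon` and `lat` must be strictly increasing cell-centre vectors.")
  }
  time <- as.Date(time)
  expected <- if (is.null(depth)) {
    c(length(lon), length(lat), length(time))
  } else {
    c(length(lon), length(lat), length(depth), length(time))
  }
  if (!identical(dim(values), as.integer(expected))) {
    abort(sprintf("`values` must have dim [%s]; got [%s].",
                  paste(expected, collapse = ", "),
                  paste(dim(values), collapse = ", ")))
  }
  if (any(is.infinite(values))) abort("`values` must be finite or NA (land).")
  if (!is.null(depth)) {
    depth <- as.numeric(depth)
    if (is.unsorted(depth, strictly = TRUE) || any(depth < 0)) {
      abort("`depth` must be increasing and non-negative (metres, positive down).")
    }
    if (is.null(depth_bounds)) {
      inner <- if (length(depth) > 1) (head(depth, -1) + tail(depth, -1)) / 2 else numeric()
      bottom <- if (length(depth) > 1) {
        tail(depth, 1) + (tail(depth, 1) - tail(inner, 1))
      } else 2 * depth
      depth_bounds <- c(0, inner, bottom)
    }
    if (length(depth_bounds) != length(depth) + 1L || is.unsorted(depth_bounds, strictly = TRUE)) {
      abort("`depth_bounds` must be an increasing vector of length(depth) + 1.")
    }
  }
  if (is.null(cell_area)) cell_area <- spherical_cell_area(lon, lat)
  if (!identical(dim(cell_area), c(length(lon), length(lat)))) {
    abort("`cell_area` must be a lon x lat matrix.")
  }
  structure(
    list(lon = lon, lat = lat, depth = depth, depth_bounds = depth_bounds,
         time = time, values = values, cell_area = cell_area, units = units),
    class = "gridded_field"
  )
}

# Areas of regular lon/lat cells on a sphere, km^2
spherical_cell_area <- function(lon, lat, radius_km = 6371.0088) {
  dlam <- if (length(lon) > 1) stats::median(diff(lon)) else 1
  dphi <- if (length(lat) > 1) stats::median(diff(lat)) else 1
  area_lat <- radius_km^2 * (dlam * pi / 180) * (dphi * pi / 180) * cos(lat * pi / 180)
  matrix(rep(area_lat, each = length(lon)), nrow = length(lon))
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field> %d lon x %d lat%s x %d days (%s to %s)\n",
              length(x$lon), length(x$lat),
              if (is.null(x$depth)) "" else sprintf(" x %d depths", length(x$depth)),
              length(x$time), min(x$time), max(x$time)))
  sea <- sum(!is.na(first_slice(x)))
  cat(sprintf("  sea cells: %d / %d; temperature %s\n",
              sea, length(x$lon) * length(x$lat), x$units))
  invisible(x)
}

first_slice <- function(field) {
  if (is.null(field$depth)) field$values[, , 1] else field$values[, , 1, 1]
}

#' Monthly warming increments for a delta-method scenario
#'
#' Holds the month-of-year temperature increments (degrees C) added to a
#' present-day daily field to construct a future scenario. Adding a
#' per-month constant preserves the daily anomalies within each month,
#' retaining the temporal resolution and variability of the present-day
#' data — the delta method.
#'
#' @param lon,lat Cell-centre vectors matching the target field.
#' @param values Numeric `lon x lat x 12` array of increments, degrees C,
#'   finite on sea cells.
#' @return An object of class `scenario_delta`.
#' @export
scenario_delta <- function(lon, lat, values) {
  if (!identical(dim(values), c(length(lon), length(lat), 12L))) {
    abort("`values` must be a lon x lat x 12 array.")
  }
  if (any(is.infinite(values))) abort("Delta values must be finite or NA.")
  structure(list(lon = as.numeric(lon), lat = as.numeric(lat), values = values),
            class = "scenario_delta")
}

#' @export
print.scenario_delta <- function(x, ...) {
  cat(sprintf("<scenario_delta> %d x %d x 12 months; range [%.2f, %.2f] degC\n",
              length(x$lon), length(x$lat),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Depth-average a temperature field over the upper water column
#'
#' Thickness-weighted mean over the layers lying (at least partly) above
#' `z_max` metres; layers straddling `z_max` contribute only the part above
#' it. Cells whose water column is shallower than `z_max` average their
#' existing layers. The habitat projections use the 0-30 m average, the
#' depth range the two species occupy.
#'
#' @param field A [gridded_field()] with a depth axis.
#' @param z_max Averaging depth, metres (default 30).
#' @return A 2-D x time [gridded_field()] (no depth axis).
#' @export
depth_average_temperature <- function(field, z_max = 30) {
  stopifnot(inherits(field, "gridded_field"))
  if (is.null(field$depth)) abort("Field has no depth axis.")
  top <- head(field$depth_bounds, -1)
  bottom <- tail(field$depth_bounds, -1)
  w <- pmax(0, pmin(bottom, z_max) - top)
  use <- which(w > 0)
  if (!length(use)) abort(sprintf("No layers above z_max = %g m.", z_max))
  d <- dim(field$values)
  out <- array(0, dim = d[c(1, 2, 4)])
  wsum <- 0
  for (k in use) {
    sub <- field$values[, , k, , drop = FALSE]
    dim(sub) <- d[c(1, 2, 4)]
    out <- out + sub * w[k]
    wsum <- wsum + w[k]
  }
  gridded_field(field$lon, field$lat, field$time, out / wsum,
                cell_area = field$cell_area, units = field$units)
}

#' Apply monthly warming increments to a daily field
#'
#' future(day, cell) = present(day, cell) + delta(month(day), cell). Daily
#' anomalies within each month are preserved exactly. Leap days use
#' February's increment.
#'
#' @param present A 2-D x time [gridded_field()].
#' @param delta A [scenario_delta()] on the same grid.
#' @return A [gridded_field()] for the future scenario.
#' @export
apply_delta_scenario <- function(present, delta) {
  stopifnot(inherits(present, "gridded_field"), inherits(delta, "scenario_delta"))
  if (!is.null(present$depth)) abort("Depth-average the field before applying a delta.")
  if (!isTRUE(all.equal(present$lon, delta$lon)) ||
      !isTRUE(all.equal(present$lat, delta$lat))) {
    abort("Delta grid is not aligned with the field grid.")
  }
  month <- as.POSIXlt(present$time)$mon + 1L
  out <- present$values
  for (m in sort(unique(month))) {
    idx <- which(month == m)
    out[, , idx] <- out[, , idx] + as.vector(delta$values[, , m])
  }
  gridded_field(present$lon, present$lat, present$time, out,
                cell_area = present$cell_area, units = present$units)
}

#' Turn a gridded field into a long tibble
#'
#' @param x A [gridded_field()].
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, (`depth`,) `time`,
#'   `temperature`; land cells are dropped.
#' @export
tidy.gridded_field <- function(x, ...) {
  if (is.null(x$depth)) {
    out <- tidyr::expand_grid(time = x$time, lat = x$lat, lon = x$lon)[, c("lon", "lat", "time")]
    out$temperature <- as.vector(x$values)
  } else {
    out <- tidyr::expand_grid(time = x$time, depth = x$depth, lat = x$lat,
                              lon = x$lon)[, c("lon", "lat", "depth", "time")]
    out$temperature <- as.vector(x$values)
  }
  dplyr::filter(out, !is.na(.data$temperature))
}
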