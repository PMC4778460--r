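#' Thermal habitat suitability map
#'
#' For each grid element i, THS is the time average of the normalised
#' metabolic scope over the scenario period:
#' \deqn{THS_i = \sum_t \max(0, MS(T_{i,t})) / (N \, MS_{max})}
#' where N is the number of days and MS_max the species' curve maximum (so
#' the index is comparable across scenarios and regions). Negative scope is
#' clamped to zero before averaging: temperatures beyond the critical
#' temperature are non-viable, and without clamping the index could leave
#' its [0, 1] range.
#'
#' @param field A 2-D x time [gridded_field()] (depth-averaged or surface).
#' @param params A [performance_params()] object.
#' @param ms_max Species' maximal scope; defaults to [curve_summary()] of
#'   `params`.
#' @return An object of class `suitability_map`: list with `lon`, `lat`,
#'   `ths` (lon x lat matrix in [0, 1], NA over land), `species`, `ms_max`,
#'   `cell_area`.
#' @export
#' @examples
#' fld <- generate_temperature_field(ocean_spec(nlon = 8, nlat = 8, years = 1, seed = 1))
#' ths <- compute_ths(fld, species_params("salema"))
compute_ths <- function(field, params, ms_max = NULL) {
  stopifnot(inherits(field, "gridded_field"))
  if (!is.null(field$depth)) abort("Depth-average the field before computing THS.")
  params <- as_performance_params(params)
  if (is.null(ms_max)) ms_max <- curve_summary(params)$ms_max
  if (ms_max <= 0) abort("`ms_max` must be positive.")
  v <- field$values
  # land mask must be time-invariant; a stray NA on a sea cell is a data error
  na_per_cell <- rowSums(matrix(is.na(v), nrow = dim(v)[1] * dim(v)[2]))
  nt <- dim(v)[3]
  if (!all(na_per_cell %in% c(0L, nt))) {
    abort("Non-finite temperatures on sea cells (mask varies over time).")
  }
  nms <- pmin(pmax(0, ms_curve(v, params)) / ms_max, 1)
  dim(nms) <- dim(v)
  ths <- rowMeans(matrix(nms, nrow = dim(v)[1] * dim(v)[2]))
  ths <- matrix(ths, nrow = length(field$lon))
  new_suitability_map(field$lon, field$lat, ths, params$species, ms_max,
                      field$cell_area)
}

new_suitability_map <- function(lon, lat, ths, species, ms_max, cell_area) {
  structure(
    list(lon = lon, lat = lat, ths = ths, species = species, ms_max = ms_max,
         cell_area = cell_area),
    class = "suitability_map"
  )
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("<suitability_map: %s> %d x %d, THS in [%.3f, %.3f]\n",
              x$species %||% "?", length(x$lon), length(x$lat),
              min(x$ths, na.rm = TRUE), max(x$ths, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.suitability_map <- function(x, ...) {
  out <- tidyr::expand_grid(lat = x$lat, lon = x$lon)[, c("lon", "lat")]
  out$ths <- as.vector(x$ths)
  out$species <- x$species
  dplyr::filter(out, !is.na(.data$ths))
}

#' Derive the suitability threshold from occurrence records
#'
#' Finds the THS isoline enclosing a fraction `coverage` of the observed
#' occurrences: the threshold is the (1 - coverage) quantile of the THS
#' values sampled at the occurrence locations, so that `coverage` of the
#' occurrences sit at THS >= threshold. Occurrences falling on land
#' (masked) cells are excluded with a warning.
#'
#' @param ths A [compute_ths()] map.
#' @param occurrences Data frame with columns `lon`, `lat` (degrees);
#'   points are assigned to the nearest cell centre.
#' @param coverage Fraction of occurrences the suitable area must cover
#'   (default 0.95).
#' @return Single threshold value in (0, 1).
#' @export
derive_threshold <- function(ths, occurrences, coverage = 0.95) {
  stopifnot(inherits(ths, "suitability_map"))
  if (!all(c("lon", "lat") %in% names(occurrences))) {
    abort("`occurrences` needs `lon` and `lat` columns.")
  }
  if (coverage <= 0 || coverage > 1) abort("`coverage` must be in (0, 1].")
  ix <- nearest_index(occurrences$lon, ths$lon)
  iy <- nearest_index(occurrences$lat, ths$lat)
  vals <- ths$ths[cbind(ix, iy)]
  n_land <- sum(is.na(vals))
  if (n_land > 0) {
    warn(sprintf("%d occurrence(s) fall on masked (land) cells; excluded.", n_land))
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) abort("All occurrences fall on masked cells.")
  if (coverage == 1) return(min(vals))
  unname(quantile(vals, probs = 1 - coverage, type = 7))
}

nearest_index <- function(x, centres) {
  vapply(x, function(v) which.min(abs(centres - v)), integer(1))
}

#' Binary suitability mask
#'
#' QMS is 1 where THS strictly exceeds the threshold and 0 otherwise (ties
#' count as unsuitable, a fixed convention so results are bit-stable).
#'
#' @param ths A [compute_ths()] map.
#' @param t_ms Threshold in (0, 1); the demo physiology uses 0.62, the
#'   isoline containing 95% of current occurrences of both species.
#' @return An object of class `qms_map`: `lon`, `lat`, `qms` (0/1 matrix,
#'   NA over land), `t_ms`, `species`, `cell_area`.
#' @export
compute_qms <- function(ths, t_ms) {
  stopifnot(inherits(ths, "suitability_map"))
  if (!is.numeric(t_ms) || length(t_ms) != 1L || t_ms <= 0 || t_ms >= 1) {
    abort("`t_ms` must be a single value in (0, 1).")
  }
  qms <- ifelse(ths$ths > t_ms, 1, 0)
  structure(
    list(lon = ths$lon, lat = ths$lat, qms = qms, t_ms = t_ms,
         species = ths$species, cell_area = ths$cell_area),
    class = "qms_map"
  )
}

#' Coexistence factor map
#'
#' CF = QMS(salema) - QMS(spinefoot) per element: +1 marks conditions
#' thermally favouring only the native salema, -1 only the invasive
#' marbled spinefoot, and 0 areas suitable (or unsuitable) for both.
#'
#' @param qms_s QMS map for the salema (native).
#' @param qms_r QMS map for the marbled spinefoot (invader).
#' @return An object of class `coexistence_map`: `lon`, `lat`, `cf`
#'   (matrix in {-1, 0, 1}, NA over land), `qms_s`, `qms_r`, `t_ms`,
#'   `cell_area`.
#' @export
compute_cf <- function(qms_s, qms_r) {
  stopifnot(inherits(qms_s, "qms_map"), inherits(qms_r, "qms_map"))
  if (!isTRUE(all.equal(qms_s$lon, qms_r$lon)) ||
      !isTRUE(all.equal(qms_s$lat, qms_r$lat))) {
    abort("The two QMS maps are not on the same grid.")
  }
  structure(
    list(lon = qms_s$lon, lat = qms_s$lat,
         cf = qms_s$qms - qms_r$qms,
         qms_s = qms_s$qms, qms_r = qms_r$qms,
         t_ms = qms_s$t_ms, cell_area = qms_s$cell_area),
    class = "coexistence_map"
  )
}

#' @export
print.coexistence_map <- function(x, ...) {
  tab <- table(factor(x$cf, levels = c(-1, 0, 1)))
  cat(sprintf("<coexistence_map> %d x %d; cells CF<0: %d, CF=0: %d, CF>0: %d\n",
              length(x$lon), length(x$lat), tab[[1]], tab[[2]], tab[[3]]))
  invisible(x)
}

#' @export
tidy.coexistence_map <- function(x, ...) {
  out <- tidyr::expand_grid(lat = x$lat, lon = x$lon)[, c("lon", "lat")]
  out$cf <- as.vector(x$cf)
  dplyr::filter(out, !is.na(.data$cf))
}

#' Area shares of the coexistence classes
#'
#' Area-weighted percentages of sea surface with CF < 0 (favouring the
#' spinefoot only), CF = 0 (both or neither) and CF > 0 (salema only).
#'
#' @param cf A [compute_cf()] map.
#' @param cell_area Optional lon x lat area matrix overriding the one
#'   carried by the map.
#' @return One-row tibble: `cf_lt0_pct`, `cf_eq0_pct`, `cf_gt0_pct`,
#'   `t_ms`; the three percentages sum to 100.
#' @export
summarize_coexistence <- function(cf, cell_area = NULL) {
  stopifnot(inherits(cf, "coexistence_map"))
  area <- cell_area %||% cf$cell_area
  if (!identical(dim(area), dim(cf$cf))) abort("`cell_area` does not match the grid.")
  sea <- !is.na(cf$cf)
  total <- sum(area[sea])
  if (total <= 0) abort("Zero total sea area.")
  pct <- function(cond) 100 * sum(area[sea & cond]) / total
  tibble::tibble(
    cf_lt0_pct = pct(!is.na(cf$cf) & cf$cf < 0),
    cf_eq0_pct = pct(!is.na(cf$cf) & cf$cf == 0),
    cf_gt0_pct = pct(!is.na(cf$cf) & cf$cf > 0),
    t_ms = cf$t_ms
  )
}

#' @param object A `suitability_map` or `coexistence_map`.
#' @param ... Unused.
#' @rdname compute_ths
#' @export
autoplot.suitability_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$lon, .data$lat, fill = .data$ths)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "THS",
                  title = object$species) +
    ggplot2::theme_minimal()
}

#' @rdname compute_cf
#' @param object A `coexistence_map`.
#' @param ... Unused.
#' @export
autoplot.coexistence_map <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(cf = factor(.data$cf, levels = c(-1, 0, 1),
                              labels = c("spinefoot only", "both/neither", "salema only")))
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$cf)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c("spinefoot only" = "#d73027",
                                          "both/neither" = "#ffffbf",
                                          "salema only" = "#1a9850"),
                               drop = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "CF") +
    ggplot2::theme_minimal()
}
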