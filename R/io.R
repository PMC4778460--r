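#' Read and write respirometry trace CSV files
#'
#' One CSV per trial with columns `time_s, o2_mg_l, o2_sat_pct, temp_c,
#' phase`, and the trial metadata (fish id, species, masses, volumes) in a
#' JSON sidecar named `<file>.meta.json`.
#'
#' @param path CSV path.
#' @return `read_trace_csv()` returns a [respirometry_trace()];
#'   `write_trace_csv()` returns `path` invisibly.
#' @export
read_trace_csv <- function(path) {
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("Missing metadata sidecar: %s", meta_path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  data <- readr::read_csv(path, show_col_types = FALSE)
  respirometry_trace(
    data,
    fish_id = meta$fish_id, species = meta$species,
    respirometer_volume = meta$respirometer_volume,
    fish_mass = meta$fish_mass,
    fish_volume = meta$fish_volume %||% (meta$fish_mass / 1.0)
  )
}

#' @param trace A [respirometry_trace()].
#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "respiro_trace"))
  readr::write_csv(tibble::as_tibble(trace), path)
  jsonlite::write_json(trace_meta(trace), paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write metabolic record CSV files
#'
#' Schema: `fish_id, species, acclim_temp_c, mmr, smr, ms, mass_kg`.
#' Reading re-validates the scope identity (`ms` = `mmr` - `smr`) and the
#' non-negativity of scope; violating rows are rejected with a warning.
#'
#' @param path CSV path.
#' @return A tibble of metabolic records.
#' @export
read_metabolic_records <- function(path) {
  recs <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("fish_id", "species", "acclim_temp_c", "mmr", "smr", "ms", "mass_kg")
  missing_cols <- setdiff(need, names(recs))
  if (length(missing_cols)) {
    abort(paste0("Record file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- recs$mmr < recs$smr | abs(recs$ms - (recs$mmr - recs$smr)) > 1e-8
  if (any(bad)) {
    warn(sprintf("%d record(s) violate MS = MMR - SMR >= 0; rejected.", sum(bad)))
    recs <- recs[!bad, ]
  }
  recs
}

#' @param records Tibble of metabolic records.
#' @rdname read_metabolic_records
#' @export
write_metabolic_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Round-trip gridded fields through a plain-text container
#'
#' Serialises a [gridded_field()] to a single JSON document carrying the
#' coordinate vectors (CF-style dimension names `lon`, `lat`, `depth`,
#' `time`), the temperature values in degrees C with `null` over land, the
#' cell areas, and a `units` attribute. Reading validates the units and
#' restores grid, mask and values to full precision.
#'
#' @param path File path (conventionally `.json`).
#' @return `read_field()` returns a [gridded_field()]; `write_field()`
#'   returns `path` invisibly.
#' @export
read_field <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("lon", "lat", "time", "values", "units")) {
    if (is.null(doc[[nm]])) abort(sprintf("Field file lacks `%s`.", nm))
  }
  if (!identical(doc$units, "degC")) {
    abort(sprintf('Unsupported temperature units "%s": expected "degC".', doc$units))
  }
  values <- array(as.numeric(doc$values), dim = as.integer(doc$dim))
  gridded_field(
    lon = doc$lon, lat = doc$lat, time = as.Date(doc$time), values = values,
    depth = doc$depth, depth_bounds = doc$depth_bounds,
    cell_area = if (!is.null(doc$cell_area)) {
      matrix(as.numeric(doc$cell_area), nrow = length(doc$lon))
    },
    units = doc$units
  )
}

#' @param field A [gridded_field()].
#' @rdname read_field
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  doc <- list(
    lon = field$lon, lat = field$lat, depth = field$depth,
    depth_bounds = field$depth_bounds,
    time = format(field$time, "%Y-%m-%d"),
    dim = dim(field$values),
    values = as.vector(field$values),
    cell_area = as.vector(field$cell_area),
    units = field$units
  )
  jsonlite::write_json(doc[!vapply(doc, is.null, logical(1))], path,
                       digits = NA, na = "null")
  invisible(path)
}

#' Write a suitability or coexistence map to a plain-text container
#'
#' @param map A `suitability_map` or `coexistence_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (inherits(map, "suitability_map")) {
    doc <- list(kind = "ths", lon = map$lon, lat = map$lat,
                values = as.vector(map$ths), species = map$species,
                ms_max = map$ms_max)
  } else if (inherits(map, "coexistence_map")) {
    doc <- list(kind = "cf", lon = map$lon, lat = map$lat,
                values = as.vector(map$cf), t_ms = map$t_ms)
  } else {
    abort("`map` must be a suitability_map or coexistence_map.")
  }
  jsonlite::write_json(doc, path, digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' Read and write occurrence point CSV files
#'
#' Schema: `lon, lat[, species]`.
#'
#' @param path CSV path.
#' @return A tibble of occurrence points.
#' @export
read_occurrences <- function(path) {
  occ <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("lon", "lat") %in% names(occ))) {
    abort("Occurrence file needs `lon` and `lat` columns.")
  }
  occ
}

#' @param occurrences Tibble with `lon`, `lat` columns.
#' @rdname read_occurrences
#' @export
write_occurrences <- function(occurrences, path) {
  readr::write_csv(occurrences, path)
  invisible(path)
}

#' Write fitted parameters and curve summaries as JSON
#'
#' @param params A [performance_params()] object.
#' @param path Output path.
#' @param extra Optional named list of fit diagnostics to include.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path, extra = NULL) {
  params <- as_performance_params(params)
  cs <- curve_summary(params)
  doc <- c(
    params[c("species", "a", "b", "omega", "delta", "t_m", "t_act")],
    list(t_opt = cs$t_opt, ms_max = cs$ms_max, t_crit = cs$t_crit),
    extra
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
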