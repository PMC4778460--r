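#' Configuration for the two-scenario projection pipeline
#'
#' Collects everything [run_pipeline()] needs: where to write, the seed,
#' how to obtain species parameters (the packaged canonical sets, a fit to
#' a metabolic-record CSV, or explicit objects), how to obtain the
#' suitability threshold (a fixed value or derivation from occurrences),
#' and the synthetic-ocean settings for the temperature scenarios.
#'
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed controlling every random component.
#' @param species Character vector of species to project.
#' @param params_source `"packaged"` (default: the canonical parameter
#'   sets), `"fit"` (fit curves to `records_path`), or a named list of
#'   [performance_params()] per species.
#' @param records_path Metabolic record CSV, required when
#'   `params_source = "fit"`.
#' @param t_ms Fixed suitability threshold in (0, 1) (default 0.62), or
#'   `"derive"` to estimate it from synthetic occurrences on the
#'   present-day map (95% coverage).
#' @param ocean An [ocean_spec()]; its `seed` is overridden by `seed`.
#' @param scenarios Scenario names to run (subset of
#'   `c("present", "future")`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            species = c("salema", "spinefoot"),
                            params_source = "packaged",
                            records_path = NULL,
                            t_ms = 0.62,
                            ocean = ocean_spec(),
                            scenarios = c("present", "future")) {
  if (is.numeric(t_ms) && (t_ms <= 0 || t_ms >= 1)) {
    abort("Fixed `t_ms` must lie in (0, 1).")
  }
  if (identical(params_source, "fit") && is.null(records_path)) {
    abort('`records_path` is required when `params_source = "fit"`.')
  }
  scenarios <- match.arg(scenarios, c("present", "future"), several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full projection pipeline
#'
#' Executes parameter acquisition, scenario temperature generation,
#' suitability projection, thresholding and coexistence mapping for every
#' configured scenario, and writes: a parameters JSON per species, a THS
#' map per species and scenario, a CF map and a summary JSON per scenario,
#' and a run log carrying the package version, the seed and a hash of the
#' configuration. The run is deterministic: identical configurations yield
#' identical scientific outputs. On any stage failure the partial outputs
#' are removed and a stage-tagged error is raised.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a tibble of per-scenario coexistence summaries.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(outdir = tempfile("aerohab"),
#'                        ocean = ocean_spec(nlon = 10, nlat = 10, years = 1))
#' run_pipeline(cfg, quiet = TRUE)
#' }
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  created <- !dir.exists(config$outdir)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  emit <- function(writer, obj, name) {
    path <- file.path(config$outdir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      if (created) unlink(config$outdir, recursive = TRUE)
      abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
    })
  }

  params <- run_stage("parameters", {
    say("parameters", paste("source:", if (is.list(config$params_source)) "supplied"
                            else config$params_source))
    get_pipeline_params(config)
  })
  for (sp in names(params)) {
    run_stage("parameters", {
      emit(function(p, path) write_params_json(p, path), params[[sp]],
           sprintf("params_%s.json", sp))
    })
  }

  ocean <- config$ocean
  ocean$seed <- config$seed
  fields <- run_stage("temperature", {
    say("temperature", sprintf("generating %d scenario field(s), %dx%d x %d y",
                               length(config$scenarios), ocean$nlon, ocean$nlat,
                               ocean$years))
    setNames(
      lapply(config$scenarios, function(sc) generate_temperature_field(ocean, sc)),
      config$scenarios
    )
  })

  maps <- run_stage("projection", {
    purrr::map(setNames(nm = config$scenarios), function(sc) {
      purrr::map(params, function(p) compute_ths(fields[[sc]], p))
    })
  })
  for (sc in config$scenarios) {
    for (sp in names(params)) {
      run_stage("projection", {
        emit(write_map, maps[[sc]][[sp]], sprintf("ths_%s_%s.json", sp, sc))
      })
    }
  }

  t_ms <- run_stage("threshold", {
    if (identical(config$t_ms, "derive")) {
      base_sc <- config$scenarios[1]
      vals <- vapply(names(params), function(sp) {
        occ <- generate_occurrences(maps[[base_sc]][[sp]], n = 200,
                                    min_ths = 0.5, seed = config$seed)
        derive_threshold(maps[[base_sc]][[sp]], occ, coverage = 0.95)
      }, numeric(1))
      say("threshold", sprintf("derived t_ms = %.3f (per-species mean)", mean(vals)))
      mean(vals)
    } else {
      config$t_ms
    }
  })

  summaries <- run_stage("coexistence", {
    if (length(params) < 2) {
      say("coexistence", "fewer than two species; skipping CF maps")
      tibble::tibble()
    } else {
    sp_native <- names(params)[1]
    sp_invader <- names(params)[2]
    purrr::map_dfr(setNames(nm = config$scenarios), function(sc) {
      cf <- compute_cf(compute_qms(maps[[sc]][[sp_native]], t_ms),
                       compute_qms(maps[[sc]][[sp_invader]], t_ms))
      emit(write_map, cf, sprintf("cf_%s.json", sc))
      summ <- dplyr::mutate(summarize_coexistence(cf), scenario = sc, .before = 1)
      emit(function(x, path) {
        jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA)
      }, summ, sprintf("summary_%s.json", sc))
      summ
    })
    }
  })

  run_stage("log", {
    log <- list(
      package = "aerohab",
      version = as.character(utils::packageVersion("aerohab")),
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
      scenarios = config$scenarios,
      species = names(params),
      t_ms = t_ms,
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )
    emit(function(x, path) jsonlite::write_json(x, path, auto_unbox = TRUE),
         log, "run_log.json")
  })
  say("done", sprintf("%d files written to %s", length(written), config$outdir))
  invisible(summaries)
}

get_pipeline_params <- function(config) {
  if (is.list(config$params_source)) {
    return(lapply(config$params_source, as_performance_params))
  }
  if (identical(config$params_source, "packaged")) {
    return(setNames(lapply(config$species, species_params), config$species))
  }
  if (identical(config$params_source, "fit")) {
    recs <- read_metabolic_records(config$records_path)
    out <- lapply(config$species, function(sp) {
      sub <- dplyr::filter(recs, .data$species == sp)
      combine_fits(fit_smr(sub), fit_mmr(sub), species = sp)
    })
    return(setNames(out, config$species))
  }
  abort('`params_source` must be "packaged", "fit", or a named list.')
}
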