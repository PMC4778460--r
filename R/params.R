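#' Thermal performance parameters for one species
#'
#' Bundles the six empirical parameters of the metabolic-rate model:
#' standard metabolic rate (SMR) follows an exponential law
#' \eqn{SMR(T) = a e^{bT}}, and maximal metabolic rate (MMR) follows a
#' skewed unimodal curve
#' \eqn{MMR(T) = \delta x^{\omega} e^{-\omega x}} with
#' \eqn{x = (T_m - T) / (T_m - T_{act})}, which peaks at `t_act` and
#' reaches zero at `t_m`. Aerobic (metabolic) scope is MS = MMR - SMR.
#'
#' @param a SMR scale, mg O2 kg^-1 h^-1. Must be positive.
#' @param b SMR exponential rate, per degree C. Must be positive.
#' @param omega MMR shape (skewness) parameter, unitless, positive.
#' @param delta MMR scale, mg O2 kg^-1 h^-1, positive.
#' @param t_m Temperature at which MMR is zero, degrees C.
#' @param t_act Temperature at which MMR peaks, degrees C. Must be < `t_m`.
#' @param species Optional species label.
#'
#' @return An object of class `performance_params`.
#' @seealso [species_params()] for the packaged parameter sets,
#'   [evaluate_curves()], [curve_summary()].
#' @export
#' @examples
#' p <- performance_params(a = 190.2, b = 0.067, omega = 1.4,
#'                         delta = 6931.1, t_m = 32.8, t_act = 24.3,
#'                         species = "salema")
#' p
performance_params <- function(a, b, omega, delta, t_m, t_act, species = NA_character_) {
  for (nm in c("a", "b", "omega", "delta", "t_m", "t_act")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (a <= 0) abort("`a` must be positive.")
  if (b <= 0) abort("`b` must be positive.")
  if (omega <= 0) abort("`omega` must be positive.")
  if (delta <= 0) abort("`delta` must be positive.")
  if (t_m <= t_act) abort("`t_m` must exceed `t_act`.")
  structure(
    list(a = a, b = b, omega = omega, delta = delta,
         t_m = t_m, t_act = t_act, species = as.character(species)),
    class = "performance_params"
  )
}

#' @export
print.performance_params <- function(x, ...) {
  sp <- if (is.na(x$species)) "unlabelled species" else x$species
  cat(sprintf("<performance_params: %s>\n", sp))
  cat(sprintf("  SMR: a = %.4g mg O2/kg/h, b = %.4g /degC\n", x$a, x$b))
  cat(sprintf("  MMR: delta = %.6g, omega = %.4g, t_m = %.4g degC, t_act = %.4g degC\n",
              x$delta, x$omega, x$t_m, x$t_act))
  invisible(x)
}

#' @export
format.performance_params <- function(x, ...) {
  sp <- if (is.na(x$species)) "?" else x$species
  sprintf("performance_params(%s)", sp)
}

#' Packaged thermal performance parameter sets
#'
#' Returns the canonical fitted parameter set for the native salema
#' (*Sarpa salpa*) or the invasive marbled spinefoot (*Siganus rivulatus*),
#' read from the parameter fixture shipped with the package. These are the
#' parameter values used throughout the worked examples and the demo
#' pipeline.
#'
#' @param species `"salema"` or `"spinefoot"`.
#' @return A [performance_params()] object.
#' @export
#' @examples
#' species_params("salema")
species_params <- function(species = c("salema", "spinefoot")) {
  species <- match.arg(species)
  path <- system.file("extdata", "species_params.json", package = "aerohab",
                      mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- all[[species]]
  performance_params(a = p$a, b = p$b, omega = p$omega, delta = p$delta,
                     t_m = p$t_m, t_act = p$t_act, species = species)
}

#' @export
tidy.performance_params <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "omega", "delta", "t_m", "t_act"),
    estimate = c(x$a, x$b, x$omega, x$delta, x$t_m, x$t_act),
    unit = c("mg O2 kg-1 h-1", "degC-1", "", "mg O2 kg-1 h-1", "degC", "degC")
  )
}

#' Coerce fit results or lists to performance parameters
#'
#' @param x Object to coerce: a `performance_params`, a named list, or the
#'   combination of an SMR fit and an MMR fit (see [combine_fits()]).
#' @param ... Unused.
#' @return A [performance_params()] object.
#' @export
as_performance_params <- function(x, ...) UseMethod("as_performance_params")

#' @export
as_performance_params.performance_params <- function(x, ...) x

#' @export
as_performance_params.list <- function(x, ...) {
  performance_params(a = x$a, b = x$b, omega = x$omega, delta = x$delta,
                     t_m = x$t_m, t_act = x$t_act,
                     species = x$species %||% NA_character_)
}

#' Combine separate SMR and MMR fits into one parameter set
#'
#' The SMR and MMR curves are fitted separately (each against its own
#' records); this merges the two coefficient sets into a single
#' `performance_params` object usable by the habitat-projection functions.
#'
#' @param smr_fit Result of [fit_smr()].
#' @param mmr_fit Result of [fit_mmr()].
#' @param species Optional species label (defaults to the SMR fit's label).
#' @return A [performance_params()] object.
#' @export
combine_fits <- function(smr_fit, mmr_fit, species = NULL) {
  stopifnot(inherits(smr_fit, "smr_fit"), inherits(mmr_fit, "mmr_fit"))
  cs <- smr_fit$estimate
  cm <- mmr_fit$estimate
  performance_params(a = cs[["a"]], b = cs[["b"]],
                     omega = cm[["omega"]], delta = cm[["delta"]],
                     t_m = cm[["t_m"]], t_act = cm[["t_act"]],
                     species = species %||% smr_fit$species %||% NA_character_)
}
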