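#' Fit the exponential standard metabolic rate curve
#'
#' Nonlinear least squares of per-fish SMR against acclimation temperature
#' under the model \eqn{SMR(T) = a e^{bT}}. Starting values come from an
#' ordinary linear regression of log(SMR) on temperature, which solves the
#' noiseless problem exactly; Levenberg-Marquardt iterations then minimise
#' the untransformed residuals.
#'
#' @param records A data frame of metabolic records with columns
#'   `acclim_temp_c` and `smr` (mg O2 kg^-1 h^-1). The output of
#'   [process_trace()] / [generate_metabolic_dataset()] works directly.
#' @return An object of class `smr_fit` with elements `estimate` (named
#'   vector `a`, `b`), `std_error`, `n`, `converged`, `species`, and the
#'   underlying `nls` object as `fit`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' recs <- generate_metabolic_dataset(design_spec(
#'   params = species_params("spinefoot"), cv = 0, seed = 1))
#' fit_smr(recs)
fit_smr <- function(records) {
  records <- validate_records(records, need = c("acclim_temp_c", "smr"))
  if (dplyr::n_distinct(records$acclim_temp_c) < 3L) {
    abort("fit_smr() needs records at >= 3 distinct temperatures.")
  }
  if (any(records$smr <= 0)) abort("SMR values must be positive.")
  start_lm <- lm(log(smr) ~ acclim_temp_c, data = records)
  start <- list(a = exp(coef(start_lm)[[1]]), b = coef(start_lm)[[2]])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      smr ~ a * exp(b * acclim_temp_c), data = records, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) abort(paste0("SMR fit did not converge: ", conditionMessage(e)))
  )
  new_curve_fit(fit, records, class = "smr_fit")
}

#' Fit the skewed maximal metabolic rate curve
#'
#' Nonlinear least squares of per-fish MMR against acclimation temperature
#' under the model \eqn{MMR(T) = \delta x^{\omega} e^{-\omega x}},
#' \eqn{x = (T_m - T)/(T_m - T_{act})}. Initialisation: `t_act` at the
#' temperature of the largest observed MMR, `t_m` 5 degrees C beyond the
#' warmest observation, `omega = 1`, `delta = max(MMR) e`. Positivity of
#' `delta` and `omega` is enforced by box bounds; the ordering `t_m > t_act`
#' is checked at the solution and a violated ordering (or an active bound)
#' is flagged in the result rather than silently accepted.
#'
#' @param records A data frame with columns `acclim_temp_c` and `mmr`.
#'   At least 5 distinct temperatures are required; designs bracketing the
#'   MMR peak identify `t_act` and `t_m` far better than one-sided designs.
#' @return An object of class `mmr_fit` (fields as in [fit_smr()], plus
#'   `boundary`, TRUE when a bound is active or the ordering failed).
#' @export
fit_mmr <- function(records) {
  records <- validate_records(records, need = c("acclim_temp_c", "mmr"))
  if (dplyr::n_distinct(records$acclim_temp_c) < 5L) {
    abort("fit_mmr() needs records at >= 5 distinct temperatures.")
  }
  if (any(records$mmr < 0)) abort("MMR values must be non-negative.")
  i_max <- which.max(records$mmr)
  start <- list(
    delta = max(records$mmr) * exp(1),
    omega = 1,
    t_m = max(records$acclim_temp_c) + 5,
    t_act = records$acclim_temp_c[i_max]
  )
  lower <- c(delta = 1e-8, omega = 1e-3, t_m = -Inf, t_act = -Inf)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      mmr ~ delta * ((t_m - acclim_temp_c) / (t_m - t_act))^omega *
        exp(-omega * (t_m - acclim_temp_c) / (t_m - t_act)),
      data = records, start = start, lower = lower,
      control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15)
    ),
    error = function(e) abort(paste0("MMR fit did not converge: ", conditionMessage(e)))
  )
  out <- new_curve_fit(fit, records, class = "mmr_fit")
  est <- out$estimate
  out$boundary <- est[["t_m"]] <= est[["t_act"]] ||
    est[["delta"]] <= 2 * lower[["delta"]] || est[["omega"]] <= 2 * lower[["omega"]]
  if (out$boundary) {
    warn("MMR fit hit a parameter bound or violated t_m > t_act; inspect `$boundary`.")
  }
  out
}

new_curve_fit <- function(fit, records, class) {
  sm <- summary(fit)
  structure(
    list(
      estimate = coef(fit),
      std_error = sm$coefficients[, "Std. Error"],
      sigma = sm$sigma,
      n = nrow(records),
      converged = fit$convInfo$isConv %||% TRUE,
      species = if ("species" %in% names(records)) {
        u <- unique(records$species)
        if (length(u) == 1L) as.character(u) else NA_character_
      } else NA_character_,
      fit = fit
    ),
    class = c(class, "curve_fit")
  )
}

validate_records <- function(records, need) {
  if (!is.data.frame(records)) abort("`records` must be a data frame.")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    abort(paste0("`records` is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  records <- records[stats::complete.cases(records[need]), , drop = FALSE]
  if (!nrow(records)) abort("No complete records to fit.")
  records
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<%s, n = %d%s>\n", class(x)[1], x$n,
              if (!is.na(x$species)) paste0(", ", x$species) else ""))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.curve_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    std.error = unname(x$std_error)
  )
}

#' @export
glance.curve_fit <- function(x, ...) {
  tibble::tibble(
    sigma = x$sigma,
    nobs = x$n,
    converged = x$converged,
    boundary = x$boundary %||% FALSE
  )
}

#' Validate scope predictions against observations
#'
#' Through-origin linear regression of observed metabolic scope on the
#' scope predicted by the fitted curves: \eqn{MS_{obs} = s \cdot MS_{pre}}.
#' The slope is \eqn{\sum x y / \sum x^2}; a slope indistinguishable from 1
#' indicates an unbiased empirical model. The reported r-squared is the
#' through-origin (uncentred) coefficient of determination, and the slope
#' is tested against 1 with a two-sided t test on n - 1 degrees of freedom.
#'
#' @param observed Numeric vector of observed MS values.
#' @param predicted Numeric vector of predicted MS values (same length).
#' @return An object of class `origin_fit` with fields `slope`, `slope_se`,
#'   `r2`, `n`, `p_slope_vs_one`; has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' p <- species_params("salema")
#' pred <- ms_curve(c(17, 20, 23, 26), p)
#' validate_predictions(pred * 1.02, pred)
validate_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length.")
  }
  keep <- is.finite(observed) & is.finite(predicted)
  x <- predicted[keep]
  y <- observed[keep]
  n <- length(x)
  if (n < 3L) abort("Need at least 3 paired observations.")
  if (all(x == 0)) abort("All predictions are zero; the slope is undefined.")
  sxx <- sum(x^2)
  slope <- sum(x * y) / sxx
  ss_res <- sum((y - slope * x)^2)
  slope_se <- sqrt(ss_res / (n - 1) / sxx)
  r2 <- 1 - ss_res / sum(y^2)
  t_stat <- (slope - 1) / slope_se
  structure(
    list(slope = slope, slope_se = slope_se, r2 = r2, n = n,
         p_slope_vs_one = 2 * pt(-abs(t_stat), df = n - 1)),
    class = "origin_fit"
  )
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> MS_obs = (%.3f +/- %.3f) x MS_pre, r2 = %.3f, n = %d\n",
              x$slope, x$slope_se, x$r2, x$n))
  cat(sprintf("  H0 slope = 1: P = %.3g\n", x$p_slope_vs_one))
  invisible(x)
}

#' @export
tidy.origin_fit <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$slope, std.error = x$slope_se,
                 p.value.vs.one = x$p_slope_vs_one)
}

#' @export
glance.origin_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n)
}

#' Confidence interval for a through-origin validation slope
#'
#' @param object An `origin_fit`.
#' @param parm Unused (the single slope).
#' @param level Confidence level (default 0.95).
#' @param ... Unused.
#' @return A 1 x 2 matrix of lower and upper bounds.
#' @export
confint.origin_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qt(1 - (1 - level) / 2, df = object$n - 1)
  out <- matrix(object$slope + c(-1, 1) * q * object$slope_se, nrow = 1)
  dimnames(out) <- list("slope", sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100))
  out
}
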