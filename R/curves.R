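#' Evaluate the thermal performance curves
#'
#' Computes standard metabolic rate (SMR), maximal metabolic rate (MMR) and
#' aerobic metabolic scope (MS = MMR - SMR) at one or more temperatures.
#'
#' SMR is the exponential \eqn{a e^{bT}}. MMR is the skewed curve
#' \eqn{\delta x^{\omega} e^{-\omega x}} with
#' \eqn{x = (T_m - T)/(T_m - T_{act})} for \eqn{T \le T_m}; above `t_m` the
#' curve is defined as exactly zero (the parameterisation's own zero point),
#' so MS = -SMR there. MS may be negative; clamping to zero is applied only
#' when scope is aggregated into habitat suitability (see [compute_ths()]).
#'
#' @param temperature Numeric vector of water temperatures, degrees C. Must
#'   be finite (NA is propagated, to support masked grids).
#' @param params A [performance_params()] object.
#' @return A tibble with columns `temperature`, `smr`, `mmr`, `ms`
#'   (all rates in mg O2 kg^-1 h^-1).
#' @export
#' @examples
#' evaluate_curves(c(17, 20, 23, 26), species_params("salema"))
evaluate_curves <- function(temperature, params) {
  params <- as_performance_params(params)
  if (!is.numeric(temperature)) abort("`temperature` must be numeric.")
  if (any(is.infinite(temperature))) abort("`temperature` must be finite.")
  tibble::tibble(
    temperature = as.numeric(temperature),
    smr = smr_curve(temperature, params),
    mmr = mmr_curve(temperature, params),
    ms = ms_curve(temperature, params)
  )
}

#' Standard, maximal and scope curves as bare vectors
#'
#' Vectorised scalar versions of the three curves, used internally and by
#' the grid projections where a full tibble per cell-day would be wasteful.
#'
#' @inheritParams evaluate_curves
#' @return Numeric vector, mg O2 kg^-1 h^-1.
#' @export
smr_curve <- function(temperature, params) {
  params <- as_performance_params(params)
  params$a * exp(params$b * temperature)
}

#' @rdname smr_curve
#' @export
mmr_curve <- function(temperature, params) {
  params <- as_performance_params(params)
  x <- (params$t_m - temperature) / (params$t_m - params$t_act)
  out <- ifelse(x < 0, 0, params$delta * x^params$omega * exp(-params$omega * x))
  out[is.na(temperature)] <- NA_real_
  out
}

#' @rdname smr_curve
#' @export
ms_curve <- function(temperature, params) {
  mmr_curve(temperature, params) - smr_curve(temperature, params)
}

#' Summarise a thermal performance curve
#'
#' Locates the optimal temperature `t_opt` (argmax of metabolic scope), the
#' maximal scope `ms_max` = MS(t_opt), and the critical temperature
#' `t_crit`, the zero crossing of MS above `t_opt`. There is no closed form
#' for either point, so `t_opt` is found by dense grid search and `t_crit`
#' by bisection, both to `resolution` degrees C.
#'
#' @param params A [performance_params()] object.
#' @param resolution Grid/bisection resolution in degrees C (default 0.001).
#' @param t_min Lower edge of the search interval, degrees C (default 0).
#' @return A one-row tibble: `species`, `t_opt`, `ms_max`, `t_crit`.
#' @export
#' @examples
#' curve_summary(species_params("spinefoot"))
curve_summary <- function(params, resolution = 0.001, t_min = 0) {
  params <- as_performance_params(params)
  grid <- seq(t_min, params$t_m, by = resolution)
  ms <- ms_curve(grid, params)
  i <- which.max(ms)
  if (ms[i] <= 0) {
    abort("Metabolic scope is non-positive everywhere: non-viable parameter set.")
  }
  t_opt <- grid[i]
  ms_max <- ms[i]
  # MS(t_m) = -SMR(t_m) < 0, so a root is bracketed on (t_opt, t_m]
  root <- uniroot(function(T) ms_curve(T, params),
                  lower = t_opt, upper = params$t_m,
                  tol = min(resolution, 0.001) / 10)
  tibble::tibble(
    species = params$species,
    t_opt = t_opt,
    ms_max = ms_max,
    t_crit = root$root
  )
}

#' Normalised metabolic scope
#'
#' NMS = max(0, MS(T)) / MS_max, a unitless index in [0, 1] expressing
#' instantaneous aerobic performance relative to the species' curve maximum.
#' Negative scope (temperatures beyond the critical temperature) is clamped
#' to zero: such conditions are non-viable, not "negatively suitable".
#'
#' @inheritParams evaluate_curves
#' @param ms_max Species' maximal metabolic scope. Defaults to the value
#'   from [curve_summary()] of `params`.
#' @return Numeric vector in [0, 1] (NA propagated).
#' @export
#' @examples
#' p <- species_params("salema")
#' normalized_ms(c(17, 22, 29), p)
normalized_ms <- function(temperature, params, ms_max = NULL) {
  params <- as_performance_params(params)
  if (is.null(ms_max)) ms_max <- curve_summary(params)$ms_max
  if (!is.numeric(ms_max) || length(ms_max) != 1L || !is.finite(ms_max) || ms_max <= 0) {
    abort("`ms_max` must be a single positive number.")
  }
  pmin(pmax(0, ms_curve(temperature, params)) / ms_max, 1)
}

#' Plot the thermal performance curves of one or more species
#'
#' @param params A [performance_params()] object.
#' @param t_range Temperature range to draw, degrees C.
#' @param ... Unused.
#' @return A ggplot object showing SMR, MMR and MS against temperature,
#'   with the optimum and critical temperatures marked.
#' @export
autoplot.performance_params <- function(params, t_range = NULL, ...) {
  params <- as_performance_params(params)
  t_range <- t_range %||% c(10, params$t_m)
  df <- evaluate_curves(seq(t_range[1], t_range[2], length.out = 400), params) |>
    tidyr::pivot_longer(c("smr", "mmr", "ms"),
                        names_to = "rate", values_to = "value") |>
    dplyr::mutate(rate = toupper(.data$rate))
  cs <- curve_summary(params)
  ggplot2::ggplot(df, ggplot2::aes(.data$temperature, .data$value,
                                   colour = .data$rate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(cs$t_opt, cs$t_crit), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = expression(paste("Rate (mg ", O[2], " ", kg^-1, " ", h^-1, ")")),
      colour = NULL,
      title = if (is.na(params$species)) NULL else params$species,
      subtitle = sprintf("T_opt = %.1f°C, T_crit = %.1f°C", cs$t_opt, cs$t_crit)
    ) +
    ggplot2::theme_minimal()
}
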