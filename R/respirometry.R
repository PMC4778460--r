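#' Construct an intermittent-flow respirometry trace
#'
#' Wraps a sampled oxygen time series from one fish in one static
#' respirometer, together with the trial metadata needed to convert oxygen
#' depletion slopes into mass-specific uptake rates. The protocol emulated
#' throughout the package is alternating 15-min closed (measurement) and
#' 15-min flush (re-oxygenation) phases with a sample every 15 s.
#'
#' @param data Data frame with columns `time_s` (seconds since trial start,
#'   strictly increasing), `o2_mg_l` (dissolved oxygen, mg O2 per litre,
#'   positive), `o2_sat_pct` (percent air saturation), `temp_c` (water
#'   temperature, held constant over the trial), `phase` (`"closed"` or
#'   `"flush"` per sample).
#' @param fish_id Fish identifier.
#' @param species Species label (`"salema"` or `"spinefoot"` in the demo
#'   datasets; any label is accepted).
#' @param respirometer_volume Chamber volume, litres.
#' @param fish_mass Fish wet mass, kg.
#' @param fish_volume Fish body volume, litres; defaults to
#'   `fish_mass / 1.0` (1 kg/l tissue density), subtracted from the chamber
#'   volume when converting slopes to rates.
#' @param temp_tolerance Maximum allowed within-trial temperature range,
#'   degrees C (default 0.5).
#' @return A tibble of class `respiro_trace` carrying the metadata as
#'   attributes.
#' @export
respirometry_trace <- function(data, fish_id, species,
                               respirometer_volume, fish_mass,
                               fish_volume = fish_mass / 1.0,
                               temp_tolerance = 0.5) {
  need <- c("time_s", "o2_mg_l", "o2_sat_pct", "temp_c", "phase")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Trace is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (is.unsorted(data$time_s, strictly = TRUE)) {
    abort("`time_s` must be strictly increasing.")
  }
  if (any(data$o2_mg_l <= 0)) abort("`o2_mg_l` must be positive throughout.")
  if (!all(data$phase %in% c("closed", "flush"))) {
    abort('`phase` must be "closed" or "flush".')
  }
  if (diff(range(data$temp_c)) > temp_tolerance) {
    abort(sprintf("Temperature varies by more than %.2f degC within the trial.",
                  temp_tolerance))
  }
  if (!is.finite(fish_mass) || fish_mass <= 0) abort("`fish_mass` must be positive.")
  if (fish_volume >= respirometer_volume) {
    abort("`fish_volume` must be smaller than `respirometer_volume`.")
  }
  structure(
    data,
    fish_id = as.character(fish_id),
    species = as.character(species),
    respirometer_volume = respirometer_volume,
    fish_mass = fish_mass,
    fish_volume = fish_volume,
    class = c("respiro_trace", class(data))
  )
}

trace_meta <- function(trace) {
  list(
    fish_id = attr(trace, "fish_id"),
    species = attr(trace, "species"),
    respirometer_volume = attr(trace, "respirometer_volume"),
    fish_mass = attr(trace, "fish_mass"),
    fish_volume = attr(trace, "fish_volume")
  )
}

#' Extract oxygen-depletion slopes from the closed phases of a trace
#'
#' Segments the trace into contiguous phases, discards flush phases, trims
#' the first and last `trim_minutes` of each closed phase, and fits an
#' ordinary least-squares line of oxygen concentration on time to each
#' trimmed window. Closed phases whose oxygen saturation dips below
#' `min_saturation` percent are flagged `hypoxic` (measurements are only
#' valid in normoxia, > 80% saturation) and are excluded by the downstream
#' rate pipeline.
#'
#' @param trace A [respirometry_trace()].
#' @param trim_minutes Minutes discarded at each end of every closed phase
#'   (default 2): mixing transients after pump switching corrupt the ends.
#' @param min_saturation Normoxia threshold, percent air saturation
#'   (default 80).
#' @return A tibble with one row per closed phase: `phase_index`,
#'   `start_s`, `end_s`, `slope_mg_l_h` (negative while the fish respires),
#'   `r2`, `n_points`, `hypoxic`. Phases with fewer than 5 trimmed samples
#'   are skipped with a warning.
#' @export
extract_phase_slopes <- function(trace, trim_minutes = 2, min_saturation = 80) {
  stopifnot(inherits(trace, "respiro_trace"))
  runs <- rle(trace$phase)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  closed <- which(runs$values == "closed")
  if (!length(closed)) abort("Trace contains no closed phases.")
  rows <- purrr::map(seq_along(closed), function(k) {
    i <- closed[k]
    seg <- trace[starts[i]:ends[i], ]
    t0 <- min(seg$time_s)
    t1 <- max(seg$time_s)
    keep <- seg$time_s >= t0 + trim_minutes * 60 & seg$time_s <= t1 - trim_minutes * 60
    win <- seg[keep, ]
    if (nrow(win) < 5L) {
      warn(sprintf("Closed phase %d has %d trimmed samples (< 5); skipped.",
                   k, nrow(win)))
      return(NULL)
    }
    t_h <- win$time_s / 3600
    fit <- lm(o2_mg_l ~ t_h, data = tibble::tibble(o2_mg_l = win$o2_mg_l, t_h = t_h))
    ss_tot <- sum((win$o2_mg_l - mean(win$o2_mg_l))^2)
    ss_res <- sum(fit$residuals^2)
    tibble::tibble(
      phase_index = k,
      start_s = t0, end_s = t1,
      slope_mg_l_h = coef(fit)[[2]],
      r2 = if (ss_res <= ss_tot * 1e-14 || ss_tot == 0) 1 else 1 - ss_res / ss_tot,
      n_points = nrow(win),
      hypoxic = min(seg$o2_sat_pct) < min_saturation
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) abort("No closed phase retained enough samples for a slope.")
  out
}

#' Correct phase slopes for background microbial respiration
#'
#' Blank (fish-free) oxygen-depletion slopes measured before and after the
#' trial are interpolated linearly in time and subtracted from each phase
#' slope, attributing the remainder to the fish. With both blanks missing
#' the slopes are returned unchanged with a warning.
#'
#' @param slopes Tibble from [extract_phase_slopes()].
#' @param blank_pre,blank_post Background slopes (mg O2 l^-1 h^-1) at the
#'   start and end of the trial; `NA` or `NULL` for unmeasured.
#' @param trial_start_s,trial_end_s Times the blanks refer to; default the
#'   first phase start and last phase end.
#' @return `slopes` with `slope_mg_l_h` corrected and a `background_mg_l_h`
#'   column recording what was subtracted.
#' @export
correct_background <- function(slopes, blank_pre = NA_real_, blank_post = NA_real_,
                               trial_start_s = NULL, trial_end_s = NULL) {
  blank_pre <- blank_pre %||% NA_real_
  blank_post <- blank_post %||% NA_real_
  if (is.na(blank_pre) && is.na(blank_post)) {
    warn("No blank slopes supplied; background correction skipped.")
    return(dplyr::mutate(slopes, background_mg_l_h = 0))
  }
  if (is.na(blank_pre)) blank_pre <- blank_post
  if (is.na(blank_post)) blank_post <- blank_pre
  t0 <- trial_start_s %||% min(slopes$start_s)
  t1 <- trial_end_s %||% max(slopes$end_s)
  mid <- (slopes$start_s + slopes$end_s) / 2
  frac <- if (t1 > t0) (mid - t0) / (t1 - t0) else rep(0, length(mid))
  bg <- blank_pre + frac * (blank_post - blank_pre)
  dplyr::mutate(slopes,
                background_mg_l_h = bg,
                slope_mg_l_h = .data$slope_mg_l_h - bg)
}

#' Convert oxygen-depletion slopes to mass-specific uptake rates
#'
#' \eqn{\dot{M}O_2 = |slope| (V_{resp} - V_{fish}) / m}: the depletion rate
#' scaled by the effective water volume (chamber minus fish body volume)
#' and normalised by fish mass. Hypoxic phases are dropped.
#'
#' @param slopes Tibble from [extract_phase_slopes()] (background-corrected
#'   or not).
#' @param trace The [respirometry_trace()] the slopes came from (supplies
#'   volumes and mass).
#' @return `slopes` with hypoxic phases removed and a new `mo2` column,
#'   mg O2 kg^-1 h^-1.
#' @export
slope_to_mo2 <- function(slopes, trace) {
  meta <- trace_meta(trace)
  if (meta$fish_volume >= meta$respirometer_volume) {
    abort("`fish_volume` must be smaller than `respirometer_volume`.")
  }
  eff_vol <- meta$respirometer_volume - meta$fish_volume
  slopes |>
    dplyr::filter(!.data$hypoxic) |>
    dplyr::mutate(mo2 = abs(.data$slope_mg_l_h) * eff_vol / meta$fish_mass)
}

#' Maximal metabolic rate from an ordered series of phase rates
#'
#' Fish are chased to exhaustion and placed in the chamber immediately, so
#' the first closed phase captures the highest aerobic rate; subsequent
#' phases track recovery. The default therefore returns the first phase's
#' rate. `mode = "max"` (the maximum over all phases) is available for
#' protocols where the peak can occur later.
#'
#' @param mo2 Numeric vector of per-phase rates, ordered in time, starting
#'   at the first post-chase closed phase.
#' @param mode `"first"` (default) or `"max"`.
#' @return Single rate, mg O2 kg^-1 h^-1.
#' @export
estimate_mmr <- function(mo2, mode = c("first", "max")) {
  mode <- match.arg(mode)
  mo2 <- mo2[!is.na(mo2)]
  if (!length(mo2)) abort("Empty rate series: cannot estimate MMR.")
  switch(mode, first = mo2[[1]], max = max(mo2))
}

#' Standard metabolic rate as the 15th percentile of the rate series
#'
#' Over a ~24 h trial most closed phases record routine activity and
#' digestion on top of maintenance; a low quantile of the per-phase rates
#' estimates the maintenance floor. The 0.15 quantile is computed with
#' linear interpolation between order statistics at rank position
#' (n - 1) q (quantile type 7).
#'
#' @param mo2 Numeric vector of per-phase rates.
#' @param prob Quantile (default 0.15).
#' @param min_n Minimum number of rates expected for a stable estimate
#'   (default 10); fewer triggers a warning but still returns the quantile.
#' @return Single rate, mg O2 kg^-1 h^-1.
#' @export
estimate_smr <- function(mo2, prob = 0.15, min_n = 10) {
  mo2 <- mo2[!is.na(mo2)]
  if (!length(mo2)) abort("Empty rate series: cannot estimate SMR.")
  if (length(mo2) < min_n) {
    warn(sprintf("Only %d rates available (< %d); SMR estimate may be unstable.",
                 length(mo2), min_n))
  }
  unname(quantile(mo2, probs = prob, type = 7))
}

#' Process one respirometry trace into a metabolic record
#'
#' Runs the full per-fish chain: slope extraction, background correction,
#' conversion to rates, MMR from the first post-chase phase and SMR as the
#' 15th percentile, and MS = MMR - SMR. Records with MMR < SMR are rejected
#' (scope cannot be negative at a viable acclimation temperature; such
#' records indicate a failed trial).
#'
#' @param trace A [respirometry_trace()].
#' @param blank_pre,blank_post Optional background slopes, mg O2 l^-1 h^-1.
#' @param trim_minutes,min_saturation Passed to [extract_phase_slopes()].
#' @param mmr_mode Passed to [estimate_mmr()].
#' @return A one-row tibble: `fish_id`, `species`, `acclim_temp_c`, `mmr`,
#'   `smr`, `ms`, `mass_kg` — or a zero-row tibble (with a warning) when
#'   the record is rejected.
#' @export
process_trace <- function(trace, blank_pre = 0, blank_post = 0,
                          trim_minutes = 2, min_saturation = 80,
                          mmr_mode = "first") {
  meta <- trace_meta(trace)
  slopes <- extract_phase_slopes(trace, trim_minutes = trim_minutes,
                                 min_saturation = min_saturation)
  slopes <- correct_background(slopes, blank_pre, blank_post)
  rates <- slope_to_mo2(slopes, trace)
  if (!nrow(rates)) abort("All closed phases were hypoxic; no rates available.")
  mmr <- estimate_mmr(rates$mo2, mode = mmr_mode)
  smr <- estimate_smr(rates$mo2)
  rec <- tibble::tibble(
    fish_id = meta$fish_id,
    species = meta$species,
    acclim_temp_c = mean(trace$temp_c),
    mmr = mmr, smr = smr, ms = mmr - smr,
    mass_kg = meta$fish_mass
  )
  if (rec$mmr < rec$smr) {
    warn(sprintf("Fish %s: MMR < SMR; record rejected.", meta$fish_id))
    return(rec[0, ])
  }
  rec
}
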