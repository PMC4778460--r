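#' Specification for a synthetic respirometry trace
#'
#' Describes one fish's ~24 h intermittent-flow trial with known ground
#' truth. Instantaneous uptake decays exponentially from `true_mmr`
#' (immediately after the exhaustive chase) towards `true_smr` with the
#' given time constant, with a small diel modulation; oxygen in the chamber
#' declines accordingly during closed phases and is restored during flush
#' phases.
#'
#' @param true_smr,true_mmr Ground-truth rates, mg O2 kg^-1 h^-1
#'   (`true_mmr >= true_smr > 0`).
#' @param recovery_time_constant Hours; e-folding time of post-chase
#'   recovery (default 1.5 h, typical of small sparids).
#' @param closed_minutes,flush_minutes Cycle structure (default 15/15).
#' @param sample_interval_s Sampling interval, seconds (default 15).
#' @param noise_sd Gaussian sd of oxygen samples, mg O2 l^-1 (default 0.01).
#' @param diel_amplitude Relative amplitude of the diel modulation of
#'   routine rate (default 0.05).
#' @param background_slope Microbial background depletion, mg O2 l^-1 h^-1
#'   (negative; default 0).
#' @param duration_hours Trial length (default 24).
#' @param o2_saturation_mg_l Air-saturated oxygen concentration used for
#'   flushes, mg O2 l^-1 (default 8).
#' @param temperature Trial temperature, degrees C (default 20).
#' @param respirometer_volume Chamber volume, litres (default 0.5, a
#'   static chamber for small juveniles).
#' @param fish_mass Fish mass, kg (default 0.005). The default mass is
#'   chosen so that even a closed phase at maximal rate depletes less than
#'   ~20% of saturation in the 0.5 l chamber, keeping the whole trial
#'   inside the normoxic (> 80% saturation) window the protocol requires;
#'   heavier fish in the same chamber drive phases hypoxic and they are
#'   then excluded by [extract_phase_slopes()].
#' @param seed Integer seed; every generator is a pure function of its
#'   spec + seed.
#' @return A list of class `trace_spec`.
#' @export
trace_spec <- function(true_smr, true_mmr, recovery_time_constant = 1.5,
                       closed_minutes = 15, flush_minutes = 15,
                       sample_interval_s = 15, noise_sd = 0.01,
                       diel_amplitude = 0.05, background_slope = 0,
                       duration_hours = 24, o2_saturation_mg_l = 8,
                       temperature = 20, respirometer_volume = 0.5,
                       fish_mass = 0.005, seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (!(true_mmr >= true_smr && true_smr > 0)) {
    abort("Need `true_mmr` >= `true_smr` > 0.")
  }
  structure(as.list(environment()), class = "trace_spec")
}

#' Generate a synthetic respirometry trace
#'
#' @param spec A [trace_spec()].
#' @param fish_id,species Labels for the resulting trace.
#' @return A [respirometry_trace()] whose processing recovers the spec's
#'   ground-truth rates (up to noise and quantile bias).
#' @export
#' @examples
#' tr <- generate_trace(trace_spec(true_smr = 150, true_mmr = 600, seed = 42))
#' process_trace(tr)
generate_trace <- function(spec, fish_id = "fish_1", species = "salema") {
  stopifnot(inherits(spec, "trace_spec"))
  withr::with_seed(spec$seed, {
    dt <- spec$sample_interval_s
    times <- seq(0, spec$duration_hours * 3600 - dt, by = dt)
    cycle_s <- (spec$closed_minutes + spec$flush_minutes) * 60
    in_cycle <- times %% cycle_s
    phase <- ifelse(in_cycle < spec$closed_minutes * 60, "closed", "flush")
    t_h <- times / 3600
    mo2 <- spec$true_smr * (1 + spec$diel_amplitude * sin(2 * pi * t_h / 24)) +
      (spec$true_mmr - spec$true_smr) * exp(-t_h / spec$recovery_time_constant)
    eff_vol <- spec$respirometer_volume - spec$fish_mass / 1.0
    depletion <- -mo2 * spec$fish_mass / eff_vol + spec$background_slope # mg/l/h
    o2 <- numeric(length(times))
    cur <- spec$o2_saturation_mg_l
    for (i in seq_along(times)) {
      if (phase[i] == "flush") {
        cur <- spec$o2_saturation_mg_l
      } else if (i > 1 && phase[i - 1] == "closed") {
        cur <- cur + depletion[i - 1] * dt / 3600
      }
      o2[i] <- cur
    }
    o2_obs <- pmax(o2 + rnorm(length(o2), sd = spec$noise_sd), 0.05)
    respirometry_trace(
      tibble::tibble(
        time_s = times,
        o2_mg_l = o2_obs,
        o2_sat_pct = 100 * o2_obs / spec$o2_saturation_mg_l,
        temp_c = spec$temperature,
        phase = phase
      ),
      fish_id = fish_id, species = species,
      respirometer_volume = spec$respirometer_volume,
      fish_mass = spec$fish_mass
    )
  })
}

#' Specification of a multi-temperature acclimation experiment
#'
#' The emulated design acclimates groups of fish to a ladder of
#' temperatures (default 17, 20, 23, 26, 29, 32 degrees C, 12 fish per
#' group) and records each fish's MMR and SMR. With the mortality rule on,
#' groups acclimated above the species' critical temperature have no
#' survivors and yield no records — an all-or-nothing rule matching the
#' observed loss of whole warm-acclimated groups.
#'
#' @param params Generating [performance_params()].
#' @param temperatures Acclimation temperatures, degrees C.
#' @param n_per_group Fish per temperature group (default 12).
#' @param cv Coefficient of variation of the per-fish log-normal noise on
#'   MMR and SMR (default 0.15, a realistic inter-individual spread).
#' @param mortality Apply the critical-temperature mortality rule
#'   (default TRUE).
#' @param mean_mass_kg,mass_cv Body-mass distribution (log-normal).
#' @param seed Integer seed.
#' @return A list of class `design_spec`.
#' @export
design_spec <- function(params, temperatures = c(17, 20, 23, 26, 29, 32),
                        n_per_group = 12, cv = 0.15, mortality = TRUE,
                        mean_mass_kg = 0.019, mass_cv = 0.3, seed = 1L) {
  params <- as_performance_params(params)
  if (n_per_group < 1) abort("`n_per_group` must be >= 1.")
  if (cv < 0) abort("`cv` must be non-negative.")
  structure(as.list(environment()), class = "design_spec")
}

#' Generate a synthetic multi-temperature metabolic dataset
#'
#' Per fish, MMR and SMR are drawn log-normally around the generating
#' curves' values at the group temperature, with the spec's CV and the
#' log-normal mean preserved (so CV = 0 reproduces the curve values
#' exactly). With the mortality rule disabled, groups beyond the critical
#' temperature are generated anyway and carry negative scope (`ms` < 0):
#' MMR and SMR are genuine positive rates there even though their
#' difference is non-viable, and the two curves are fitted separately, so
#' such counterfactual records are what identify the MMR zero point `t_m`
#' in recovery studies. Trace processing ([process_trace()]), by contrast,
#' rejects measured records with MMR < SMR as failed trials.
#'
#' @param spec A [design_spec()].
#' @return Tibble of metabolic records (`fish_id`, `species`,
#'   `acclim_temp_c`, `mmr`, `smr`, `ms`, `mass_kg`).
#' @export
#' @examples
#' recs <- generate_metabolic_dataset(design_spec(species_params("salema"), seed = 7))
#' dplyr::count(recs, acclim_temp_c)  # no survivors above T_crit
generate_metabolic_dataset <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  p <- spec$params
  t_crit <- curve_summary(p)$t_crit
  withr::with_seed(spec$seed, {
    rows <- purrr::map(spec$temperatures, function(temp) {
      if (spec$mortality && temp > t_crit) return(NULL)
      mmr0 <- mmr_curve(temp, p)
      smr0 <- smr_curve(temp, p)
      s <- sqrt(log(1 + spec$cv^2))
      sm <- sqrt(log(1 + spec$mass_cv^2))
      n <- spec$n_per_group
      tibble::tibble(
        fish_id = sprintf("%s_T%g_%02d", p$species %||% "fish", temp, seq_len(n)),
        species = p$species,
        acclim_temp_c = temp,
        mmr = mmr0 * rlnorm(n, meanlog = -s^2 / 2, sdlog = s),
        smr = smr0 * rlnorm(n, meanlog = -s^2 / 2, sdlog = s),
        mass_kg = spec$mean_mass_kg * rlnorm(n, meanlog = -sm^2 / 2, sdlog = sm)
      )
    })
    out <- dplyr::bind_rows(rows)
    dplyr::mutate(out, ms = .data$mmr - .data$smr, .after = "smr")
  })
}

#' Specification of a synthetic coastal temperature climatology
#'
#' Emulates a decade of daily 0-30 m temperatures over a lon/lat box with a
#' north-south gradient: the annual mean and the seasonal amplitude are
#' linear in latitude (warm wide-ranging south, cool damped north), with
#' AR(1) day-to-day anomalies. The defaults span monthly-mean temperatures
#' of roughly 13-31 degrees C, a warm-temperate shelf-sea envelope, and a
#' future warming increment between `delta_range[1]` and `delta_range[2]`
#' degrees C that varies smoothly in space and by month.
#'
#' @param lon_range,lat_range Domain edges, degrees (default 8.5-16.5 E,
#'   31.2-39.5 N).
#' @param nlon,nlat Grid size (default 40 x 40).
#' @param years Scenario length in years (default 10).
#' @param mean_south,mean_north Annual-mean temperature at the southern /
#'   northern edge, degrees C (defaults 23.7 / 17.6).
#' @param amp_south,amp_north Seasonal half-amplitude at the edges,
#'   degrees C (defaults 7.5 / 4.5).
#' @param peak_doy Day-of-year of the seasonal maximum (default 226,
#'   mid-August).
#' @param noise_sd,ar1 Daily anomaly sd (degrees C) and lag-1
#'   autocorrelation (defaults 0.5, 0.8).
#' @param delta_range Range of the monthly future increments, degrees C
#'   (default c(0.2, 1.5)).
#' @param start_date First day of the present scenario (default
#'   "2001-01-01").
#' @param seed Integer seed.
#' @return A list of class `ocean_spec`.
#' @export
ocean_spec <- function(lon_range = c(8.5, 16.5), lat_range = c(31.2, 39.5),
                       nlon = 40, nlat = 40, years = 10,
                       mean_south = 23.7, mean_north = 17.6,
                       amp_south = 7.5, amp_north = 4.5,
                       peak_doy = 226, noise_sd = 0.5, ar1 = 0.8,
                       delta_range = c(0.2, 1.5),
                       start_date = "2001-01-01", seed = 1L) {
  if (lon_range[1] >= lon_range[2] || lat_range[1] >= lat_range[2]) {
    abort("Inverted `lon_range`/`lat_range` box.")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  structure(as.list(environment()), class = "ocean_spec")
}

#' Generate a synthetic daily temperature field
#'
#' The present-day field is latitudinal mean + seasonal sinusoid + AR(1)
#' daily anomalies, all deterministic under the spec's seed. The future
#' field is the present field plus per-cell monthly increments drawn within
#' `delta_range` and interpolated from a coarse random surface so they vary
#' smoothly in space; the increments are attached to either return value as
#' attribute `"delta"` (a [scenario_delta()]), and
#' `apply_delta_scenario(present, delta)` reproduces the future field
#' exactly.
#'
#' @param spec An [ocean_spec()].
#' @param scenario `"present"` or `"future"`.
#' @return A [gridded_field()] with attribute `delta`.
#' @export
#' @examples
#' fld <- generate_temperature_field(ocean_spec(nlon = 6, nlat = 6, years = 1, seed = 3))
generate_temperature_field <- function(spec, scenario = c("present", "future")) {
  stopifnot(inherits(spec, "ocean_spec"))
  scenario <- match.arg(scenario)
  lon <- seq(spec$lon_range[1], spec$lon_range[2], length.out = spec$nlon)
  lat <- seq(spec$lat_range[1], spec$lat_range[2], length.out = spec$nlat)
  time <- seq(as.Date(spec$start_date), by = "day",
              length.out = round(spec$years * 365.25))
  doy <- as.POSIXlt(time)$yday + 1
  frac <- (lat - spec$lat_range[1]) / diff(spec$lat_range)
  mean_lat <- spec$mean_south + frac * (spec$mean_north - spec$mean_south)
  amp_lat <- spec$amp_south + frac * (spec$amp_north - spec$amp_south)
  ncell <- spec$nlon * spec$nlat
  nt <- length(time)
  present <- withr::with_seed(spec$seed, {
    seasonal <- outer(amp_lat, cos(2 * pi * (doy - spec$peak_doy) / 365.25)) # nlat x nt
    base <- array(0, dim = c(spec$nlon, spec$nlat, nt))
    for (j in seq_len(spec$nlat)) {
      base[, j, ] <- rep(mean_lat[j] + seasonal[j, ], each = spec$nlon)
    }
    if (spec$noise_sd > 0) {
      innov_sd <- spec$noise_sd * sqrt(1 - spec$ar1^2)
      e <- rnorm(ncell, sd = spec$noise_sd)
      noise <- matrix(0, nrow = ncell, ncol = nt)
      for (t in seq_len(nt)) {
        e <- spec$ar1 * e + rnorm(ncell, sd = innov_sd)
        noise[, t] <- e
      }
      base <- base + array(noise, dim = dim(base))
    }
    base
  })
  delta <- generate_delta(spec, lon, lat)
  fld <- gridded_field(lon, lat, time, present)
  if (scenario == "future") fld <- apply_delta_scenario(fld, delta)
  attr(fld, "delta") <- delta
  fld
}

# Smooth monthly warming increments: coarse uniform random surface per
# month, bilinearly interpolated to the grid, scaled into delta_range.
generate_delta <- function(spec, lon, lat) {
  withr::with_seed(spec$seed + 1000L, {
    coarse <- array(runif(4 * 4 * 12), dim = c(4, 4, 12))
    vals <- array(NA_real_, dim = c(length(lon), length(lat), 12))
    cx <- seq(0, 1, length.out = 4)
    gx <- seq(0, 1, length.out = length(lon))
    gy <- seq(0, 1, length.out = length(lat))
    for (m in 1:12) {
      rowinterp <- apply(coarse[, , m], 2, function(col) {
        stats::approx(cx, col, xout = gx)$y
      }) # nlon x 4
      vals[, , m] <- t(apply(rowinterp, 1, function(row) {
        stats::approx(cx, row, xout = gy)$y
      }))
    }
    vals <- spec$delta_range[1] + diff(spec$delta_range) * vals
    scenario_delta(lon, lat, vals)
  })
}

#' Sample synthetic occurrence points from suitable habitat
#'
#' Draws `n` occurrence locations uniformly from the grid cells whose THS
#' is at least `min_ths` (points sit at cell centres). Used to exercise
#' [derive_threshold()] with a known construction: with coverage 1 the
#' derived threshold is at least `min_ths`.
#'
#' @param ths A [compute_ths()] map.
#' @param n Number of points (default 100).
#' @param min_ths Minimum suitability of occupied cells (default 0.62).
#' @param seed Integer seed.
#' @return Tibble with columns `lon`, `lat`.
#' @export
generate_occurrences <- function(ths, n = 100, min_ths = 0.62, seed = 1L) {
  stopifnot(inherits(ths, "suitability_map"))
  ok <- which(!is.na(ths$ths) & ths$ths >= min_ths, arr.ind = TRUE)
  if (!nrow(ok)) abort(sprintf("No cells with THS >= %g.", min_ths))
  withr::with_seed(seed, {
    pick <- ok[sample.int(nrow(ok), n, replace = TRUE), , drop = FALSE]
    tibble::tibble(lon = ths$lon[pick[, 1]], lat = ths$lat[pick[, 2]])
  })
}
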