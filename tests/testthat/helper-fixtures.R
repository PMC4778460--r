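# Canonical parameter sets, constructed directly from their published values
# so tests do not depend on the packaged JSON fixture being intact.
salema_params <- function() {
  performance_params(a = 190.2, b = 0.067, omega = 1.4, delta = 6931.1,
                     t_m = 32.8, t_act = 24.3, species = "salema")
}

spinefoot_params <- function() {
  performance_params(a = 176.7, b = 0.050, omega = 1.3, delta = 6762.2,
                     t_m = 42.7, t_act = 32.2, species = "spinefoot")
}

# Minimal hand-built trace: closed/flush cycle with an exactly linear O2
# decline of `slope` mg/l/h during closed phases.
linear_trace <- function(n_cycles = 2, slope = -0.6, o2_start = 8,
                         closed_min = 15, flush_min = 15, dt_s = 15,
                         temp = 20, sat_mg_l = 8,
                         volume = 0.5, mass = 0.02, fish_volume = 0.02) {
  cycle_s <- (closed_min + flush_min) * 60
  times <- seq(0, n_cycles * cycle_s - dt_s, by = dt_s)
  in_cycle <- times %% cycle_s
  phase <- ifelse(in_cycle < closed_min * 60, "closed", "flush")
  o2 <- ifelse(phase == "closed", o2_start + slope * (in_cycle / 3600), o2_start)
  respirometry_trace(
    tibble::tibble(time_s = times, o2_mg_l = o2,
                   o2_sat_pct = 100 * o2 / sat_mg_l,
                   temp_c = temp, phase = phase),
    fish_id = "f1", species = "salema",
    respirometer_volume = volume, fish_mass = mass, fish_volume = fish_volume
  )
}

# Suitability map with prescribed THS values (column-major over the grid).
new_map_for_test <- function(ths_vals, nlon = 2, nlat = 2) {
  structure(
    list(lon = seq_len(nlon), lat = 30 + seq_len(nlat),
         ths = matrix(ths_vals, nrow = nlon, ncol = nlat),
         species = "test", ms_max = 1,
         cell_area = matrix(1, nrow = nlon, ncol = nlat)),
    class = "suitability_map"
  )
}

# One-depth gridded field with constant-per-day temperatures.
flat_field <- function(temps, lon = c(10, 11), lat = c(35, 36),
                       start = "2001-01-01") {
  nt <- length(temps)
  vals <- array(rep(temps, each = length(lon) * length(lat)),
                dim = c(length(lon), length(lat), nt))
  gridded_field(lon, lat, seq(as.Date(start), by = "day", length.out = nt), vals)
}
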