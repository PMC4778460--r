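make_depth_field <- function(layer_temps, depth, depth_bounds) {
  nd <- length(depth)
  vals <- array(rep(layer_temps, each = 4), dim = c(2, 2, nd, 1))
  gridded_field(c(10, 11), c(35, 36), as.Date("2001-06-01"), vals,
                depth = depth, depth_bounds = depth_bounds)
}

test_that("depth averaging weights layers by thickness above z_max", {
  eq <- make_depth_field(c(20, 22, 24), depth = c(5, 15, 25),
                         depth_bounds = c(0, 10, 20, 30))
  expect_equal(unique(as.vector(depth_average_temperature(eq, 30)$values)), 22)
  uneq <- make_depth_field(c(20, 23), depth = c(2.5, 17.5),
                           depth_bounds = c(0, 5, 30))
  expect_equal(unique(as.vector(depth_average_temperature(uneq, 30)$values)),
               (5 * 20 + 25 * 23) / 30)
  single <- make_depth_field(21.5, depth = 5, depth_bounds = c(0, 10))
  expect_equal(as.vector(depth_average_temperature(single, 30)$values), rep(21.5, 4))
  deep <- make_depth_field(c(20, 23), depth = c(45, 55), depth_bounds = c(40, 50, 60))
  expect_error(depth_average_temperature(deep, 30), "No layers")
})

test_that("layers straddling z_max contribute only their upper part", {
  fld <- make_depth_field(c(20, 24), depth = c(10, 30), depth_bounds = c(0, 20, 40))
  # 20 m at 20 degrees plus the 20-30 m slice of the lower layer
  expect_equal(unique(as.vector(depth_average_temperature(fld, 30)$values)),
               (20 * 20 + 10 * 24) / 30)
})

test_that("delta scenarios shift by month and preserve daily anomalies", {
  spec <- ocean_spec(nlon = 4, nlat = 4, years = 1, seed = 8)
  pres <- generate_temperature_field(spec, "present")
  delta <- attr(pres, "delta")
  zero <- scenario_delta(pres$lon, pres$lat, array(0, dim = c(4, 4, 12)))
  expect_equal(apply_delta_scenario(pres, zero)$values, pres$values)
  fut <- apply_delta_scenario(pres, delta)
  month <- as.POSIXlt(pres$time)$mon + 1
  jul <- which(month == 7)
  expect_equal(fut$values[2, 3, jul[1]],
               pres$values[2, 3, jul[1]] + delta$values[2, 3, 7])
  # shift invariance: within-month variance of daily values is untouched
  for (m in c(1, 7, 12)) {
    idx <- which(month == m)
    expect_equal(apply(fut$values[, , idx], c(1, 2), var),
                 apply(pres$values[, , idx], c(1, 2), var))
  }
  off <- scenario_delta(pres$lon + 1, pres$lat, array(0, dim = c(4, 4, 12)))
  expect_error(apply_delta_scenario(pres, off), "aligned")
})

test_that("THS normalisation hits its anchor values", {
  p <- salema_params()
  cs <- curve_summary(p)
  expect_equal(unique(as.vector(compute_ths(flat_field(rep(cs$t_opt, 4)), p)$ths)),
               1, tolerance = 1e-6)
  expect_equal(unique(as.vector(compute_ths(flat_field(rep(cs$t_crit + 1, 4)), p)$ths)),
               0)
  half <- flat_field(c(rep(cs$t_opt, 5), rep(cs$t_crit + 1, 5)))
  expect_equal(unique(as.vector(compute_ths(half, p)$ths)), 0.5, tolerance = 1e-6)
})

test_that("single-cell single-day THS equals the normalised scope oracle", {
  p <- spinefoot_params()
  cs <- curve_summary(p)
  for (temp in c(18, 25, 31, 36, 40)) {
    vals <- array(temp, dim = c(1, 1, 1))
    fld <- gridded_field(10, 35, as.Date("2001-01-01"), vals)
    expect_equal(as.vector(compute_ths(fld, p)$ths),
                 normalized_ms(temp, p, cs$ms_max))
  }
})

test_that("THS stays within [0,1] on random fields and respects the land mask", {
  p <- salema_params()
  for (seed in 1:5) {
    set.seed(seed)
    vals <- array(runif(5 * 4 * 30, -2, 45), dim = c(5, 4, 30))
    vals[2, 3, ] <- NA  # land cell
    fld <- gridded_field(1:5, 31:34, seq(as.Date("2001-01-01"), by = "day",
                                         length.out = 30), vals)
    ths <- compute_ths(fld, p)
    expect_true(all(ths$ths[!is.na(ths$ths)] >= 0 & ths$ths[!is.na(ths$ths)] <= 1))
    expect_true(is.na(ths$ths[2, 3]))
  }
  bad <- array(20, dim = c(2, 2, 3)); bad[1, 1, 2] <- NA
  fld_bad <- gridded_field(1:2, 31:32, seq(as.Date("2001-01-01"), by = "day",
                                           length.out = 3), bad)
  expect_error(compute_ths(fld_bad, p), "mask varies")
})

test_that("warming shifts THS monotonically on either side of the optimum", {
  p <- salema_params()
  cs <- curve_summary(p)
  below <- flat_field(seq(12, 18, length.out = 6))   # entirely below t_opt
  above <- flat_field(seq(24, 27, length.out = 6))   # entirely above t_opt
  dlt <- scenario_delta(below$lon, below$lat, array(1, dim = c(2, 2, 12)))
  expect_true(all(compute_ths(apply_delta_scenario(below, dlt), p)$ths >=
                    compute_ths(below, p)$ths))
  expect_true(all(compute_ths(apply_delta_scenario(above, dlt), p)$ths <=
                    compute_ths(above, p)$ths))
})

test_that("threshold derivation is the coverage quantile of occurrence THS", {
  set.seed(13)
  vals <- array(runif(100, 10, 30), dim = c(10, 10, 1))
  fld <- gridded_field(seq(8, 17, 1), seq(31, 40, 1), as.Date("2001-07-01"), vals)
  ths <- compute_ths(fld, salema_params())
  occ <- generate_occurrences(ths, n = 100, min_ths = 0.3, seed = 7)
  ix <- vapply(occ$lon, function(v) which.min(abs(ths$lon - v)), integer(1))
  iy <- vapply(occ$lat, function(v) which.min(abs(ths$lat - v)), integer(1))
  sampled <- ths$ths[cbind(ix, iy)]
  expect_equal(derive_threshold(ths, occ, coverage = 0.95),
               unname(quantile(sampled, 0.05, type = 7)))
  expect_equal(derive_threshold(ths, occ, coverage = 1), min(sampled))
  expect_gte(derive_threshold(ths, occ, coverage = 1), 0.3)
  one <- occ[1, ]
  expect_equal(derive_threshold(ths, one, coverage = 0.95), sampled[1])
})

test_that("occurrences on land are excluded, and all-land input errors", {
  vals <- array(20, dim = c(3, 3, 2)); vals[1, 1, ] <- NA
  fld <- gridded_field(1:3, 31:33, as.Date("2001-01-01") + 0:1, vals)
  ths <- compute_ths(fld, salema_params())
  occ <- tibble::tibble(lon = c(1, 2), lat = c(31, 32))
  expect_warning(t_ms <- derive_threshold(ths, occ, coverage = 1), "land")
  expect_equal(t_ms, ths$ths[2, 2])
  expect_error(suppressWarnings(
    derive_threshold(ths, tibble::tibble(lon = 1, lat = 31))), "masked")
})

test_that("QMS uses a strict threshold with ties counting as unsuitable", {
  ths <- new_map_for_test(c(0.70, 0.62, 0.10, NA))
  qms <- compute_qms(ths, 0.62)
  expect_equal(as.vector(qms$qms), c(1, 0, 0, NA))
  expect_error(compute_qms(ths, 1.2), "in \\(0, 1\\)")
})

test_that("CF is the signed difference of masks and antisymmetric under swap", {
  a <- compute_qms(new_map_for_test(c(1, 1, 0, 0) * 0.9 + 0.05), 0.5)
  b <- compute_qms(new_map_for_test(c(1, 0, 1, 0) * 0.9 + 0.05), 0.5)
  cf <- compute_cf(a, b)
  expect_equal(as.vector(cf$cf), c(0, 1, -1, 0))
  expect_equal(compute_cf(b, a)$cf, -cf$cf)
  expect_true(all(cf$cf %in% c(-1, 0, 1)))
})

test_that("coexistence area fractions are area-weighted and sum to 100", {
  cf_vals <- c(rep(1, 3), rep(0, 6), -1)
  maps <- replicate(2, new_map_for_test(rep(0.5, 10), nlon = 10, nlat = 1),
                    simplify = FALSE)
  qa <- compute_qms(maps[[1]], 0.4); qb <- compute_qms(maps[[2]], 0.4)
  cf <- compute_cf(qa, qb)
  cf$cf <- matrix(cf_vals, nrow = 10)
  area1 <- matrix(1, nrow = 10, ncol = 1)
  s <- summarize_coexistence(cf, cell_area = area1)
  expect_equal(c(s$cf_gt0_pct, s$cf_eq0_pct, s$cf_lt0_pct), c(30, 60, 10))
  expect_equal(s$cf_lt0_pct + s$cf_eq0_pct + s$cf_gt0_pct, 100, tolerance = 1e-9)
  # doubling all areas changes nothing
  expect_equal(summarize_coexistence(cf, cell_area = 2 * area1), s)
  cf0 <- cf; cf0$cf <- matrix(0, nrow = 10)
  s0 <- summarize_coexistence(cf0, cell_area = area1)
  expect_equal(c(s0$cf_lt0_pct, s0$cf_eq0_pct, s0$cf_gt0_pct), c(0, 100, 0))
})

test_that("tidying maps yields long tibbles without land cells", {
  vals <- array(22, dim = c(2, 2, 3)); vals[1, 2, ] <- NA
  fld <- gridded_field(c(10, 11), c(35, 36), as.Date("2001-01-01") + 0:2, vals)
  ths <- compute_ths(fld, salema_params())
  td <- tidy(ths)
  expect_identical(nrow(td), 3L)
  expect_true(all(c("lon", "lat", "ths", "species") %in% names(td)))
})
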