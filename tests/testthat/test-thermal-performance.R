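test_that("curve evaluation matches the closed forms at anchor temperatures", {
  sal <- salema_params()
  # MMR is exactly zero at t_m and peaks at t_act with value delta * exp(-omega)
  expect_identical(mmr_curve(32.8, sal), 0)
  expect_equal(mmr_curve(24.3, sal), 6931.1 * exp(-1.4))
  expect_equal(mmr_curve(24.3, sal), 1709.2, tolerance = 1e-4)
  expect_equal(smr_curve(17, sal), 190.2 * exp(0.067 * 17))
  expect_equal(smr_curve(17, sal), 594.1, tolerance = 1e-4)
  # beyond t_m the MMR branch is defined as zero, so MS = -SMR
  expect_equal(ms_curve(35, sal), -smr_curve(35, sal))
})

test_that("vectorised evaluation equals element-wise scalar calls", {
  p <- spinefoot_params()
  grid <- seq(5, 45, by = 2.5)
  expect_equal(evaluate_curves(grid, p)$ms,
               vapply(grid, function(T) ms_curve(T, p), numeric(1)))
  expect_error(evaluate_curves(c(20, Inf), p), "finite")
})

test_that("MMR peak and zero hold for random valid parameter sets", {
  set.seed(4)
  for (i in 1:20) {
    p <- performance_params(a = runif(1, 50, 300), b = runif(1, 0.02, 0.1),
                            omega = runif(1, 0.5, 3), delta = runif(1, 2000, 9000),
                            t_m = runif(1, 30, 45), t_act = runif(1, 15, 28))
    expect_identical(mmr_curve(p$t_m, p), 0)
    near <- mmr_curve(p$t_act + c(-0.01, 0, 0.01), p)
    expect_equal(near[2], p$delta * exp(-p$omega))
    expect_true(near[2] >= near[1] && near[2] >= near[3])
    # SMR strictly increasing in temperature
    expect_true(all(diff(smr_curve(seq(0, 40, 0.5), p)) > 0))
  }
})

test_that("curve summaries order t_opt < t_crit < t_m and detect non-viable sets", {
  for (p in list(salema_params(), spinefoot_params())) {
    cs <- curve_summary(p)
    expect_lt(cs$t_opt, cs$t_crit)
    expect_lt(cs$t_crit, p$t_m)
    expect_equal(cs$ms_max, ms_curve(cs$t_opt, p))
    expect_gt(cs$ms_max, 0)
  }
  dead <- performance_params(a = 5000, b = 0.067, omega = 1.4, delta = 6931.1,
                             t_m = 32.8, t_act = 24.3)
  expect_error(curve_summary(dead), "non-viable")
})

test_that("SMR fit recovers generating parameters from noiseless data", {
  recs <- generate_metabolic_dataset(design_spec(salema_params(), cv = 0,
                                                 mortality = FALSE, seed = 1))
  fit <- fit_smr(recs)
  expect_equal(unname(fit$estimate[["a"]]), 190.2, tolerance = 1e-6)
  expect_equal(unname(fit$estimate[["b"]]), 0.067, tolerance = 1e-6)
  expect_error(fit_smr(recs[recs$acclim_temp_c %in% c(17, 20), ]), "3 distinct")
})

test_that("SMR fit degrades gracefully to a constant for temperature-free data", {
  set.seed(31)
  recs <- tibble::tibble(acclim_temp_c = rep(c(10, 20, 30), each = 4),
                         smr = 250 * exp(rnorm(12, sd = 1e-4)))
  fit <- fit_smr(recs)
  expect_lt(abs(fit$estimate[["b"]]), 1e-4)
  expect_equal(unname(fit$estimate[["a"]]), 250, tolerance = 1e-3)
})

test_that("MMR fit recovers generating parameters from noiseless data", {
  recs <- generate_metabolic_dataset(design_spec(spinefoot_params(), cv = 0, seed = 1))
  fit <- fit_mmr(recs)
  truth <- c(delta = 6762.2, omega = 1.3, t_m = 42.7, t_act = 32.2)
  for (nm in names(truth)) {
    expect_equal(unname(fit$estimate[[nm]]), unname(truth[[nm]]),
                 tolerance = 1e-6, label = nm)
  }
  expect_false(fit$boundary)
  expect_error(fit_mmr(recs[recs$acclim_temp_c < 29, ]), "5 distinct")
})

test_that("noiseless generate-fit-summarise round trip reproduces the curve summary", {
  for (p in list(salema_params(), spinefoot_params())) {
    recs <- generate_metabolic_dataset(design_spec(p, cv = 0, mortality = FALSE, seed = 2))
    refit <- combine_fits(fit_smr(recs), fit_mmr(recs), species = p$species)
    cs0 <- curve_summary(p)
    cs1 <- curve_summary(refit)
    expect_equal(cs1$t_opt, cs0$t_opt, tolerance = 2e-3 / cs0$t_opt)
    expect_equal(cs1$t_crit, cs0$t_crit, tolerance = 2e-3 / cs0$t_crit)
  }
})

test_that("through-origin validation slope behaves as the closed form requires", {
  x <- c(100, 250, 400, 700)
  ident <- validate_predictions(x, x)
  expect_equal(ident$slope, 1)
  expect_equal(ident$r2, 1)
  expect_equal(validate_predictions(2 * x, x)$slope, 2)
  # scale equivariance of the slope
  set.seed(9)
  y <- x * 1.1 + rnorm(4, sd = 5)
  expect_equal(validate_predictions(3 * y, x)$slope, 3 * validate_predictions(y, x)$slope)
  expect_error(validate_predictions(x, rep(0, 4)), "zero")
  expect_error(validate_predictions(x[1:2], x[1:2]), "3 paired")
})

test_that("validation regression matches lm through the origin", {
  set.seed(21)
  x <- runif(40, 50, 800)
  y <- 1.05 * x + rnorm(40, sd = 60)
  v <- validate_predictions(y, x)
  ref <- summary(lm(y ~ 0 + x))
  expect_equal(v$slope, unname(coef(ref)[1, "Estimate"]))
  expect_equal(v$slope_se, unname(coef(ref)[1, "Std. Error"]))
  expect_equal(v$r2, ref$r.squared)
})

test_that("normalised scope is 1 at the optimum, 0 beyond critical, MS/MS_max between", {
  p <- salema_params()
  cs <- curve_summary(p)
  expect_equal(normalized_ms(cs$t_opt, p, cs$ms_max), 1, tolerance = 1e-6)
  expect_equal(normalized_ms(c(cs$t_crit, cs$t_crit + 2), p, cs$ms_max), c(0, 0),
               tolerance = 1e-6)
  mid <- (cs$t_opt + cs$t_crit) / 2
  expect_equal(normalized_ms(mid, p, cs$ms_max), ms_curve(mid, p) / cs$ms_max)
  expect_error(normalized_ms(20, p, ms_max = -1), "positive")
})

test_that("tidy and glance methods expose fit results as tibbles", {
  recs <- generate_metabolic_dataset(design_spec(spinefoot_params(), cv = 0.05, seed = 3))
  fit <- fit_smr(recs)
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b"))
  expect_true(all(c("sigma", "nobs", "converged") %in% names(glance(fit))))
  v <- validate_predictions(recs$ms, ms_curve(recs$acclim_temp_c, spinefoot_params()))
  expect_identical(nrow(tidy(v)), 1L)
})
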