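test_that("growth-kinetics fit equals the closed-form normal-equations solution", {
  set.seed(31)
  for (rep in 1:10) {
    conc <- sort(runif(5, 0.5, 20))
    v_um <- dimers_s_to_um_min(2.6 * conc - 7.5 + rnorm(5, 0, 2))
    fit <- fit_growth_kinetics(data.frame(tubulin_uM = conc,
                                          growth_rate_um_min = v_um))
    oracle <- normal_equations_fit(conc, um_min_to_dimers_s(v_um))
    expect_equal(fit$k_a, unname(oracle[2]), tolerance = 1e-10)
    expect_equal(fit$k_d, -unname(oracle[1]), tolerance = 1e-10)
    expect_equal(fit$C_c, fit$k_d / fit$k_a)
  }
  # three points on y = x (in dimers/s): slope 1, intercept 0
  conc <- c(1, 2, 3)
  fit <- fit_growth_kinetics(data.frame(
    tubulin_uM = conc, growth_rate_um_min = dimers_s_to_um_min(conc)
  ))
  expect_equal(fit$k_a, 1)
  expect_equal(fit$k_d, 0, tolerance = 1e-12)
  expect_error(fit_growth_kinetics(data.frame(tubulin_uM = c(1, 2),
                                              growth_rate_um_min = c(1, 2))),
               "at least 3")
})

test_that("noiseless kinetic data recover the generating law to six significant digits", {
  p <- control_params()
  conc <- c(5, 10, 14)
  fit <- fit_growth_kinetics(data.frame(
    tubulin_uM = conc, growth_rate_um_min = growth_velocity(conc, p)
  ))
  expect_equal(fit$k_a, 2.6, tolerance = 1e-7)
  expect_equal(fit$C_c, 2.89, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1)
  p5 <- ckap2_500nM_params()
  conc5 <- c(0.05, 0.1, 0.2, 0.3)
  fit5 <- fit_growth_kinetics(data.frame(
    tubulin_uM = conc5, growth_rate_um_min = growth_velocity(conc5, p5)
  ))
  expect_equal(fit5$k_a, 142, tolerance = 1e-7)
  expect_equal(fit5$C_c, 0.02, tolerance = 1e-7)
  # fold change between the two fitted conditions: 142 / 2.6
  fc <- fold_change(fit, fit5)
  expect_equal(fc$ratio, 54.615, tolerance = 1e-4)
})

test_that("fit methods expose coef, predict, residuals and summaries", {
  p <- control_params()
  conc <- c(5, 8, 10, 14)
  fit <- fit_growth_kinetics(data.frame(
    tubulin_uM = conc, growth_rate_um_min = growth_velocity(conc, p)
  ))
  expect_named(coef(fit), c("k_a", "k_d", "C_c"))
  expect_equal(predict(fit, 8), growth_velocity(8, p), tolerance = 1e-9)
  expect_equal(length(residuals(fit)), 4)
  s <- summary(fit)
  expect_equal(s$estimate[s$parameter == "C_c"], 2.89, tolerance = 1e-7)
  expect_output(print(fit), "k_a")
})

test_that("constrained Hill fit recovers noiseless parameters and rejects degenerate data", {
  conc <- c(2, 4, 6, 8, 10, 12, 16, 20)
  frac <- hill_probability(conc, C = 6.85, s = 3.37)
  fit <- fit_nucleation_hill(data.frame(tubulin_uM = conc, fraction = frac))
  expect_equal(fit$C, 6.85, tolerance = 1e-6)
  expect_equal(fit$s, 3.37, tolerance = 1e-6)
  low <- c(0.01, 0.02, 0.035, 0.05, 0.075, 0.1, 0.15, 0.2)
  fracl <- hill_probability(low, C = 0.05, s = 3.10)
  fitl <- fit_nucleation_hill(data.frame(tubulin_uM = low, fraction = fracl))
  expect_equal(fitl$C, 0.05, tolerance = 1e-6)
  expect_equal(fitl$s, 3.10, tolerance = 1e-6)
  expect_equal(predict(fitl, 0.05), 0.5, tolerance = 1e-6)
  # no transition coverage: refuse rather than extrapolate
  expect_error(
    fit_nucleation_hill(data.frame(tubulin_uM = c(6, 6.85, 7.5),
                                   fraction = c(0.5, 0.5, 0.5))),
    "straddle"
  )
  expect_error(
    fit_nucleation_hill(data.frame(tubulin_uM = conc, fraction = rep(0.9, 8))),
    "straddle"
  )
})

test_that("censored nucleation ECDF matches hand values and the empirical CDF", {
  r <- data.frame(lag_s = c(10, 20, 30), censored = c(FALSE, FALSE, FALSE))
  e <- nucleation_ecdf(r)
  expect_equal(ecdf_at(e, 20), 2 / 3)
  expect_equal(ecdf_at(e, 9.99), 0)
  expect_equal(ecdf_at(e, 31), 1)
  # all censored: identically zero over the window
  rc <- data.frame(lag_s = rep(60, 5), censored = TRUE)
  ec <- nucleation_ecdf(rc)
  expect_true(all(ecdf_at(ec, c(0, 30, 60)) == 0))
  # invariant to record order; equals stats::ecdf with no censoring
  set.seed(32)
  lag <- rexp(300, 1 / 40)
  a <- nucleation_ecdf(data.frame(lag_s = lag, censored = FALSE))
  b <- nucleation_ecdf(data.frame(lag_s = rev(sort(lag)), censored = FALSE))
  grid <- seq(0, 200, by = 0.5)
  expect_equal(ecdf_at(a, grid), ecdf_at(b, grid))
  expect_equal(ecdf_at(a, grid), stats::ecdf(lag)(grid))
})

test_that("large-sample ECDF lies within the DKW band of the exponential CDF", {
  set.seed(33)
  lambda <- 1 / 55
  n <- 10000
  lag <- rexp(n, lambda)
  e <- nucleation_ecdf(data.frame(lag_s = lag, censored = FALSE))
  grid <- seq(0, 400, by = 0.5)
  band <- sqrt(log(2 / 0.05) / (2 * n))
  expect_lt(max(abs(ecdf_at(e, grid) - pexp(grid, lambda))), band)
})

test_that("spontaneous-nucleation fit recovers noiseless critical concentrations", {
  conc <- c(26, 30, 35, 40, 45, 50)
  d <- data.frame(tubulin_uM = conc, count = 2 * (conc - 25.4))
  fit <- fit_spontaneous_nucleation(d)
  expect_equal(fit$critical_conc, 25.4, tolerance = 1e-9)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  low <- c(0.3, 0.35, 0.4, 0.45, 0.5)
  dl <- data.frame(tubulin_uM = low, count = 100 * (low - 0.25))
  fitl <- fit_spontaneous_nucleation(dl)
  expect_equal(fitl$critical_conc, 0.25, tolerance = 1e-9)
  # below-critical plateau is excluded by the zero floor
  d2 <- rbind(data.frame(tubulin_uM = c(5, 15, 20), count = 0), d)
  fit2 <- fit_spontaneous_nucleation(d2)
  expect_equal(fit2$critical_conc, 25.4, tolerance = 1e-9)
  expect_error(
    fit_spontaneous_nucleation(data.frame(tubulin_uM = conc, count = 0)),
    "zero floor"
  )
  expect_error(
    fit_spontaneous_nucleation(data.frame(tubulin_uM = conc,
                                          count = 50 - conc)),
    "non-positive"
  )
})

test_that("catastrophe frequency is events over growth time with a valid bootstrap CI", {
  # 26 filaments, one catastrophe each, 100/26 min of growth each:
  # 26 events over 100 min of growth -> 0.26 per min
  g_end <- 100 / 26 * 60
  filaments <- lapply(1:26, function(i) {
    data.frame(t_start_s = c(0, g_end), t_end_s = c(g_end, g_end + 10),
               slope_um_min = c(1, -10), phase = c("growth", "shrink"))
  })
  ds <- summarize_dynamics(filaments)
  cf <- catastrophe_frequency(ds, n_boot = 500, seed = 34)
  expect_equal(cf$n_events, 26)
  expect_equal(cf$frequency, 26 / ds$total_growth_time_min)
  expect_lte(cf$ci_low, cf$frequency)
  expect_gte(cf$ci_high, cf$frequency)
  # zero events: frequency and lower CI are zero, time still counted
  quiet <- lapply(1:5, function(i) {
    data.frame(t_start_s = 0, t_end_s = 600, slope_um_min = 0.5,
               phase = "growth")
  })
  cf0 <- catastrophe_frequency(summarize_dynamics(quiet), n_boot = 200,
                               seed = 35)
  expect_equal(cf0$frequency, 0)
  expect_equal(cf0$ci_low, 0)
  expect_equal(cf0$total_time_min, 50)
  expect_error(
    catastrophe_frequency(summarize_dynamics(
      data.frame(t_start_s = 0, t_end_s = 10, slope_um_min = -5,
                 phase = "shrink")
    )),
    "zero total"
  )
})

test_that("fold-change SE propagation agrees with a Monte Carlo of the ratio", {
  p <- control_params()
  set.seed(36)
  make_fit <- function(k_a, C_c, noise) {
    conc <- c(2, 6, 10, 14, 18)
    v <- dimers_s_to_um_min(k_a * conc - k_a * C_c + rnorm(5, 0, noise))
    fit_growth_kinetics(data.frame(tubulin_uM = conc, growth_rate_um_min = v))
  }
  fa <- make_fit(2.6, 2.89, 0.4)
  fb <- make_fit(142, 0.02, 8)
  expect_equal(fold_change(fa, fa)$ratio, 1)
  fc <- fold_change(fa, fb)
  mc <- replicate(100000, {
    rnorm(1, fb$k_a, fb$k_a_se) / rnorm(1, fa$k_a, fa$k_a_se)
  })
  expect_equal(fc$se, sd(mc), tolerance = 0.05)
})
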