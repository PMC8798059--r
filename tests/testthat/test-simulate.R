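test_that("without catastrophes a trajectory is one growth phase of the exact length", {
  p <- control_params(f_cat = 0)
  tr <- sample_trajectory(p, 8, duration_s = 600, noise_cv = 0, seed = 1)
  expect_equal(length(tr$phases), 1)
  expect_equal(tr$phases, "growth")
  expect_equal(tail(tr$lengths_um, 1), growth_velocity(8, p) * 10)
  expect_equal(tr$times_s[1], 0)
})

test_that("noise-free growth slopes all equal the kinetic-law velocity", {
  p <- control_params(f_cat = 0.5)
  tr <- sample_trajectory(p, 8, duration_s = 3600, noise_cv = 0, seed = 2)
  seg <- trajectory_segments(tr)
  g <- seg$slope_um_min[seg$phase == "growth"]
  expect_gt(length(g), 5)
  expect_equal(g, rep(0.49056, length(g)), tolerance = 1e-9)
  s <- seg$slope_um_min[seg$phase == "shrink"]
  expect_equal(s, rep(-p$v_shrink, length(s)), tolerance = 1e-9)
})

test_that("trajectories respect simulator invariants and are seed-reproducible", {
  p <- control_params(f_cat = 0.4)
  a <- sample_trajectory(p, 10, 900, seed = 11)
  b <- sample_trajectory(p, 10, 900, seed = 11)
  expect_identical(a, b)
  for (sd in 1:10) {
    tr <- sample_trajectory(p, 10, 900, seed = sd)
    expect_true(all(diff(tr$times_s) > 0))
    expect_true(all(tr$lengths_um >= 0))
    seg <- trajectory_segments(tr)
    expect_true(all(seg$slope_um_min[seg$phase == "growth"] > 0))
    expect_true(all(seg$slope_um_min[seg$phase == "shrink"] < 0))
    expect_equal(max(tr$times_s), 900)
  }
  expect_error(sample_trajectory(p, 1, 600), "cannot elongate")
})

test_that("catastrophe waiting times are exponential with the configured rate", {
  set.seed(3)
  p <- control_params(f_cat = 0.5)
  waits <- c()
  for (i in 1:600) {
    tr <- sample_trajectory(p, 10, 3600, noise_cv = 0)
    seg <- trajectory_segments(tr)
    n <- nrow(seg)
    # completed intervals starting with ample remaining time are exact
    # exponential draws (no truncation bias from the movie end)
    done <- which(seg$phase == "growth" & seq_len(n) < n &
                    c(seg$phase[-1], "") == "shrink" & seg$t_start_s < 1800)
    waits <- c(waits, (seg$t_end_s - seg$t_start_s)[done])
  }
  waits <- waits[seq_len(min(length(waits), 10000))]
  expect_gt(length(waits), 9000)
  # mean waiting time 1/f_cat = 2 min, within 3 SE
  expect_lt(abs(mean(waits) / 60 - 2), 3 * 2 / sqrt(length(waits)))
  ks <- stats::ks.test(waits, "pexp", rate = 0.5 / 60)
  expect_gt(ks$p.value, 0.01)
})

test_that("nucleation lags reproduce the Hill law at one minute", {
  p <- control_params()
  r <- sample_nucleation_lags(p, p$hill_C, n_seeds = 10000, t_max_s = 120,
                              seed = 4)
  frac <- mean(r$lag_s <= 60 & !r$censored)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
  # zero tubulin: nothing nucleates
  r0 <- sample_nucleation_lags(p, 0, n_seeds = 50, t_max_s = 60, seed = 4)
  expect_true(all(r0$censored))
  # infinite window: nothing is censored
  rInf <- sample_nucleation_lags(p, 8, n_seeds = 200, t_max_s = Inf, seed = 4)
  expect_false(any(rInf$censored))
  expect_true(all(rInf$lag_s > 0))
  # empirical 1-min fraction tracks the Hill curve across concentrations
  for (cc in c(3, 6, 10, 16)) {
    ri <- sample_nucleation_lags(p, cc, n_seeds = 4000, t_max_s = 90, seed = cc)
    ptrue <- hill_probability(cc, p$hill_C, p$hill_s)
    se <- sqrt(ptrue * (1 - ptrue) / 4000)
    expect_lt(abs(mean(ri$lag_s <= 60 & !ri$censored) - ptrue), 4 * se)
  }
  expect_warning(
    sample_nucleation_lags(kinetic_params(k_a = 1, k_d = 1, hill_C = 0.01,
                                          hill_s = 5),
                           100, n_seeds = 5, seed = 1),
    "capped"
  )
})

test_that("spontaneous counts are Poisson with a thresholded linear mean", {
  p <- kinetic_params(k_a = 2.6, C_c = 2.89, spont_slope = 2, spont_Cc = 25.4)
  expect_true(all(sample_spontaneous_count(p, 20, n_fields = 200, seed = 5) == 0))
  expect_true(all(sample_spontaneous_count(p, 25.4, n_fields = 200, seed = 5) == 0))
  x <- sample_spontaneous_count(p, 30, n_fields = 10000, seed = 6)
  # mean 2 * (30 - 25.4) = 9.2, within 3 SE
  expect_lt(abs(mean(x) - 9.2), 3 * sqrt(9.2 / 10000))
  expect_true(all(x == round(x) & x >= 0))
  p0 <- kinetic_params(k_a = 2.6, C_c = 2.89, spont_slope = 0, spont_Cc = 0)
  expect_true(all(sample_spontaneous_count(p0, 50, n_fields = 100, seed = 7) == 0))
})

test_that("GMPCPP seed depolymerization is linear at the configured speed", {
  p <- kinetic_params(k_a = 2.6, C_c = 2.89, v_depoly_gmpcpp = 0.013)
  tr <- sample_gmpcpp_depolymerization(p, duration_min = 600,
                                       frame_interval_min = 1,
                                       initial_length_um = 10, seed = 8)
  expect_equal(tr$origin, "gmpcpp_seed")
  expect_true(all(diff(tr$lengths_um) <= 0))
  expect_equal(tr$lengths_um[1] - tail(tr$lengths_um, 1), 7.8)
  expect_equal(tail(tr$lengths_um, 1), 10 - 0.013 * 600)
  # saturated MAP case: no depolymerization at all
  pz <- kinetic_params(k_a = 142, C_c = 0.02, v_depoly_gmpcpp = 0)
  trz <- sample_gmpcpp_depolymerization(pz, 600, 1, 10, seed = 8)
  expect_true(all(trz$lengths_um == 10))
  # localization noise perturbs but stays non-negative
  trn <- sample_gmpcpp_depolymerization(p, 600, 1, 10, noise_sd_um = 0.05,
                                        seed = 9)
  expect_true(all(trn$lengths_um >= 0))
})

test_that("ground-truth trajectory summaries count catastrophes and growth time", {
  p <- control_params(f_cat = 0.6)
  trs <- lapply(1:20, function(i) sample_trajectory(p, 10, 1200, seed = 100 + i))
  ds <- summarize_trajectories(trs, condition = "control")
  truth_events <- sum(vapply(trs, function(tr) sum(tr$phases == "shrink"),
                             numeric(1)))
  expect_equal(ds$n_catastrophes, truth_events)
  truth_time <- sum(vapply(trs, function(tr) {
    sum(diff(tr$times_s)[tr$phases == "growth"])
  }, numeric(1))) / 60
  expect_equal(ds$total_growth_time_min, truth_time)
  expect_lte(ds$n_catastrophes, length(ds$growth_rates_um_min))
})
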