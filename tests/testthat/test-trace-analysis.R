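test_that("tip tracking of a noiseless ramp is accurate to half a pixel", {
  p <- control_params(f_cat = 0)
  tr <- sample_trajectory(p, 10, 600, noise_cv = 0, seed = 1)  # 0.6826 um/min
  opt <- optics_config(frame_interval_s = 2)
  ky <- render_kymograph(tr, opt, noise = FALSE)
  trace <- track_tip(ky)
  truth <- approx(tr$times_s, tr$lengths_um, xout = trace$frame_times_s,
                  rule = 2)$y
  ok <- !is.na(trace$tip_um) & truth > 1  # resolvable regime
  expect_gt(sum(ok), 200)
  expect_lt(max(abs(trace$tip_um[ok] - truth[ok])), 0.107 / 2)
})

test_that("an all-background kymograph yields an all-missing trace", {
  ky <- background_kymograph()
  trace <- track_tip(ky)
  expect_true(all(is.na(trace$tip_um)))
})

test_that("tracked slope of a default-noise render is within 5% of the generator", {
  p <- control_params(f_cat = 0)
  opt <- optics_config(frame_interval_s = 5)
  for (cc in c(6, 10, 14)) {
    tr <- sample_trajectory(p, cc, 600, noise_cv = 0, seed = cc)
    ky <- render_kymograph(tr, opt, noise = TRUE, seed = cc)
    trace <- track_tip(ky)
    slope <- -depolymerization_rate(trace)  # OLS slope of the whole trace
    expect_lt(abs(slope / growth_velocity(cc, p) - 1), 0.05)
  }
})

test_that("segmentation recovers an exact two-piece trace to the frame", {
  tr <- manual_trajectory(
    times_s = c(0, 300, 330), lengths_um = c(0, 5, 0),
    phases = c("growth", "shrink")
  )
  trace <- trace_from_trajectory(tr, frame_interval_s = 5)
  segs <- segment_phases(trace)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$phase, c("growth", "shrink"))
  expect_lt(abs(segs$t_end_s[1] - 300), 5 + 1e-9)  # breakpoint within 1 frame
  expect_equal(segs$slope_um_min[1], 1, tolerance = 0.02)
  expect_equal(segs$slope_um_min[2], -10, tolerance = 0.05)
})

test_that("a constant trace is a single pause segment", {
  trace <- manual_trace(seq(0, 120, by = 5), rep(2.5, 25))
  segs <- segment_phases(trace)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$phase, "pause")
  expect_equal(segs$t_start_s, 0)
  expect_equal(segs$t_end_s, 120)
})

test_that("segmentation recovers slopes within 2% and breakpoints within 1 frame on a noiseless grid", {
  frame <- 4
  for (v1 in c(0.3, 0.8, 1.5)) {
    for (v2 in c(-2, -6, -12)) {
      # 6 um excursions keep every phase at least min_segment frames long
      peak <- 6
      t_break <- peak / v1 * 60
      t_end <- t_break + peak / abs(v2) * 60
      tr <- manual_trajectory(c(0, t_break, t_end), c(0, peak, 0),
                              c("growth", "shrink"))
      trace <- trace_from_trajectory(tr, frame)
      segs <- segment_phases(trace)
      segs <- segs[segs$phase != "pause", ]
      expect_equal(nrow(segs), 2)
      expect_equal(segs$slope_um_min[1], v1, tolerance = 0.02)
      expect_equal(segs$slope_um_min[2], v2, tolerance = 0.02)
      expect_lt(abs(segs$t_end_s[1] - t_break), frame + 1e-9)
    }
  }
})

test_that("detected catastrophe count matches generator truth within 10%", {
  set.seed(42)
  p <- kinetic_params(k_a = 2.6, C_c = 2.89, f_cat = 0.5, v_shrink = 3)
  truth <- 0
  detected <- 0
  for (i in 1:55) {
    tr <- sample_trajectory(p, 14, 600)
    truth <- truth + sum(tr$phases == "shrink")
    segs <- segment_phases(trace_from_trajectory(tr, 2))
    detected <- detected +
      sum(segs$phase[-nrow(segs)] == "growth" & segs$phase[-1] == "shrink")
  }
  expect_gt(truth, 150)
  expect_lt(abs(detected / truth - 1), 0.10)
})

test_that("dynamics summaries count catastrophes, censor movie-end growth, and conserve time", {
  seg1 <- data.frame(t_start_s = c(0, 300), t_end_s = c(300, 330),
                     slope_um_min = c(1, -10), phase = c("growth", "shrink"))
  ds <- summarize_dynamics(seg1)
  expect_equal(ds$n_catastrophes, 1)
  expect_equal(ds$total_growth_time_min, 5)
  expect_equal(ds$growth_rates_um_min, 1)
  # growth running into the movie end: time counted, no event
  seg2 <- data.frame(t_start_s = 0, t_end_s = 600, slope_um_min = 0.5,
                     phase = "growth")
  ds2 <- summarize_dynamics(seg2)
  expect_equal(ds2$n_catastrophes, 0)
  expect_equal(ds2$total_growth_time_min, 10)
  # pooled across filaments; segment durations partition the trace
  ds3 <- summarize_dynamics(list(seg1, seg2))
  expect_equal(ds3$n_catastrophes, 1)
  expect_equal(ds3$total_growth_time_min, 15)
  expect_equal(nrow(ds3$per_filament), 2)
  p <- control_params(f_cat = 0.5)
  tr <- sample_trajectory(p, 10, 600, seed = 5)
  segs <- segment_phases(trace_from_trajectory(tr, 2))
  expect_equal(sum(segs$t_end_s - segs$t_start_s), 600, tolerance = 2 + 1e-9)
})

test_that("nucleation lag is the interpolated threshold crossing, censored when absent", {
  # growth at 1 um/min from t = 0 crosses 0.5 um at 30 s
  trace <- manual_trace(seq(0, 120, by = 5), seq(0, 120, by = 5) / 60)
  lag <- nucleation_lag(trace, threshold_um = 0.5)
  expect_false(lag$censored)
  expect_equal(lag$lag_s, 30)
  # no growth: censored
  flat <- manual_trace(seq(0, 120, by = 5), rep(0, 25))
  expect_true(nucleation_lag(flat, 0.5)$censored)
  # window shorter than the crossing: censored at the window
  lag2 <- nucleation_lag(trace, threshold_um = 0.5, t_max_s = 20)
  expect_true(lag2$censored)
  expect_equal(lag2$lag_s, 20)
})

test_that("rendered nucleation lags recover the true crossing-time ECDF within a DKW band", {
  set.seed(9)
  p <- control_params(f_cat = 0)
  cc <- 6.85
  v <- growth_velocity(cc, p)               # 0.380 um/min
  delay <- 0.5 / v * 60                     # deterministic crossing delay
  lags <- sample_nucleation_lags(p, cc, n_seeds = 200, t_max_s = 120)
  opt <- optics_config(frame_interval_s = 2)
  measured <- rep(NA_real_, 200)
  meas_cens <- rep(TRUE, 200)
  truth <- rep(NA_real_, 200)
  truth_cens <- lags$censored
  duration <- 300
  for (i in 1:200) {
    if (lags$censored[i]) {
      measured[i] <- duration
      truth[i] <- duration
      next
    }
    lag <- lags$lag_s[i]
    truth[i] <- lag + delay
    tr <- manual_trajectory(
      times_s = c(0, lag, duration),
      lengths_um = c(0, 0, v * (duration - lag) / 60),
      phases = c("pause", "growth")
    )
    ky <- render_kymograph(tr, opt, noise = TRUE)
    m <- nucleation_lag(track_tip(ky), threshold_um = 0.5)
    measured[i] <- m$lag_s
    meas_cens[i] <- m$censored
  }
  em <- nucleation_ecdf(data.frame(lag_s = measured, censored = meas_cens))
  et <- nucleation_ecdf(data.frame(lag_s = truth, censored = truth_cens))
  grid <- seq(0, 240, by = 1)
  band <- sqrt(log(2 / 0.05) / (2 * 200))
  expect_lt(max(abs(ecdf_at(em, grid) - ecdf_at(et, grid))), band)
})

test_that("depolymerization rate is recovered exactly, at zero, and from a noisy render", {
  p <- kinetic_params(k_a = 2.6, C_c = 2.89, v_depoly_gmpcpp = 0.013)
  tr <- sample_gmpcpp_depolymerization(p, 600, 1, 10)
  trace <- trace_from_trajectory(tr, 60)
  expect_equal(depolymerization_rate(trace), 0.013, tolerance = 1e-9)
  flat <- manual_trace(seq(0, 6000, by = 60), rep(5, 101))
  expect_equal(depolymerization_rate(flat), 0)
  expect_error(depolymerization_rate(manual_trace(1:5, 1:5)), "at least 10")
  # noisy imaging loop at 1-min frames, 600 frames
  opt <- optics_config(frame_interval_s = 60)
  ky <- render_kymograph(tr, opt, noise = TRUE, seed = 10, max_width_um = 20)
  rate <- depolymerization_rate(track_tip(ky))
  expect_lt(abs(rate / 0.013 - 1), 0.10)
})

test_that("line profiles are background-subtracted, averaged and peak-normalized", {
  img <- rbind(c(0, 2, 4), c(0, 2, 4), c(0, 0, 0))
  lines <- list(list(start = c(1, 1), end = c(1, 3)),
                list(start = c(2, 1), end = c(2, 3)))
  lp <- average_line_profiles(img, lines, background = 0, n_samples = 3)
  expect_equal(lp$mean_intensity, c(0, 0.5, 1))
  expect_equal(lp$sem, c(0, 0, 0))
  expect_equal(lp$n_profiles, 2)
  expect_false(lp$constant)
  # a uniform image is a degenerate (flat) profile, flagged not normalized
  uni <- matrix(7, 5, 5)
  lpu <- average_line_profiles(uni, list(list(start = c(3, 1), end = c(3, 5))),
                               background = 0, n_samples = 5)
  expect_true(lpu$constant)
  expect_equal(unique(lpu$mean_intensity), 7)
  # background mask overlapping the scan is an error
  bg <- matrix(FALSE, 5, 5); bg[3, ] <- TRUE
  expect_error(
    average_line_profiles(uni, list(list(start = c(3, 1), end = c(3, 5))),
                          background = bg),
    "overlaps"
  )
})

test_that("profile peak of a tip-decorated filament sits at the true tip", {
  opt <- optics_config(photons_per_um = 2000)
  lattice <- cbind(c(2, 6), c(5, 5))
  tip_dot <- cbind(c(5.9, 6.1), c(5, 5))
  f <- render_field(list(lattice, tip_dot), opt, field_size_um = 10,
                    labels = c("lattice", "ckap2"), noise = TRUE, seed = 11)
  px <- opt$pixel_size_nm / 1000
  row <- 5 / px + 0.5
  line <- list(start = c(row, 2 / px + 0.5), end = c(row, 8 / px + 0.5))
  lp <- average_line_profiles(f$channels$ckap2, list(line), background = 20,
                              n_samples = 120, pixel_size_nm = 107)
  peak_um <- 2 + lp$offsets_um[which.max(lp$mean_intensity)]
  expect_lt(abs(peak_um - 6), 2 * px)  # true tip at x = 6 um
})

test_that("recruitment ratio is the mean lattice over mean background signal", {
  img <- matrix(100, 20, 20)
  lat <- matrix(FALSE, 20, 20); lat[5:8, ] <- TRUE
  bgm <- matrix(FALSE, 20, 20); bgm[15:18, ] <- TRUE
  img[lat] <- 300
  expect_equal(recruitment_ratio(img, lat, bgm), 3)
  img2 <- matrix(42, 20, 20)
  expect_equal(recruitment_ratio(img2, lat, bgm), 1)
  expect_error(recruitment_ratio(img, lat, lat), "disjoint")
  zero <- matrix(0, 20, 20)
  expect_error(recruitment_ratio(zero, lat, bgm), "background")
  # rendered decorated filament: noisy ratio matches the noise-free ratio
  opt <- optics_config()
  chain <- list(cbind(c(2, 8), c(5, 5)))
  fq <- render_field(chain, opt, field_size_um = 10, noise = FALSE)
  fn <- render_field(chain, opt, field_size_um = 10, noise = TRUE, seed = 12)
  px <- opt$pixel_size_nm / 1000
  latm <- matrix(FALSE, nrow(fq$channels$lattice), ncol(fq$channels$lattice))
  latm[round(5 / px) + (-1:1), (round(2.5 / px)):(round(7.5 / px))] <- TRUE
  bgm2 <- matrix(FALSE, nrow(latm), ncol(latm)); bgm2[1:20, ] <- TRUE
  r_true <- recruitment_ratio(fq$channels$lattice, latm, bgm2)
  r_noisy <- recruitment_ratio(fn$channels$lattice, latm, bgm2)
  expect_gt(r_true, 1.5)
  expect_equal(r_noisy, r_true, tolerance = 0.05)
})
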