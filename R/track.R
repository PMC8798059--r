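new_tip_trace <- function(frame_times_s, tip_um) {
  stopifnot(length(frame_times_s) == length(tip_um))
  structure(list(frame_times_s = frame_times_s, tip_um = tip_um),
            class = "tip_trace")
}

#' @export
print.tip_trace <- function(x, ...) {
  ok <- sum(!is.na(x$tip_um))
  cat(sprintf("Tip trace: %d frames over %g s, %d tracked (%.0f%%)\n",
              length(x$tip_um), max(x$frame_times_s), ok,
              100 * ok / length(x$tip_um)))
  invisible(x)
}

#' @export
plot.tip_trace <- function(x, xlab = "time (s)", ylab = "tip position (um)",
                           ...) {
  graphics::plot(x$frame_times_s, x$tip_um, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Track the filament tip across a kymograph
#'
#' Automates the manual procedure of reading growth and shrinkage slopes
#' off a kymograph. Per frame (row), a filament is detected when the
#' lightly smoothed intensity exceeds `background mean + k * SD` anywhere;
#' the tip is then located as the farthest threshold crossing, refined to
#' sub-pixel precision by linear interpolation between the last
#' supra-threshold pixel and its neighbour. Frames with no detection are
#' recorded as missing; an all-background kymograph yields an all-missing
#' trace.
#'
#' Three localization modes are available. `"half_max"` (default) places
#' the crossing threshold at background + half the row's signal amplitude
#' (never below the detection threshold). Because the blurred edge of a
#' resolvable filament passes through half its plateau intensity exactly
#' at the true tip, this localization is amplitude-invariant and unbiased
#' once the filament exceeds a few PSF widths; frames where the filament
#' is too dim become missing rather than biased. `"threshold"` uses the
#' fixed detection threshold `background + k * SD` itself, which carries a
#' constant offset for bright filaments (harmless for velocities) but
#' makes the apparent tip of sub-resolution filaments advance faster than
#' the true tip while their blob brightens. `"model"` performs
#' matched-filter localization against the imaging model: the tip is the
#' position whose expected PSF-blurred polymer profile (at the calibrated
#' photon budget) best fits the row in least squares, with parabolic
#' sub-grid refinement and a matched-filter detection gate at `k` SDs.
#' Model localization is free of the length-dependent offsets that any
#' threshold rule shows near the resolution limit and is the mode used by
#' the quantitative velocity pipeline; it requires the photon budget,
#' taken from the kymograph's optics (or `photons_per_um`).
#'
#' Background statistics default to the robust median and MAD of the
#' outermost 10 percent of columns, which lie beyond the farthest tip
#' excursion in any kymograph cropped with a background margin (as the
#' renderer guarantees); they can be given explicitly.
#'
#' @param kymo A `kymograph`.
#' @param channel Channel name or index (default: last channel, the
#'   dynamic lattice).
#' @param k Detection threshold in background SDs (default 3).
#' @param mode `"half_max"` (amplitude-referenced localization, default),
#'   `"threshold"` (fixed threshold crossing) or `"model"` (matched-filter
#'   fit of the imaging model).
#' @param smooth_window Running-mean window in pixels (odd; default 3).
#' @param background Optional `list(mean =, sd =)` overriding the robust
#'   estimate.
#' @param photons_per_um Photon budget for `"model"` mode (default: from
#'   the kymograph's optics).
#' @return A `tip_trace`: frame times and tip positions in um beyond the
#'   seed plus end (beyond the minus end for shrinking-seed kymographs),
#'   `NA` where undetected.
#' @export
track_tip <- function(kymo, channel = length(kymo$channels), k = 3,
                      mode = c("half_max", "threshold", "model"),
                      smooth_window = 3, background = NULL,
                      photons_per_um = NULL) {
  stopifnot(inherits(kymo, "kymograph"))
  mode <- match.arg(mode)
  img <- kymo$channels[[channel]]
  if (nrow(img) < 2) stop("kymograph must have at least 2 frames")
  pixel_um <- kymo$optics$pixel_size_nm / 1000
  if (is.null(background)) {
    far <- img[, seq(max(1, ncol(img) - max(3, ceiling(ncol(img) * 0.1)) + 1),
                     ncol(img)), drop = FALSE]
    background <- list(mean = stats::median(far), sd = stats::mad(far))
  }
  origin <- kymo$seed_extent_um[2]
  if (mode == "model") {
    if (is.null(photons_per_um)) photons_per_um <- kymo$optics$photons_per_um
    tip <- track_tip_model(img, kymo$optics, origin, background, k,
                           photons_per_um)
    return(new_tip_trace(kymo$frame_times_s, pmax(tip - origin, 0)))
  }
  detect <- background$mean + k * background$sd
  half <- (smooth_window - 1) / 2
  tip <- rep(NA_real_, nrow(img))
  for (i in seq_len(nrow(img))) {
    v <- img[i, ]
    if (half >= 1) {
      v <- stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
      v[is.na(v)] <- img[i, ][is.na(v)]
      v <- as.numeric(v)
    }
    thr <- if (mode == "half_max") {
      max(background$mean + 0.5 * (max(v) - background$mean), detect)
    } else {
      detect
    }
    above <- which(v > thr)
    if (length(above) == 0 || max(v) <= detect) next
    j <- max(above)
    x <- (j - 0.5) * pixel_um
    if (j < length(v) && v[j] > v[j + 1]) {
      frac <- (v[j] - thr) / (v[j] - v[j + 1])
      x <- x + pixel_um * min(max(frac, 0), 1)
    }
    tip[i] <- max(x - origin, 0)
  }
  new_tip_trace(kymo$frame_times_s, tip)
}

# Matched-filter tip localization: for each row, the candidate tip whose
# expected blurred polymer profile (polymer on [origin, b], calibrated
# photon budget) minimizes the least-squares misfit. With the amplitude
# known, argmin_b ||r - E_b||^2 = argmax_b <E_b, r> - ||E_b||^2 / 2, which
# is a single matrix product over all rows. Detection requires the matched
# signal-to-noise <E_b, r> / (sd_bg * ||E_b||) to reach k.
track_tip_model <- function(img, optics, origin_um, background, k,
                            photons_per_um) {
  n_px <- ncol(img)
  pixel_um <- optics$pixel_size_nm / 1000
  psf_px <- optics$psf_sigma_nm / 1000 / pixel_um
  K <- gaussian_blur_operator(n_px, psf_px)
  step <- pixel_um / 4
  b_grid <- seq(origin_um + step, n_px * pixel_um, by = step)
  E <- t(vapply(b_grid, function(b) {
    segment_photons(origin_um, b, n_px, pixel_um, photons_per_um)
  }, numeric(n_px))) %*% K
  e2 <- rowSums(E^2)
  R <- t(img - background$mean)           # n_px x n_frames
  cross <- E %*% R                        # n_b x n_frames
  score <- cross - e2 / 2
  best <- max.col(t(score), ties.method = "first")
  # parabolic sub-grid refinement on the score around the best candidate
  refine <- function(i) {
    j <- best[i]
    if (j <= 1 || j >= length(b_grid)) return(b_grid[j])
    s0 <- score[j - 1, i]; s1 <- score[j, i]; s2 <- score[j + 1, i]
    denom <- s0 - 2 * s1 + s2
    if (denom >= 0) return(b_grid[j])
    b_grid[j] + 0.5 * (s0 - s2) / denom * step
  }
  tip <- vapply(seq_len(nrow(img)), refine, numeric(1))
  z <- cross[cbind(best, seq_len(nrow(img)))] /
    (max(background$sd, .Machine$double.eps) * sqrt(e2[best]))
  tip[z < k] <- NA_real_
  tip
}

#' Sample a simulated trajectory as a tip trace
#'
#' Ideal (image-free) observation of a trajectory at regular frame times,
#' for analyzing simulated data in table mode and for oracle tests of the
#' segmentation independent of the imaging model.
#'
#' @param traj A `filament_trajectory`.
#' @param frame_interval_s Sampling interval in seconds.
#' @param noise_sd_um Optional Gaussian localization noise SD.
#' @param seed Optional RNG seed.
#' @return A `tip_trace`.
#' @export
trace_from_trajectory <- function(traj, frame_interval_s, noise_sd_um = 0,
                                  seed = NULL) {
  stopifnot(inherits(traj, "filament_trajectory"), frame_interval_s > 0)
  if (!is.null(seed)) set.seed(seed)
  duration <- max(traj$times_s)
  frame_times <- seq(0, duration, by = frame_interval_s)
  y <- stats::approx(traj$times_s, traj$lengths_um, xout = frame_times,
                     rule = 2)$y
  if (noise_sd_um > 0) y <- pmax(y + stats::rnorm(length(y), sd = noise_sd_um), 0)
  new_tip_trace(frame_times, y)
}

# Segment SSE of OLS lines through points i..j from cumulative sums.
# make_sse_fun(t, y) returns f(i, j) with vectorized i for the DP sweep.
make_sse_fun <- function(t, y) {
  Sx <- c(0, cumsum(t)); Sy <- c(0, cumsum(y))
  Sxx <- c(0, cumsum(t^2)); Sxy <- c(0, cumsum(t * y)); Syy <- c(0, cumsum(y^2))
  function(i, j) {
    n <- j - i + 1
    sx <- Sx[j + 1] - Sx[i]
    sy <- Sy[j + 1] - Sy[i]
    sxx <- Sxx[j + 1] - Sxx[i]
    sxy <- Sxy[j + 1] - Sxy[i]
    syy <- Syy[j + 1] - Syy[i]
    vxx <- sxx - sx^2 / n
    vxy <- sxy - sx * sy / n
    vyy <- syy - sy^2 / n
    out <- vyy - vxy^2 / pmax(vxx, .Machine$double.xmin)
    out[vxx <= 0] <- vyy[vxx <= 0]
    pmax(out, 0)
  }
}

phase_label <- function(slope, pause_band, shrink_threshold) {
  if (slope > pause_band) "growth"
  else if (slope < -shrink_threshold) "shrink"
  else "pause"
}

#' Segment a tip trace into growth, shrink and pause phases
#'
#' Piecewise-linear change-point segmentation by dynamic programming:
#' minimizes total least-squares error plus a BIC-style penalty per
#' segment (`penalty * sigma^2 * log(n)`, with the noise variance
#' estimated robustly from second differences of the trace). Exact ties
#' are broken in favour of fewer segments. Missing frames are bridged by
#' linear interpolation for the change-point search but excluded when
#' estimating each segment's slope. Segments are labelled growth
#' (slope above `+pause_band`), shrink (slope below `-shrink_threshold`)
#' or pause, and adjacent same-label segments are merged.
#'
#' Tip positions closer to the seed than `min_reliable_um` can be excluded
#' from slope estimation (they are still used to place breakpoints):
#' threshold-based localization of a sub-resolution filament stub tracks
#' the brightening of its diffraction blob rather than the true tip, so
#' positions below roughly four PSF widths carry a length-dependent bias.
#' When a segment has fewer than two reliable points its slope falls back
#' to all observed points.
#'
#' @param trace A `tip_trace`.
#' @param min_segment Minimum segment length in frames (default 3).
#' @param shrink_threshold Shrink classification threshold, um/min
#'   (default 1: shrinkage is roughly an order of magnitude faster than
#'   growth in this system).
#' @param pause_band Half-width of the pause band, um/min (default 0.05).
#' @param penalty Penalty coefficient (default 3).
#' @param min_reliable_um Tip positions below this are excluded from slope
#'   estimation (default 0: keep all).
#' @return A data frame of segments: `t_start_s`, `t_end_s`,
#'   `slope_um_min`, `phase`, and `reliable_s`, the observed time spent at
#'   reliable tip positions (used to weight slope pooling downstream).
#' @export
segment_phases <- function(trace, min_segment = 3, shrink_threshold = 1,
                           pause_band = 0.05, penalty = 3,
                           min_reliable_um = 0) {
  stopifnot(inherits(trace, "tip_trace"), min_segment >= 2)
  t <- trace$frame_times_s
  y_obs <- trace$tip_um
  ok <- !is.na(y_obs)
  if (sum(ok) < 2 * min_segment) {
    stop("trace too short: need at least 2 * min_segment tracked frames")
  }
  y <- y_obs
  if (any(!ok)) {
    y <- stats::approx(t[ok], y_obs[ok], xout = t, rule = 2)$y
  }
  n <- length(y)
  sse <- make_sse_fun(t, y)
  d2 <- diff(y, differences = 2)
  sigma2 <- (stats::mad(d2)^2) / 6
  scale2 <- max(diff(range(y))^2, .Machine$double.eps)
  beta <- penalty * sigma2 * log(n) + 1e-9 * scale2  # tie-break: fewer segments

  # F[j+1] = optimal cost of points 1..j; cut[j+1] = last segment start.
  F <- rep(Inf, n + 1)
  F[1] <- 0
  cut <- integer(n + 1)
  for (j in min_segment:n) {
    starts <- seq(1, j - min_segment + 1)
    starts <- starts[is.finite(F[starts])]  # previous part ends validly
    vals <- F[starts] + sse(starts, j) + beta
    # ties broken toward the earliest feasible start (fewer segments)
    best_q <- which(vals < min(vals) + 1e-12)[1]
    F[j + 1] <- vals[best_q]
    cut[j + 1] <- starts[best_q]
  }
  # backtrack
  bounds <- integer(0)
  j <- n
  while (j > 0) {
    i <- cut[j + 1]
    bounds <- c(i, bounds)
    j <- i - 1
  }
  starts <- bounds
  ends <- c(bounds[-1] - 1, n)

  seg_fit <- function(i, j) {
    sel <- which(ok[i:j]) + i - 1
    reliable <- sel[y_obs[sel] >= min_reliable_um]
    if (length(reliable) >= 2) sel <- reliable
    if (length(sel) < 2) sel <- i:j
    stats::coef(stats::lm.fit(cbind(1, t[sel] / 60), y_obs_or_interp(sel)))
  }
  seg_slope <- function(i, j) seg_fit(i, j)[2]
  frame_s <- stats::median(diff(t))
  seg_reliable <- function(i, j) {
    sel <- which(ok[i:j]) + i - 1
    n_rel <- sum(y_obs[sel] >= min_reliable_um)
    if (n_rel >= 2) n_rel * frame_s else 0
  }
  y_obs_or_interp <- function(sel) ifelse(ok[sel], y_obs[sel], y[sel])

  segs <- data.frame(
    t_start_s = t[starts], t_end_s = t[ends],
    slope_um_min = vapply(seq_along(starts),
                          function(q) seg_slope(starts[q], ends[q]),
                          numeric(1)),
    reliable_s = vapply(seq_along(starts),
                        function(q) seg_reliable(starts[q], ends[q]),
                        numeric(1)),
    stringsAsFactors = FALSE
  )
  segs$phase <- vapply(segs$slope_um_min, phase_label, character(1),
                       pause_band = pause_band,
                       shrink_threshold = shrink_threshold)

  # Merge adjacent same-label segments, refitting the slope over the union.
  # Merging requires the two fitted lines to meet at the junction: a
  # displacement jump there marks an event too brief to segment (for
  # instance a catastrophe and regrowth spanning a single frame), and
  # pooling across it would dilute both slopes.
  gap_tol <- 5 * sqrt(sigma2) + 1e-6 * sqrt(scale2)
  junction_gap <- function(m, q) {
    fl <- seg_fit(which(t == merged$t_start_s[m]),
                  which(t == merged$t_end_s[m]))
    fr <- seg_fit(which(t == segs$t_start_s[q]),
                  which(t == segs$t_end_s[q]))
    tj <- (merged$t_end_s[m] + segs$t_start_s[q]) / 2 / 60
    abs((fl[1] + fl[2] * tj) - (fr[1] + fr[2] * tj))
  }
  merged <- segs[0, ]
  for (q in seq_len(nrow(segs))) {
    m <- nrow(merged)
    if (m > 0 && merged$phase[m] == segs$phase[q] &&
        junction_gap(m, q) <= gap_tol) {
      i <- which(t == merged$t_start_s[m])
      j <- which(t == segs$t_end_s[q])
      merged$t_end_s[m] <- segs$t_end_s[q]
      merged$slope_um_min[m] <- seg_slope(i, j)
      merged$reliable_s[m] <- seg_reliable(i, j)
    } else {
      merged <- rbind(merged, segs[q, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Summarize dynamics of segmented filaments
#'
#' Pools phase segments across filaments into the quantities the
#' catastrophe-frequency estimator consumes: all growth-segment slopes,
#' the catastrophe count (a growth segment immediately followed by a
#' shrink segment; growth running into the end of the movie is censored
#' and contributes observation time but no event), and the total growth
#' time.
#'
#' @param segments_per_filament A list of segment data frames (one per
#'   filament) as returned by [segment_phases()] or
#'   [trajectory_segments()], or a single data frame for one filament.
#' @param condition Optional condition label.
#' @return An object of class `dynamics_summary` with fields
#'   `growth_rates_um_min`, `n_catastrophes`, `total_growth_time_min`,
#'   `per_filament` (events and growth time per filament) and `condition`.
#' @export
summarize_dynamics <- function(segments_per_filament, condition = NULL) {
  if (is.data.frame(segments_per_filament)) {
    segments_per_filament <- list(segments_per_filament)
  }
  stopifnot(length(segments_per_filament) >= 1)
  rates <- numeric(0)
  n_cat <- integer(length(segments_per_filament))
  g_time <- numeric(length(segments_per_filament))
  for (i in seq_along(segments_per_filament)) {
    seg <- segments_per_filament[[i]]
    is_g <- seg$phase == "growth"
    rates <- c(rates, seg$slope_um_min[is_g])
    g_time[i] <- sum((seg$t_end_s - seg$t_start_s)[is_g]) / 60
    followed_by_shrink <- is_g[-nrow(seg)] & seg$phase[-1] == "shrink"
    n_cat[i] <- if (nrow(seg) > 1) sum(followed_by_shrink) else 0L
  }
  structure(
    list(growth_rates_um_min = rates,
         n_catastrophes = sum(n_cat),
         total_growth_time_min = sum(g_time),
         per_filament = data.frame(filament = seq_along(n_cat),
                                   n_catastrophes = n_cat,
                                   growth_time_min = g_time),
         condition = condition),
    class = "dynamics_summary"
  )
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf(
    "Dynamics summary%s: %d growth events (mean rate %.3g um/min), %d catastrophes over %.3g min growth time\n",
    if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
    length(x$growth_rates_um_min), mean(x$growth_rates_um_min),
    x$n_catastrophes, x$total_growth_time_min
  ))
  invisible(x)
}

#' Time for a seed to nucleate a microtubule
#'
#' The nucleation lag is the first time the tracked tip exceeds
#' `threshold_um` beyond the seed (linearly interpolated between frames);
#' right-censored at `t_max_s` if the threshold is never reached within
#' the window. The crossing must be sustained for `min_frames` consecutive
#' frames, which rejects single-frame spurious detections in noisy
#' kymographs.
#'
#' @param trace A `tip_trace` starting at assay start.
#' @param threshold_um Length defining "nucleated" (default 0.5 um,
#'   about five pixels).
#' @param t_max_s Observation window (default: end of trace).
#' @param min_frames Consecutive supra-threshold frames required (default 2).
#' @return A list with `lag_s` and logical `censored`.
#' @export
nucleation_lag <- function(trace, threshold_um = 0.5, t_max_s = Inf,
                           min_frames = 2) {
  stopifnot(inherits(trace, "tip_trace"), min_frames >= 1)
  t <- trace$frame_times_s
  y <- trace$tip_um
  y[is.na(y)] <- 0
  t_end <- min(t_max_s, max(t))
  above <- y >= threshold_um
  sustained <- above
  if (min_frames > 1) {
    for (q in seq_len(min_frames - 1)) {
      sustained <- sustained & c(above[-seq_len(q)], rep(TRUE, q))
    }
  }
  idx <- which(sustained & t <= t_end)
  if (length(idx) == 0) {
    return(list(lag_s = t_end, censored = TRUE))
  }
  j <- idx[1]
  if (j == 1) return(list(lag_s = t[1], censored = FALSE))
  frac <- (threshold_um - y[j - 1]) / (y[j] - y[j - 1])
  list(lag_s = t[j - 1] + frac * (t[j] - t[j - 1]), censored = FALSE)
}

#' Depolymerization rate from a tip trace
#'
#' Minus the OLS slope of tip position versus time, in um/min. Net growth
#' yields a negative value (returned as-is).
#'
#' @param trace A `tip_trace` with at least 10 tracked frames.
#' @return Depolymerization rate in um/min (positive for shrinkage).
#' @export
depolymerization_rate <- function(trace) {
  stopifnot(inherits(trace, "tip_trace"))
  ok <- !is.na(trace$tip_um)
  if (sum(ok) < 10) stop("need at least 10 tracked frames")
  fit <- stats::lm.fit(cbind(1, trace$frame_times_s[ok] / 60),
                       trace$tip_um[ok])
  -unname(stats::coef(fit)[2])
}
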