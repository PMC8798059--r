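new_filament_trajectory <- function(times_s, lengths_um, phases, origin,
                                    tubulin_uM = NA_real_, label = NA_character_) {
  stopifnot(
    length(times_s) == length(lengths_um),
    length(phases) == length(times_s) - 1,
    all(diff(times_s) > 0), times_s[1] == 0,
    all(lengths_um >= -1e-9)
  )
  structure(
    list(times_s = times_s, lengths_um = pmax(lengths_um, 0), phases = phases,
         origin = origin, tubulin_uM = tubulin_uM, label = label),
    class = "filament_trajectory"
  )
}

#' @export
print.filament_trajectory <- function(x, ...) {
  cat(sprintf(
    "Filament trajectory (%s, '%s', %g uM tubulin): %d breakpoints over %g s; %d growth / %d shrink / %d pause intervals\n",
    x$origin, x$label, x$tubulin_uM, length(x$times_s), max(x$times_s),
    sum(x$phases == "growth"), sum(x$phases == "shrink"), sum(x$phases == "pause")
  ))
  invisible(x)
}

#' @export
plot.filament_trajectory <- function(x, xlab = "time (s)",
                                     ylab = "length (um)", type = "l", ...) {
  graphics::plot(x$times_s, x$lengths_um, type = type, xlab = xlab,
                 ylab = ylab, ...)
  invisible(x)
}

#' Simulate a dynamic microtubule trajectory
#'
#' Generates the piecewise-linear length history of one filament growing
#' from a stabilized seed under the two-state dynamic instability model:
#' growth intervals at the net velocity [growth_velocity()] with
#' exponentially distributed durations (constant catastrophe hazard
#' `f_cat`), alternating with shrinkage at `v_shrink` until the filament
#' returns to the seed (immediate regrowth) or the movie ends. Rescues
#' occur at rate `f_res` during shrinkage (default 0). Each interval's
#' slope is jittered by multiplicative Gaussian noise with coefficient of
#' variation `noise_cv`, emulating filament-to-filament and segment-level
#' variability in measured slopes.
#'
#' @param params A [kinetic_params()] object.
#' @param tubulin_uM Tubulin concentration, uM; the net growth velocity at
#'   this concentration must be positive.
#' @param duration_s Movie duration in seconds (> 0).
#' @param noise_cv Multiplicative slope jitter CV (default 0.1; 0 disables).
#' @param geometry An [mt_geometry()] object.
#' @param seed Optional RNG seed; `NULL` continues the current RNG stream.
#' @return A `filament_trajectory`: breakpoint times (s, starting at 0),
#'   lengths (um beyond the seed) and per-interval phase labels.
#' @examples
#' p <- kinetic_params(k_a = 2.6, C_c = 2.89, f_cat = 0.3)
#' tr <- sample_trajectory(p, tubulin_uM = 10, duration_s = 600, seed = 1)
#' @export
sample_trajectory <- function(params, tubulin_uM, duration_s, noise_cv = 0.1,
                              geometry = mt_geometry(), seed = NULL) {
  stopifnot(duration_s > 0, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  v_g <- growth_velocity(tubulin_uM, params, geometry)
  if (v_g <= 0) {
    stop(sprintf(
      "net growth velocity is %.4g um/min at %g uM tubulin: filament cannot elongate",
      v_g, tubulin_uM
    ))
  }
  jitter <- function(v) {
    if (noise_cv == 0) return(v)
    max(v * (1 + stats::rnorm(1, sd = noise_cv)), 0.05 * v)
  }
  times <- 0
  lengths <- 0
  phases <- character(0)
  t <- 0
  len <- 0
  state <- "growth"
  while (t < duration_s) {
    if (state == "growth") {
      dur <- if (params$f_cat > 0) stats::rexp(1, rate = params$f_cat / 60) else Inf
      t_end <- min(t + dur, duration_s)
      v <- jitter(v_g)
      len <- len + v * (t_end - t) / 60
      times <- c(times, t_end)
      lengths <- c(lengths, len)
      phases <- c(phases, "growth")
      t <- t_end
      state <- "shrink"
    } else {
      if (len <= 0) { state <- "growth"; next }
      v_s <- jitter(params$v_shrink)
      dur_res <- if (params$f_res > 0) stats::rexp(1, rate = params$f_res / 60) else Inf
      t_end <- min(t + len / v_s * 60, t + dur_res, duration_s)
      len <- max(len - v_s * (t_end - t) / 60, 0)
      times <- c(times, t_end)
      lengths <- c(lengths, len)
      phases <- c(phases, "shrink")
      t <- t_end
      state <- "growth"
    }
  }
  new_filament_trajectory(times, lengths, phases, origin = "seed_plus_end",
                          tubulin_uM = tubulin_uM, label = params$label)
}

#' Simulate seed-templated nucleation lags
#'
#' Draws the waiting time for each stabilized seed to nucleate a
#' microtubule. The nucleation hazard is constant in time and calibrated so
#' that the probability of nucleating within 60 s equals the Hill law
#' [hill_probability()]: `lambda(c) = -log(1 - p(c)) / 60` per second.
#' Lags exceeding `t_max_s` are right-censored.
#'
#' @param params A [kinetic_params()] object (its `hill_C`, `hill_s`).
#' @param tubulin_uM Tubulin concentration, uM.
#' @param n_seeds Number of seeds (> 0).
#' @param t_max_s Observation window in seconds; lags beyond it are censored.
#' @param eps Cap tolerance: if the 1-min probability exceeds `1 - eps` the
#'   hazard is capped there and a warning is issued.
#' @param seed Optional RNG seed.
#' @return A data frame with columns `seed_id`, `lag_s` (censored records
#'   carry `t_max_s`) and logical `censored`.
#' @export
sample_nucleation_lags <- function(params, tubulin_uM, n_seeds,
                                   t_max_s = 120, eps = 1e-6, seed = NULL) {
  stopifnot(n_seeds > 0, t_max_s > 0, tubulin_uM >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- hill_probability(tubulin_uM, params$hill_C, params$hill_s)
  if (p > 1 - eps) {
    warning(sprintf(
      "1-min nucleation probability %.3g exceeds 1 - eps; hazard capped", p
    ))
    p <- 1 - eps
  }
  if (p <= 0) {
    lag <- rep(Inf, n_seeds)
  } else {
    lambda <- -log(1 - p) / 60
    lag <- stats::rexp(n_seeds, rate = lambda)
  }
  censored <- lag > t_max_s
  lag[censored] <- t_max_s
  data.frame(seed_id = seq_len(n_seeds), lag_s = lag, censored = censored)
}

#' Simulate spontaneous nucleation counts per field of view
#'
#' Number of microtubules nucleated de novo (no seed template) in one field
#' of view, Poisson-distributed with mean
#' `spont_slope * max(0, c - spont_Cc)`: zero below the spontaneous
#' critical concentration, linear in tubulin above it.
#'
#' @param params A [kinetic_params()] object.
#' @param tubulin_uM Tubulin concentration, uM.
#' @param n_fields Number of fields to draw (default 1).
#' @param seed Optional RNG seed.
#' @return Integer vector of length `n_fields`.
#' @export
sample_spontaneous_count <- function(params, tubulin_uM, n_fields = 1,
                                     seed = NULL) {
  stopifnot(n_fields > 0, tubulin_uM >= 0)
  if (!is.null(seed)) set.seed(seed)
  mu <- params$spont_slope * max(0, tubulin_uM - params$spont_Cc)
  stats::rpois(n_fields, lambda = mu)
}

#' Simulate depolymerization of a GMPCPP-stabilized seed
#'
#' A stabilized seed imaged at regular intervals while it shrinks at the
#' constant speed `v_depoly_gmpcpp`, with optional per-frame Gaussian
#' localization noise on the measured length. With zero noise the trace is
#' exactly linear (and exactly constant when the depolymerization speed is
#' zero, the MAP-saturated case).
#'
#' @param params A [kinetic_params()] object.
#' @param duration_min Total imaging time in minutes (> 0).
#' @param frame_interval_min Frame interval in minutes (> 0).
#' @param initial_length_um Seed length at time zero (default 10 um).
#' @param noise_sd_um Per-frame localization noise SD in um (default 0).
#' @param seed Optional RNG seed.
#' @return A `filament_trajectory` with origin `"gmpcpp_seed"`, sampled at
#'   frame times; monotone non-increasing when `noise_sd_um = 0`.
#' @export
sample_gmpcpp_depolymerization <- function(params, duration_min = 600,
                                           frame_interval_min = 1,
                                           initial_length_um = 10,
                                           noise_sd_um = 0, seed = NULL) {
  stopifnot(duration_min > 0, frame_interval_min > 0, initial_length_um > 0,
            noise_sd_um >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_min <- seq(0, duration_min, by = frame_interval_min)
  len <- pmax(initial_length_um - params$v_depoly_gmpcpp * t_min, 0)
  if (noise_sd_um > 0) {
    len <- pmax(len + stats::rnorm(length(len), sd = noise_sd_um), 0)
  }
  new_filament_trajectory(
    times_s = t_min * 60, lengths_um = len,
    phases = rep("shrink", length(t_min) - 1),
    origin = "gmpcpp_seed", tubulin_uM = 0, label = params$label
  )
}

#' Convert a trajectory to ground-truth phase segments
#'
#' Exact per-interval segments (start, end, slope, phase) of a simulated
#' trajectory, used as the generator truth against which the image-based
#' analysis is validated.
#'
#' @param traj A `filament_trajectory`.
#' @return A data frame with columns `t_start_s`, `t_end_s`,
#'   `slope_um_min`, `phase`.
#' @export
trajectory_segments <- function(traj) {
  stopifnot(inherits(traj, "filament_trajectory"))
  n <- length(traj$times_s)
  dt <- diff(traj$times_s)
  slope <- diff(traj$lengths_um) / dt * 60
  data.frame(
    t_start_s = traj$times_s[-n],
    t_end_s = traj$times_s[-1],
    slope_um_min = slope,
    phase = traj$phases,
    stringsAsFactors = FALSE
  )
}

#' Ground-truth dynamics summary of simulated trajectories
#'
#' Summarizes a list of simulated trajectories directly from their generator
#' phases (no imaging, no segmentation): growth-segment slopes, catastrophe
#' counts (growth intervals terminated by shrinkage) and total growth time.
#' Used as the oracle end of generator/analyzer consistency checks.
#'
#' @param trajs List of `filament_trajectory` objects.
#' @param condition Optional condition label.
#' @return A `dynamics_summary` (see [summarize_dynamics()]).
#' @export
summarize_trajectories <- function(trajs, condition = NULL) {
  seg_list <- lapply(trajs, trajectory_segments)
  summarize_dynamics(seg_list, condition = condition)
}
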