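# Shared fixtures for the test suite. Everything is generated in code.

control_params <- function(...) {
  kinetic_params(k_a = 2.6, C_c = 2.89, hill_C = 6.85, hill_s = 3.37,
                 spont_slope = 2, spont_Cc = 25.4, v_depoly_gmpcpp = 0.013,
                 label = "control", ...)
}

ckap2_500nM_params <- function(...) {
  kinetic_params(k_a = 142, C_c = 0.02, hill_C = 0.05, hill_s = 3.10,
                 spont_slope = 100, spont_Cc = 0.25, label = "ckap2_500nM", ...)
}

# Piecewise-linear trajectory with given breakpoints, built directly (not
# via the stochastic generator), for oracle tests of the analysis layer.
manual_trajectory <- function(times_s, lengths_um, phases,
                              origin = "seed_plus_end") {
  structure(
    list(times_s = times_s, lengths_um = lengths_um, phases = phases,
         origin = origin, tubulin_uM = NA_real_, label = "manual"),
    class = "filament_trajectory"
  )
}

manual_trace <- function(frame_times_s, tip_um) {
  structure(list(frame_times_s = frame_times_s, tip_um = tip_um),
            class = "tip_trace")
}

# Background-only kymograph (Poisson background, no filament).
background_kymograph <- function(n_frames = 30, n_px = 60,
                                 optics = optics_config(), seed = 1) {
  set.seed(seed)
  img <- matrix(stats::rpois(n_frames * n_px, optics$background_photons),
                n_frames, n_px)
  structure(
    list(channels = list(lattice = img), optics = optics,
         frame_times_s = (seq_len(n_frames) - 1) * optics$frame_interval_s,
         seed_extent_um = c(0, 0), origin = "seed_plus_end"),
    class = "kymograph"
  )
}

# Closed-form OLS through the normal equations, as an independent oracle
# for the regression-based estimators.
normal_equations_fit <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
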