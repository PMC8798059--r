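#' Fit the linear growth-kinetics law across a tubulin series
#'
#' Regresses per-concentration mean growth velocities (converted to
#' dimers/s through the lattice geometry) on tubulin concentration by
#' ordinary least squares: `v = k_a * c - k_d`. The apparent critical
#' concentration is `C_c = k_d / k_a`, with its standard error from the
#' delta method using the full coefficient covariance (the two estimates
#' are correlated). Raw per-event velocities may be supplied; they are
#' averaged within concentration before fitting, which is how
#' concentration-series growth curves are conventionally fitted.
#'
#' @param data Data frame with columns `tubulin_uM` and `growth_rate_um_min`
#'   (one row per measured growth event, or already per-concentration means).
#' @param geometry An [mt_geometry()] object.
#' @param weighted If `TRUE`, weight concentration means by event counts.
#' @return An object of class `growth_kinetics_fit` with `k_a`, `k_a_se`
#'   (dimers uM^-1 s^-1), `k_d`, `k_d_se` (dimers/s), `C_c`, `C_c_se` (uM),
#'   `r_squared`, `n_points`, the underlying `lm` fit and the fitted means.
#' @examples
#' p <- kinetic_params(k_a = 2.6, C_c = 2.89)
#' d <- data.frame(tubulin_uM = c(5, 10, 14),
#'                 growth_rate_um_min = growth_velocity(c(5, 10, 14), p))
#' fit <- fit_growth_kinetics(d)
#' coef(fit)
#' @export
fit_growth_kinetics <- function(data, geometry = mt_geometry(),
                                weighted = FALSE) {
  stopifnot(all(c("tubulin_uM", "growth_rate_um_min") %in% names(data)))
  conc <- sort(unique(data$tubulin_uM))
  if (length(conc) < 3) stop("need at least 3 distinct tubulin concentrations")
  means <- vapply(conc, function(cc) {
    mean(data$growth_rate_um_min[data$tubulin_uM == cc])
  }, numeric(1))
  counts <- vapply(conc, function(cc) sum(data$tubulin_uM == cc), numeric(1))
  v_dimers <- um_min_to_dimers_s(means, geometry)
  df <- data.frame(c_uM = conc, v_dimers_s = v_dimers)
  fit <- if (weighted) {
    stats::lm(v_dimers_s ~ c_uM, data = df, weights = counts)
  } else {
    stats::lm(v_dimers_s ~ c_uM, data = df)
  }
  b <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))  # exact fits trip summary.lm
  k_a <- unname(b[2])
  k_d <- -unname(b[1])
  if (k_a <= 0) stop("fitted on-rate is non-positive: no growth kinetics")
  C_c <- k_d / k_a
  # delta method for C_c = -b0/b1: gradient (-1/b1, b0/b1^2)
  g <- c(-1 / b[2], b[1] / b[2]^2)
  C_c_var <- as.numeric(t(g) %*% V %*% g)
  structure(
    list(k_a = k_a, k_a_se = sqrt(V[2, 2]),
         k_d = k_d, k_d_se = sqrt(V[1, 1]),
         C_c = C_c, C_c_se = sqrt(max(C_c_var, 0)),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n_points = length(conc), n_events = sum(counts),
         lm = fit, means = df, geometry = geometry),
    class = "growth_kinetics_fit"
  )
}

#' @export
print.growth_kinetics_fit <- function(x, ...) {
  cat("Growth kinetics (linear regression of mean growth rate vs tubulin)\n")
  cat(sprintf("  k_a = %.4g +/- %.2g dimers uM^-1 s^-1\n", x$k_a, x$k_a_se))
  cat(sprintf("  k_d = %.4g +/- %.2g dimers s^-1\n", x$k_d, x$k_d_se))
  cat(sprintf("  C_c = %.4g +/- %.2g uM\n", x$C_c, x$C_c_se))
  cat(sprintf("  R^2 = %.4f over %d concentrations (%d events)\n",
              x$r_squared, x$n_points, x$n_events))
  invisible(x)
}

#' @export
coef.growth_kinetics_fit <- function(object, ...) {
  c(k_a = object$k_a, k_d = object$k_d, C_c = object$C_c)
}

#' @export
summary.growth_kinetics_fit <- function(object, ...) {
  data.frame(
    parameter = c("k_a", "k_d", "C_c"),
    estimate = c(object$k_a, object$k_d, object$C_c),
    se = c(object$k_a_se, object$k_d_se, object$C_c_se),
    units = c("dimers/uM/s", "dimers/s", "uM")
  )
}

#' @export
predict.growth_kinetics_fit <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$tubulin_uM else newdata
  dimers_s_to_um_min(object$k_a * conc - object$k_d, object$geometry)
}

#' @export
residuals.growth_kinetics_fit <- function(object, ...) {
  stats::residuals(object$lm)
}

#' @export
plot.growth_kinetics_fit <- function(x, xlab = "tubulin (uM)",
                                     ylab = "growth rate (dimers/s)", ...) {
  graphics::plot(x$means$c_uM, x$means$v_dimers_s, xlab = xlab, ylab = ylab,
                 ...)
  graphics::abline(-x$k_d, x$k_a, col = "red")
  invisible(x)
}

#' Endpoint-constrained Hill fit of templated nucleation
#'
#' Nonlinear least squares of per-concentration 1-minute nucleation
#' fractions against the Hill law with endpoints fixed at 0 and 1
#' (`p = c^s / (C^s + c^s)`), estimating the half-max concentration `C`
#' and steepness `s`. Standard errors come from the Jacobian-based
#' covariance. The data must straddle the transition (at least one
#' fraction below 0.5 and one above); otherwise the fit refuses rather
#' than extrapolate. Starting values: `C` at the concentration whose
#' fraction is nearest 0.5, `s = 3`; bounds `C > 0`, `0.5 < s < 20`.
#'
#' @param data Data frame with columns `tubulin_uM` and `fraction`
#'   (and optionally `n`, the seed count per concentration).
#' @return An object of class `hill_fit` with `C`, `C_se`, `s`, `s_se`,
#'   residual summary and the underlying `nls` object.
#' @export
fit_nucleation_hill <- function(data) {
  stopifnot(all(c("tubulin_uM", "fraction") %in% names(data)))
  conc <- data$tubulin_uM
  frac <- data$fraction
  if (length(unique(conc)) < 3) {
    stop("need at least 3 tubulin concentrations")
  }
  if (!any(frac < 0.5) || !any(frac > 0.5)) {
    stop(paste(
      "fractions do not straddle the half-max transition",
      "(need at least one < 0.5 and one > 0.5);",
      "refusing to extrapolate the Hill midpoint"
    ))
  }
  C0 <- conc[which.min(abs(frac - 0.5))]
  fit <- minpack.lm::nlsLM(
    fraction ~ tubulin_uM^s / (C^s + tubulin_uM^s),
    data = data.frame(tubulin_uM = conc, fraction = frac),
    start = list(C = max(C0, 1e-6), s = 3),
    lower = c(C = 1e-9, s = 0.5), upper = c(C = Inf, s = 20),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(C = NA_real_, s = NA_real_))
  structure(
    list(C = unname(est["C"]), C_se = unname(se["C"]),
         s = unname(est["s"]), s_se = unname(se["s"]),
         rss = sum(stats::residuals(fit)^2),
         n_points = length(conc), nls = fit,
         data = data.frame(tubulin_uM = conc, fraction = frac)),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Endpoint-constrained Hill fit of 1-min nucleation probability\n")
  cat(sprintf("  C = %.4g +/- %.2g uM (half-max tubulin concentration)\n",
              x$C, x$C_se))
  cat(sprintf("  s = %.4g +/- %.2g (steepness)\n", x$s, x$s_se))
  cat(sprintf("  RSS = %.3g over %d concentrations\n", x$rss, x$n_points))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) c(C = object$C, s = object$s)

#' @export
predict.hill_fit <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$tubulin_uM else newdata
  hill_probability(conc, object$C, object$s)
}

#' @export
plot.hill_fit <- function(x, xlab = "tubulin (uM)",
                          ylab = "P(nucleated within 1 min)", ...) {
  d <- x$data
  graphics::plot(d$tubulin_uM, d$fraction, xlab = xlab, ylab = ylab, ...)
  grid <- seq(0, max(d$tubulin_uM) * 1.05, length.out = 200)
  graphics::lines(grid, predict(x, grid), col = "red")
  invisible(x)
}

#' Censored empirical distribution of nucleation lags
#'
#' Kaplan-Meier estimate of the cumulative probability to nucleate by time
#' t, honoring right-censoring of seeds that never nucleated within the
#' observation window. With no censoring it reduces to the ordinary
#' empirical CDF; it is invariant to record order.
#'
#' @param records Data frame with columns `lag_s` and logical `censored`
#'   (as from [sample_nucleation_lags()]).
#' @return An object of class `nucleation_ecdf` with `time_s`, `cdf`, and
#'   the underlying `survfit`. Evaluate at arbitrary times with
#'   [ecdf_at()].
#' @export
nucleation_ecdf <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(c("lag_s", "censored") %in% names(records)))
  stopifnot(all(records$lag_s[!records$censored] > 0))
  sf <- survival::survfit(
    survival::Surv(records$lag_s, !records$censored) ~ 1
  )
  structure(
    list(time_s = sf$time, cdf = 1 - sf$surv, n = nrow(records),
         survfit = sf),
    class = "nucleation_ecdf"
  )
}

#' Evaluate a nucleation ECDF at given times
#'
#' @param x A `nucleation_ecdf`.
#' @param t_s Times in seconds.
#' @return Cumulative nucleation probabilities (0 before the first event).
#' @export
ecdf_at <- function(x, t_s) {
  stopifnot(inherits(x, "nucleation_ecdf"))
  f <- stats::stepfun(x$time_s, c(0, x$cdf))
  f(t_s)
}

#' @export
print.nucleation_ecdf <- function(x, ...) {
  cat(sprintf(
    "Censored nucleation ECDF: n = %d seeds, final cumulative probability %.3f at %g s\n",
    x$n, max(x$cdf, 0), max(x$time_s)
  ))
  invisible(x)
}

#' @export
plot.nucleation_ecdf <- function(x, xlab = "time (s)",
                                 ylab = "cumulative probability to nucleate",
                                 ...) {
  graphics::plot(stats::stepfun(x$time_s, c(0, x$cdf)), xlab = xlab,
                 ylab = ylab, do.points = FALSE, ...)
  invisible(x)
}

#' Linear fit of spontaneous nucleation counts
#'
#' Fits mean per-field microtubule counts versus tubulin concentration by
#' OLS, restricted to concentrations whose mean count exceeds a zero-floor
#' threshold (the below-critical plateau is excluded). The critical
#' concentration is the x-intercept `-intercept/slope`, with a
#' delta-method standard error.
#'
#' @param data Data frame with columns `tubulin_uM` and `count` (one row
#'   per field).
#' @param zero_floor Mean-count floor below which a concentration is
#'   considered part of the zero plateau (default 0.5).
#' @return An object of class `spontaneous_fit` with `slope`, `slope_se`
#'   (microtubules field^-1 uM^-1), `critical_conc`, `critical_conc_se`
#'   (uM) and the underlying `lm`.
#' @export
fit_spontaneous_nucleation <- function(data, zero_floor = 0.5) {
  stopifnot(all(c("tubulin_uM", "count") %in% names(data)))
  conc <- sort(unique(data$tubulin_uM))
  if (length(conc) < 3) stop("need at least 3 tubulin concentrations")
  means <- vapply(conc, function(cc) mean(data$count[data$tubulin_uM == cc]),
                  numeric(1))
  keep <- means > zero_floor
  if (sum(keep) < 2) stop("no fit: fewer than 2 concentrations above the zero floor")
  df <- data.frame(c_uM = conc[keep], mean_count = means[keep])
  fit <- stats::lm(mean_count ~ c_uM, data = df)
  b <- stats::coef(fit)
  V <- suppressWarnings(stats::vcov(fit))
  if (unname(b[2]) <= 0) stop("fitted slope is non-positive: no nucleation trend")
  cc <- -unname(b[1]) / unname(b[2])
  g <- c(-1 / b[2], b[1] / b[2]^2)
  cc_var <- as.numeric(t(g) %*% V %*% g)
  structure(
    list(slope = unname(b[2]), slope_se = sqrt(V[2, 2]),
         critical_conc = cc, critical_conc_se = sqrt(max(cc_var, 0)),
         n_points = sum(keep), lm = fit, means = df),
    class = "spontaneous_fit"
  )
}

#' @export
print.spontaneous_fit <- function(x, ...) {
  cat("Spontaneous nucleation (linear fit of mean field counts vs tubulin)\n")
  cat(sprintf("  slope = %.4g +/- %.2g microtubules/field/uM\n",
              x$slope, x$slope_se))
  cat(sprintf("  critical concentration = %.4g +/- %.2g uM\n",
              x$critical_conc, x$critical_conc_se))
  invisible(x)
}

#' @export
coef.spontaneous_fit <- function(object, ...) {
  c(slope = object$slope, critical_conc = object$critical_conc)
}

#' @export
predict.spontaneous_fit <- function(object, newdata, ...) {
  conc <- if (is.data.frame(newdata)) newdata$tubulin_uM else newdata
  pmax(object$slope * (conc - object$critical_conc), 0)
}

#' Catastrophe frequency with bootstrap confidence interval
#'
#' The catastrophe frequency is the total number of catastrophe events
#' divided by the total microtubule growth time in the channel. The
#' confidence interval is a nonparametric percentile bootstrap over
#' filaments (the exchangeable unit): filaments are resampled with
#' replacement and the events/time ratio recomputed.
#'
#' @param summary A `dynamics_summary` from [summarize_dynamics()].
#' @param n_boot Bootstrap replicates (default 10000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return An object of class `catastrophe_frequency` with `frequency`
#'   (min^-1), `n_events`, `total_time_min`, `ci_low`, `ci_high`.
#' @export
catastrophe_frequency <- function(summary, n_boot = 10000, conf = 0.95,
                                  seed = NULL) {
  stopifnot(inherits(summary, "dynamics_summary"))
  if (!is.null(seed)) set.seed(seed)
  pf <- summary$per_filament
  total_time <- sum(pf$growth_time_min)
  if (total_time <= 0) stop("zero total growth time")
  n_events <- sum(pf$n_catastrophes)
  freq <- n_events / total_time
  m <- nrow(pf)
  if (m == 1) {
    ci <- c(freq, freq)
  } else {
    idx <- matrix(sample.int(m, m * n_boot, replace = TRUE), nrow = m)
    ev <- matrix(pf$n_catastrophes[idx], nrow = m)
    tm <- matrix(pf$growth_time_min[idx], nrow = m)
    tsum <- colSums(tm)
    ratio <- colSums(ev)[tsum > 0] / tsum[tsum > 0]
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(ratio, c(alpha, 1 - alpha), type = 7))
  }
  structure(
    list(frequency = freq, n_events = n_events, total_time_min = total_time,
         ci_low = ci[1], ci_high = ci[2], conf = conf, n_boot = n_boot,
         n_filaments = m),
    class = "catastrophe_frequency"
  )
}

#' @export
print.catastrophe_frequency <- function(x, ...) {
  cat(sprintf(
    "Catastrophe frequency: %.4g min^-1 (%d events / %.3g min growth; %g%% CI %.4g-%.4g, %d filaments)\n",
    x$frequency, x$n_events, x$total_time_min, 100 * x$conf, x$ci_low,
    x$ci_high, x$n_filaments
  ))
  invisible(x)
}

#' Fold change of the apparent on-rate between two conditions
#'
#' Ratio `k_a(b) / k_a(a)` with a first-order (delta method) standard
#' error from the two fits' independent uncertainties.
#'
#' @param fit_a,fit_b `growth_kinetics_fit` objects (reference first).
#' @return A list with `ratio` and `se`.
#' @export
fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "growth_kinetics_fit"),
            inherits(fit_b, "growth_kinetics_fit"))
  if (fit_a$k_a == 0) stop("reference k_a is zero")
  r <- fit_b$k_a / fit_a$k_a
  se <- abs(r) * sqrt((fit_a$k_a_se / fit_a$k_a)^2 +
                      (fit_b$k_a_se / fit_b$k_a)^2)
  list(ratio = r, se = se)
}
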