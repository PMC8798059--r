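#' Net growth velocity of a microtubule plus end
#'
#' In the single-site kinetic model the dimer flux at the growing end is
#' `k_a * c - k_d` dimers/s, linear in the free tubulin concentration `c`.
#' The flux is converted to a tip velocity in um/min through the lattice
#' geometry. Below the critical concentration the returned velocity is
#' negative (net disassembly); it is deliberately not clamped so the same
#' law serves depolymerization checks.
#'
#' @param c Tubulin concentration in uM (vectorized, >= 0).
#' @param params A [kinetic_params()] object.
#' @param geometry An [mt_geometry()] object.
#' @return Velocity in um/min.
#' @examples
#' p <- kinetic_params(k_a = 2.6, C_c = 2.89)
#' growth_velocity(8, p)        # ~0.4906 um/min
#' growth_velocity(p$C_c, p)    # 0: definition of the critical concentration
#' @export
growth_velocity <- function(c, params, geometry = mt_geometry()) {
  stopifnot(all(c >= 0))
  dimers_s_to_um_min(params$k_a * c - params$k_d, geometry)
}

#' Apparent critical concentration
#'
#' The tubulin concentration at which net elongation stalls: `C_c = k_d / k_a`.
#'
#' @param params A [kinetic_params()] object.
#' @return Critical concentration in uM.
#' @export
critical_concentration <- function(params) {
  if (params$k_a <= 0) stop("critical concentration requires k_a > 0")
  params$k_d / params$k_a
}

#' Endpoint-constrained Hill law for templated nucleation
#'
#' Probability that a stabilized seed nucleates a microtubule within one
#' minute, as a function of tubulin concentration: a Hill curve forced to
#' start at 0 and end at 1, `p(c) = c^s / (C^s + c^s)`, with half-max
#' concentration `C` and steepness `s`. Monotone increasing in `c`,
#' `p(C) = 0.5` for every `s`.
#'
#' @param c Tubulin concentration in uM (vectorized, >= 0).
#' @param C Half-maximal concentration, uM (> 0).
#' @param s Steepness (> 0).
#' @return Probability in `[0, 1]`.
#' @examples
#' hill_probability(6.85, C = 6.85, s = 3.37)  # 0.5
#' @export
hill_probability <- function(c, C, s) {
  stopifnot(all(c >= 0), C > 0, s > 0)
  # computed via the ratio (c/C)^s for numerical stability at extreme c
  r <- (c / C)^s
  p <- r / (1 + r)
  p[r == Inf] <- 1
  p[c == 0] <- 0
  p
}
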