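#' Experimental condition descriptor
#'
#' A lightweight record identifying one assay condition: the free tubulin
#' concentration, the concentration of the microtubule-associated protein
#' under study (CKAP2 in the bundled defaults), and whether filaments grow
#' from stabilized seed templates or nucleate spontaneously.
#'
#' @param tubulin_uM Tubulin concentration in uM (>= 0).
#' @param ckap2_nM MAP concentration in nM (>= 0).
#' @param label Non-empty condition label.
#' @param seeded Logical; `TRUE` for the seed-templated assay.
#' @return An object of class `experiment_condition`.
#' @export
experiment_condition <- function(tubulin_uM, ckap2_nM = 0, label = "control",
                                 seeded = TRUE) {
  stopifnot(
    is.numeric(tubulin_uM), length(tubulin_uM) == 1, tubulin_uM >= 0,
    is.numeric(ckap2_nM), length(ckap2_nM) == 1, ckap2_nM >= 0,
    is.character(label), length(label) == 1, nzchar(label),
    is.logical(seeded), length(seeded) == 1
  )
  structure(
    list(tubulin_uM = tubulin_uM, ckap2_nM = ckap2_nM, label = label,
         seeded = seeded),
    class = "experiment_condition"
  )
}

#' @export
print.experiment_condition <- function(x, ...) {
  cat(sprintf("Condition '%s': %g uM tubulin, %g nM CKAP2, %s\n",
              x$label, x$tubulin_uM, x$ckap2_nM,
              if (x$seeded) "seed-templated" else "spontaneous"))
  invisible(x)
}

#' Kinetic parameters of one condition
#'
#' Houses the per-condition rate law shared by the simulator and the
#' estimators: the apparent tubulin on-rate constant `k_a`
#' (dimers uM^-1 s^-1) and off-rate `k_d` (dimers s^-1) of the linear
#' growth law `v = k_a * c - k_d`, the catastrophe rate `f_cat` (min^-1),
#' the shrinkage speed `v_shrink` (um/min, positive magnitude), the
#' endpoint-constrained Hill law for seed-templated nucleation within one
#' minute (`hill_C` uM half-max, `hill_s` steepness), the spontaneous
#' nucleation law (Poisson field counts with mean
#' `spont_slope * max(0, c - spont_Cc)`), the depolymerization speed of
#' GMPCPP-stabilized seeds, and an optional rescue rate (default 0: in this
#' system shrinkage virtually always proceeds back to the seed).
#'
#' Exactly one of `k_d` or `C_c` must be given; the other is derived from
#' `C_c = k_d / k_a`.
#'
#' @param k_a Apparent on-rate constant, dimers uM^-1 s^-1 (> 0).
#' @param k_d Apparent off-rate, dimers s^-1 (>= 0).
#' @param C_c Apparent critical concentration, uM (alternative to `k_d`).
#' @param f_cat Catastrophe rate in growth time, min^-1 (>= 0).
#' @param v_shrink Shrinkage speed, um/min (> 0).
#' @param hill_C Half-max tubulin concentration of the nucleation Hill law, uM.
#' @param hill_s Steepness of the nucleation Hill law.
#' @param spont_slope Spontaneous nucleation slope, microtubules field^-1 uM^-1.
#' @param spont_Cc Critical tubulin concentration for spontaneous nucleation, uM.
#' @param v_depoly_gmpcpp GMPCPP seed depolymerization speed, um/min (>= 0).
#' @param f_res Rescue rate in shrinkage time, min^-1 (default 0).
#' @param label Condition label.
#' @return An object of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(k_a = 2.6, C_c = 2.89)
#' p$k_d  # 7.514
#' @export
kinetic_params <- function(k_a, k_d = NULL, C_c = NULL, f_cat = 0,
                           v_shrink = 10, hill_C = 1, hill_s = 3,
                           spont_slope = 0, spont_Cc = 0,
                           v_depoly_gmpcpp = 0, f_res = 0,
                           label = "unnamed") {
  stopifnot(is.numeric(k_a), length(k_a) == 1, k_a > 0)
  if (is.null(k_d) && is.null(C_c)) {
    stop("one of 'k_d' or 'C_c' must be supplied")
  }
  if (is.null(k_d)) k_d <- k_a * C_c
  if (is.null(C_c)) C_c <- k_d / k_a
  if (abs(k_d - k_a * C_c) > 1e-8 * max(1, k_d)) {
    stop("'k_d' and 'C_c' are inconsistent: C_c must equal k_d / k_a")
  }
  stopifnot(
    k_d >= 0, f_cat >= 0, v_shrink > 0, hill_C > 0, hill_s > 0,
    spont_slope >= 0, spont_Cc >= 0, v_depoly_gmpcpp >= 0, f_res >= 0
  )
  structure(
    list(k_a = k_a, k_d = k_d, C_c = C_c, f_cat = f_cat, v_shrink = v_shrink,
         hill_C = hill_C, hill_s = hill_s, spont_slope = spont_slope,
         spont_Cc = spont_Cc, v_depoly_gmpcpp = v_depoly_gmpcpp,
         f_res = f_res, label = label),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters for '%s'\n", x$label))
  cat(sprintf("  growth:      k_a = %g dimers/uM/s, k_d = %g dimers/s, C_c = %g uM\n",
              x$k_a, x$k_d, x$C_c))
  cat(sprintf("  instability: f_cat = %g /min, v_shrink = %g um/min, f_res = %g /min\n",
              x$f_cat, x$v_shrink, x$f_res))
  cat(sprintf("  nucleation:  Hill C = %g uM, s = %g; spontaneous slope = %g /field/uM above Cc = %g uM\n",
              x$hill_C, x$hill_s, x$spont_slope, x$spont_Cc))
  cat(sprintf("  seed depolymerization: %g um/min\n", x$v_depoly_gmpcpp))
  invisible(x)
}

#' Bundled per-condition parameter table
#'
#' Default kinetic parameters for a tubulin-alone control and four CKAP2
#' concentrations, populated from concentration-series fits of in vitro
#' reconstitution data (growth kinetics, templated-nucleation Hill curves,
#' spontaneous nucleation, seed depolymerization). Quantities never reported
#' per condition (catastrophe rates, spontaneous slopes, and kinetic
#' constants at conditions where only nucleation was assayed) carry
#' documented working defaults; see the package vignette for the provenance
#' of each column.
#'
#' @return A data frame, one row per condition, with unit-suffixed columns.
#' @export
default_conditions <- function() {
  data.frame(
    label = c("control", "ckap2_125nM", "ckap2_200nM", "ckap2_500nM", "ckap2_1uM"),
    ckap2_nM = c(0, 125, 200, 500, 1000),
    k_a_dimers_uM_s = c(2.6, 109.2, 120, 142, 142),
    C_c_uM = c(2.89, 0.05, 0.03, 0.02, 0.02),
    f_cat_per_min = c(0.3, 0.05, 0.03, 0.02, 0.01),
    v_shrink_um_min = c(10, 10, 10, 10, 10),
    hill_C_uM = c(6.85, 0.18, 0.10, 0.05, 0.05),
    hill_s = c(3.37, 6.96, 3.5, 3.10, 3.79),
    spont_slope_per_uM = c(2, 100, 100, 100, 100),
    spont_Cc_uM = c(25.4, 0.25, 0.25, 0.25, 0.25),
    v_depoly_um_min = c(0.013, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Look up the kinetic parameters of a bundled condition
#'
#' @param label Row label in `conditions`.
#' @param conditions A condition table as returned by [default_conditions()].
#' @return A [kinetic_params()] object.
#' @examples
#' condition_params("control")$C_c  # 2.89
#' @export
condition_params <- function(label, conditions = default_conditions()) {
  i <- match(label, conditions$label)
  if (is.na(i)) {
    stop(sprintf("unknown condition '%s'; available: %s", label,
                 paste(conditions$label, collapse = ", ")))
  }
  r <- conditions[i, ]
  kinetic_params(
    k_a = r$k_a_dimers_uM_s, C_c = r$C_c_uM, f_cat = r$f_cat_per_min,
    v_shrink = r$v_shrink_um_min, hill_C = r$hill_C_uM, hill_s = r$hill_s,
    spont_slope = r$spont_slope_per_uM, spont_Cc = r$spont_Cc_uM,
    v_depoly_gmpcpp = r$v_depoly_um_min, label = r$label
  )
}

#' Read or write a condition/parameter table
#'
#' Delimited-text (tab-separated) persistence for condition tables in the
#' [default_conditions()] layout: one row per condition, header with
#' unit-suffixed column names. Unknown extra columns are preserved.
#'
#' @param path File path.
#' @param conditions Condition table to write.
#' @return `read_condition_table` returns the table as a data frame.
#' @export
read_condition_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- setdiff(names(default_conditions()), NULL)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("condition table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

#' @rdname read_condition_table
#' @export
write_condition_table <- function(conditions, path) {
  utils::write.table(conditions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
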