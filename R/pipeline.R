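#' Pipeline run configuration
#'
#' Assembles the full experimental design of a simulation-to-fit run. The
#' defaults reproduce the bundled reference experiment: growth kinetics for
#' the control (tubulin 5-14 uM) and 500 nM CKAP2 (0.05-0.3 uM) conditions
#' with 150 filaments per concentration analyzed through the
#' render/track/segment loop; templated-nucleation Hill curves at 150 seeds
#' per concentration; spontaneous-nucleation field counts; and a
#' stabilized-seed depolymerization movie (600 frames at 1 min).
#'
#' @param seed Mandatory RNG seed for the whole run.
#' @param outdir Optional output directory; when given, event tables and
#'   fit tables are written there as delimited text.
#' @param imaging If `TRUE` (default) the growth and depolymerization
#'   assays go through the synthetic-imaging loop (render, track, segment);
#'   if `FALSE` trajectories are analyzed directly (table mode, much
#'   faster, no imaging noise).
#' @param conditions Condition parameter table ([default_conditions()] layout).
#' @param geometry,optics Geometry and optics settings.
#' @param growth,templated,spontaneous,depolymerization Per-assay settings
#'   lists; see the defaults for the expected fields. Set an assay to
#'   `NULL` to skip it.
#' @param noise_cv Trajectory slope jitter CV.
#' @param analysis Analysis thresholds (`min_segment`, `shrink_threshold`,
#'   `pause_band`, `penalty`, `track_k`, `track_mode`, `min_reliable_um`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(
    seed,
    outdir = NULL,
    imaging = TRUE,
    conditions = default_conditions(),
    geometry = mt_geometry(),
    optics = optics_config(),
    noise_cv = 0.1,
    growth = list(
      conditions = c("control", "ckap2_500nM"),
      tubulin_uM = list(control = c(5, 8, 11, 14),
                        ckap2_500nM = c(0.05, 0.1, 0.2, 0.3)),
      n_filaments = 150, duration_s = 600
    ),
    templated = list(
      conditions = c("control", "ckap2_500nM"),
      tubulin_uM = list(
        control = c(2, 4, 6, 8, 10, 12, 16, 20),
        ckap2_500nM = c(0.01, 0.02, 0.035, 0.05, 0.075, 0.1, 0.15, 0.2)
      ),
      n_seeds = 150, t_max_s = 120
    ),
    spontaneous = list(
      conditions = c("control", "ckap2_200nM"),
      tubulin_uM = list(control = c(26, 30, 35, 40, 45, 50),
                        ckap2_200nM = c(0.3, 0.35, 0.4, 0.45, 0.5)),
      n_fields = list(control = 20, ckap2_200nM = 14)
    ),
    depolymerization = list(
      conditions = "control", duration_min = 600, frame_interval_min = 1,
      initial_length_um = 10
    ),
    analysis = list(min_segment = 3, shrink_threshold = 1, pause_band = 0.05,
                    penalty = 3, track_k = 3, track_mode = "model",
                    min_reliable_um = 0)) {
  if (missing(seed) || is.null(seed)) stop("a run seed is mandatory")
  all_cond <- unique(c(growth$conditions, templated$conditions,
                       spontaneous$conditions, depolymerization$conditions))
  unknown <- setdiff(all_cond, conditions$label)
  if (length(unknown) > 0) {
    stop("conditions without parameters: ", paste(unknown, collapse = ", "))
  }
  structure(
    list(seed = seed, outdir = outdir, imaging = imaging,
         conditions = conditions, geometry = geometry, optics = optics,
         noise_cv = noise_cv, growth = growth, templated = templated,
         spontaneous = spontaneous, depolymerization = depolymerization,
         analysis = analysis),
    class = "run_config"
  )
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

# growth assay for one condition: simulate filaments at each tubulin
# concentration, optionally render + track + segment, return growth-rate
# samples and per-filament dynamics.
run_growth_condition <- function(label, config) {
  params <- condition_params(label, config$conditions)
  concs <- config$growth$tubulin_uM[[label]]
  if (is.null(concs)) stop("no tubulin series configured for ", label)
  a <- config$analysis
  rates <- list()
  seg_lists <- list()
  for (cc in concs) {
    segs_here <- vector("list", config$growth$n_filaments)
    for (i in seq_len(config$growth$n_filaments)) {
      traj <- sample_trajectory(params, cc, config$growth$duration_s,
                                noise_cv = config$noise_cv,
                                geometry = config$geometry)
      if (config$imaging) {
        kymo <- render_kymograph(traj, config$optics)
        trace <- track_tip(kymo, k = a$track_k, mode = a$track_mode)
        segs <- segment_phases(trace, min_segment = a$min_segment,
                               shrink_threshold = a$shrink_threshold,
                               pause_band = a$pause_band,
                               penalty = a$penalty,
                               min_reliable_um = a$min_reliable_um)
      } else {
        segs <- trajectory_segments(traj)
      }
      segs$tubulin_uM <- cc
      segs_here[[i]] <- segs
    }
    g <- do.call(rbind, lapply(segs_here, function(s) s[s$phase == "growth", ]))
    rates[[as.character(cc)]] <- data.frame(
      tubulin_uM = cc, slope_um_min = g$slope_um_min,
      duration_s = g$t_end_s - g$t_start_s,
      # observed time at reliably localizable tip positions; segments whose
      # slope could not be measured in that regime get zero pooling weight
      weight_s = if ("reliable_s" %in% names(g)) g$reliable_s
                 else g$t_end_s - g$t_start_s
    )
    seg_lists[[as.character(cc)]] <- segs_here
  }
  rate_df <- do.call(rbind, rates)
  # per-concentration mean growth rate weighted by segment duration: the
  # automated analogue of measuring long hand-drawn kymograph lines (total
  # growth displacement over total growth time); immune to the short
  # segmentation fragments that arise around catastrophes
  mean_df <- do.call(rbind, lapply(split(rate_df, rate_df$tubulin_uM),
    function(d) data.frame(
      tubulin_uM = d$tubulin_uM[1],
      growth_rate_um_min = sum(d$slope_um_min * d$weight_s) / sum(d$weight_s)
    )))
  fit <- fit_growth_kinetics(mean_df, geometry = config$geometry)
  fit$n_events <- nrow(rate_df)  # measured growth events behind the means
  freqs <- lapply(names(seg_lists), function(nm) {
    catastrophe_frequency(
      summarize_dynamics(seg_lists[[nm]],
                         condition = sprintf("%s @ %s uM", label, nm)),
      n_boot = 2000
    )
  })
  names(freqs) <- names(seg_lists)
  list(fit = fit, rates = rate_df, means = mean_df, segments = seg_lists,
       catastrophe = freqs)
}

run_templated_condition <- function(label, config) {
  params <- condition_params(label, config$conditions)
  concs <- config$templated$tubulin_uM[[label]]
  if (is.null(concs)) stop("no tubulin series configured for ", label)
  recs <- list()
  frac <- numeric(length(concs))
  for (q in seq_along(concs)) {
    r <- sample_nucleation_lags(params, concs[q], config$templated$n_seeds,
                                t_max_s = config$templated$t_max_s)
    r$tubulin_uM <- concs[q]
    recs[[q]] <- r
    frac[q] <- mean(r$lag_s <= 60 & !r$censored)
  }
  fit <- fit_nucleation_hill(data.frame(tubulin_uM = concs, fraction = frac,
                                        n = config$templated$n_seeds))
  list(fit = fit, fractions = data.frame(tubulin_uM = concs, fraction = frac),
       records = do.call(rbind, recs))
}

run_spontaneous_condition <- function(label, config) {
  params <- condition_params(label, config$conditions)
  concs <- config$spontaneous$tubulin_uM[[label]]
  n_fields <- config$spontaneous$n_fields[[label]]
  if (is.null(concs) || is.null(n_fields)) {
    stop("no spontaneous design configured for ", label)
  }
  counts <- do.call(rbind, lapply(concs, function(cc) {
    data.frame(tubulin_uM = cc,
               count = sample_spontaneous_count(params, cc, n_fields))
  }))
  list(fit = fit_spontaneous_nucleation(counts), counts = counts)
}

run_depoly_condition <- function(label, config) {
  params <- condition_params(label, config$conditions)
  d <- config$depolymerization
  traj <- sample_gmpcpp_depolymerization(
    params, duration_min = d$duration_min,
    frame_interval_min = d$frame_interval_min,
    initial_length_um = d$initial_length_um
  )
  if (config$imaging) {
    optics <- config$optics
    # depolymerization movies use the slowest supported acquisition rate
    optics$frame_interval_s <- 60
    kymo <- render_kymograph(traj, optics,
                             max_width_um = d$initial_length_um + 10)
    trace <- track_tip(kymo, k = config$analysis$track_k,
                       mode = config$analysis$track_mode)
    rate <- depolymerization_rate(trace)
  } else {
    trace <- trace_from_trajectory(traj, d$frame_interval_min * 60)
    rate <- depolymerization_rate(trace)
  }
  list(rate_um_min = rate, trajectory = traj)
}

#' Run the full simulation-analysis-fit pipeline
#'
#' Executes every configured assay for every configured condition:
#' simulates trajectories / lags / counts, optionally renders and tracks
#' synthetic kymographs, segments phases, and produces the per-condition
#' fits (growth kinetics, Hill nucleation, spontaneous nucleation,
#' catastrophe frequencies, depolymerization rates). The run is
#' deterministic for a fixed config seed. A failing condition is recorded
#' in `errors` and skipped; the run continues.
#'
#' @param config A [run_config()].
#' @return An object of class `mt_results`: per-assay named lists of
#'   results, `errors`, and `provenance` (config hash, seed, package
#'   version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  results <- list(growth = list(), templated = list(), spontaneous = list(),
                  depolymerization = list())
  errors <- list()
  run_safe <- function(assay, label, fun) {
    tryCatch(fun(label, config), error = function(e) {
      errors[[paste(assay, label, sep = ":")]] <<- conditionMessage(e)
      NULL
    })
  }
  for (label in config$growth$conditions) {
    results$growth[[label]] <- run_safe("growth", label, run_growth_condition)
  }
  for (label in config$templated$conditions) {
    results$templated[[label]] <-
      run_safe("templated", label, run_templated_condition)
  }
  for (label in config$spontaneous$conditions) {
    results$spontaneous[[label]] <-
      run_safe("spontaneous", label, run_spontaneous_condition)
  }
  for (label in config$depolymerization$conditions) {
    results$depolymerization[[label]] <-
      run_safe("depolymerization", label, run_depoly_condition)
  }
  out <- structure(
    list(growth = results$growth, templated = results$templated,
         spontaneous = results$spontaneous,
         depolymerization = results$depolymerization,
         errors = errors,
         provenance = list(
           config_hash = config_hash(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("mtkinetics"))
         )),
    class = "mt_results"
  )
  if (!is.null(config$outdir)) write_results(out, config$outdir)
  out
}

#' Fit table of a pipeline run
#'
#' One row per fitted quantity across all conditions, with estimate,
#' standard error and units.
#'
#' @param results An `mt_results` object.
#' @return A data frame.
#' @export
results_fit_table <- function(results) {
  rows <- list()
  add <- function(condition, assay, quantity, estimate, se, units) {
    rows[[length(rows) + 1]] <<- data.frame(
      condition = condition, assay = assay, quantity = quantity,
      estimate = estimate, se = se, units = units, stringsAsFactors = FALSE
    )
  }
  for (label in names(results$growth)) {
    f <- results$growth[[label]]$fit
    if (is.null(f)) next
    add(label, "growth", "k_a", f$k_a, f$k_a_se, "dimers/uM/s")
    add(label, "growth", "k_d", f$k_d, f$k_d_se, "dimers/s")
    add(label, "growth", "C_c", f$C_c, f$C_c_se, "uM")
    for (cc in names(results$growth[[label]]$catastrophe)) {
      fr <- results$growth[[label]]$catastrophe[[cc]]
      add(label, "growth",
          sprintf("f_cat @ %s uM", cc), fr$frequency,
          (fr$ci_high - fr$ci_low) / 4, "1/min")
    }
  }
  for (label in names(results$templated)) {
    f <- results$templated[[label]]$fit
    if (is.null(f)) next
    add(label, "templated_nucleation", "hill_C", f$C, f$C_se, "uM")
    add(label, "templated_nucleation", "hill_s", f$s, f$s_se, "")
  }
  for (label in names(results$spontaneous)) {
    f <- results$spontaneous[[label]]$fit
    if (is.null(f)) next
    add(label, "spontaneous_nucleation", "slope", f$slope, f$slope_se,
        "MT/field/uM")
    add(label, "spontaneous_nucleation", "critical_conc", f$critical_conc,
        f$critical_conc_se, "uM")
  }
  for (label in names(results$depolymerization)) {
    r <- results$depolymerization[[label]]
    if (is.null(r)) next
    add(label, "depolymerization", "v_depoly", r$rate_um_min, NA_real_,
        "um/min")
  }
  do.call(rbind, rows)
}

write_results <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(results_fit_table(results),
                     file.path(outdir, "fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (label in names(results$growth)) {
    r <- results$growth[[label]]
    if (is.null(r)) next
    segs <- do.call(rbind, lapply(seq_along(r$segments), function(q) {
      per_conc <- r$segments[[q]]
      do.call(rbind, lapply(seq_along(per_conc), function(i) {
        s <- per_conc[[i]]
        s$filament_id <- sprintf("%s_c%d_f%d", label, q, i)
        s$condition <- label
        s
      }))
    }))
    write_event_table(segs, file.path(outdir, sprintf("segments_%s.tsv", label)))
  }
  for (label in names(results$templated)) {
    r <- results$templated[[label]]
    if (is.null(r)) next
    write_nucleation_table(
      r$records, file.path(outdir, sprintf("nucleation_%s.tsv", label))
    )
  }
  prov <- results$provenance
  yaml::write_yaml(prov, file.path(outdir, "provenance.yaml"))
  invisible(outdir)
}

#' @export
print.mt_results <- function(x, ...) {
  report(x)
}

#' Human-readable summary report of a pipeline run
#'
#' Prints every fitted quantity in `estimate +/- SE unit` form, grouped by
#' assay and condition, plus any per-condition failures.
#'
#' @param results An `mt_results` object.
#' @return The fit table, invisibly.
#' @export
report <- function(results) {
  stopifnot(inherits(results, "mt_results"))
  tab <- results_fit_table(results)
  cat("== Pipeline results ==\n")
  if (is.null(tab) || nrow(tab) == 0) {
    cat("(no successful fits)\n")
  } else {
    for (assay in unique(tab$assay)) {
      cat(sprintf("-- %s --\n", assay))
      sub <- tab[tab$assay == assay, ]
      for (i in seq_len(nrow(sub))) {
        se_txt <- if (is.na(sub$se[i])) "" else sprintf(" +/- %.3g", sub$se[i])
        cat(sprintf("  %-12s %-14s = %.4g%s %s\n", sub$condition[i],
                    sub$quantity[i], sub$estimate[i], se_txt, sub$units[i]))
      }
    }
  }
  if (length(results$errors) > 0) {
    cat("-- failures --\n")
    for (nm in names(results$errors)) {
      cat(sprintf("  %s: %s\n", nm, results$errors[[nm]]))
    }
  }
  cat(sprintf("seed %s, config %s\n", results$provenance$seed,
              results$provenance$config_hash))
  invisible(tab)
}

#' @export
plot.mt_results <- function(x, ...) {
  n <- length(x$growth) + length(x$templated) + length(x$spontaneous)
  if (n == 0) stop("nothing to plot")
  old <- graphics::par(mfrow = c(1, max(
    (length(x$growth) > 0) + (length(x$templated) > 0) +
      (length(x$spontaneous) > 0), 1)))
  on.exit(graphics::par(old))
  if (length(x$growth) > 0) {
    f <- x$growth[[1]]$fit
    if (!is.null(f)) plot(f, main = names(x$growth)[1])
  }
  if (length(x$templated) > 0) {
    f <- x$templated[[1]]$fit
    if (!is.null(f)) plot(f, main = names(x$templated)[1])
  }
  if (length(x$spontaneous) > 0) {
    f <- x$spontaneous[[1]]
    if (!is.null(f$fit)) {
      graphics::plot(f$counts$tubulin_uM, f$counts$count,
                     xlab = "tubulin (uM)", ylab = "microtubules/field",
                     main = names(x$spontaneous)[1])
      graphics::abline(-f$fit$critical_conc * f$fit$slope, f$fit$slope,
                       col = "red")
    }
  }
  invisible(x)
}
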