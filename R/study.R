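# Evaluative-study machinery: the paired Wilcoxon signed-rank test with the
# tie-omission and small-sample skip rules, cohort comparison tables, the
# two-calibration propagation experiment, and the end-to-end synthetic study
# runner.

#' Two-sided Wilcoxon signed-rank test with tie omission and n < 10 rule
#'
#' Differences `x - y` that are exactly zero are omitted; if fewer than 10
#' nonzero differences remain the comparison is reported as not tested.
#' Otherwise the two-sided signed-rank p value is computed by exact
#' enumeration of all 2^n sign assignments (ties in |d| handled through
#' average ranks) for n <= 15, and by the normal approximation with tie
#' correction and continuity correction for n > 15.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return object of class `wilcoxon_result`: list with `tested` (logical),
#'   `p` (`NA` when not tested), `n` (nonzero differences), `statistic`
#'   (the positive-rank sum W+), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("empty input")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 10) {
    return(structure(list(tested = FALSE, p = NA_real_, n = n,
                          statistic = NA_real_, method = "not tested (n < 10)"),
                     class = "wilcoxon_result"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 15) {
    # exact: null distribution of W+ over all sign assignments
    signs <- matrix(FALSE, nrow = 2^n, ncol = n)
    for (j in seq_len(n))
      signs[, j] <- bitwAnd(0:(2^n - 1), bitwShiftL(1L, j - 1L)) > 0
    Wdist <- as.numeric(signs %*% r)
    eps <- 1e-9
    p <- 2 * min(mean(Wdist <= W + eps), mean(Wdist >= W - eps))
    p <- min(1, p)
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie + continuity corrected)"
  }
  structure(list(tested = TRUE, p = p, n = n, statistic = W, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$tested)
    cat(sprintf("Wilcoxon signed rank: W+ = %g, n = %d, p = %.6g (%s)\n",
                x$statistic, x$n, x$p, x$method))
  else
    cat(sprintf("Wilcoxon signed rank: not tested (n = %d < 10 after tie omission)\n",
                x$n))
  invisible(x)
}

#' Assemble a two-arm cohort result
#'
#' @param table long data.frame with columns `patient`, `arm`, `metric`,
#'   `value`; both arms must cover identical patients and metrics.
#' @param arms length-2 character of arm labels, test arm first.
#' @param seeds optional per-patient seeds recorded for reproducibility.
#' @export
cohort_result <- function(table, arms, seeds = NULL) {
  stopifnot(all(c("patient", "arm", "metric", "value") %in% names(table)),
            length(arms) == 2, all(table$arm %in% arms))
  for (a in arms) {
    sub <- table[table$arm == a, ]
    key <- interaction(sub$patient, sub$metric, drop = TRUE)
    if (anyDuplicated(key)) stop("duplicate patient/metric rows in an arm")
  }
  k1 <- with(table[table$arm == arms[1], ], paste(patient, metric))
  k2 <- with(table[table$arm == arms[2], ], paste(patient, metric))
  if (!setequal(k1, k2)) stop("arms do not cover identical patients and metrics")
  structure(list(table = table, arms = arms, seeds = seeds),
            class = "cohort_result")
}

#' Paired comparison table for a cohort result
#'
#' Per metric: mean and standard deviation per arm, the Wilcoxon signed-rank
#' outcome under the tie-omission / n < 10 rules, and a significance flag at
#' p <= 0.05.  Paired per-patient values (1-1 scatter data) are attached as
#' attribute `pairs`.
#'
#' @param result a [cohort_result()].
#' @param metrics optional subset of metric names (defaults to all).
#' @param alpha significance level (default 0.05).
#' @return data.frame with one row per metric.
#' @export
compare_cohorts <- function(result, metrics = NULL, alpha = 0.05) {
  stopifnot(inherits(result, "cohort_result"))
  tb <- result$table
  if (is.null(metrics)) metrics <- unique(tb$metric)
  a1 <- result$arms[1]; a2 <- result$arms[2]
  rows <- list(); pairs <- list()
  for (m in metrics) {
    s1 <- tb[tb$metric == m & tb$arm == a1, ]
    s2 <- tb[tb$metric == m & tb$arm == a2, ]
    s1 <- s1[order(s1$patient), ]; s2 <- s2[order(s2$patient), ]
    w <- wilcoxon_signed_rank(s1$value, s2$value)
    rows[[m]] <- data.frame(
      metric = m,
      mean_1 = mean(s1$value), sd_1 = stats::sd(s1$value),
      mean_2 = mean(s2$value), sd_2 = stats::sd(s2$value),
      p_value = w$p, tested = w$tested,
      significant = isTRUE(w$tested) && !is.na(w$p) && w$p <= alpha,
      stringsAsFactors = FALSE
    )
    pairs[[m]] <- data.frame(metric = m, patient = s1$patient,
                             value_1 = s1$value, value_2 = s2$value,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[2:5] <- c(paste0("mean_", a1), paste0("sd_", a1),
                       paste0("mean_", a2), paste0("sd_", a2))
  attr(out, "pairs") <- do.call(rbind, pairs)
  out
}

#' Render a comparison table as formatted text
#'
#' Mean +/- SD per arm, the p value (or the not-tested marker), significant
#' rows flagged with `*`.
#' @param comparison output of [compare_cohorts()].
#' @param arms the two arm labels, in column order.
#' @export
format_comparison <- function(comparison, arms = c("arm1", "arm2")) {
  p_txt <- ifelse(comparison$tested,
                  sprintf("%.3f", comparison$p_value), "n < 10")
  lines <- sprintf("%-28s %14s %14s %8s%s",
                   comparison$metric,
                   sprintf("%.2f +/- %.2f", comparison[[2]], comparison[[3]]),
                   sprintf("%.2f +/- %.2f", comparison[[4]], comparison[[5]]),
                   p_txt,
                   ifelse(comparison$significant, " *", ""))
  header <- sprintf("%-28s %14s %14s %8s", "Metric", arms[1], arms[2], "p")
  paste(c(header, lines), collapse = "\n")
}

# ---- metric panels -----------------------------------------------------

#' Default study metric panel
#'
#' The quantitative comparison panel: per-PTV D98%, D99%, D2% and HI on the
#' subtraction-convention reporting masks, Paddick CI at 95% of each PTV's
#' nominal prescription, the OAR dose-volume levels of the clinical goal
#' table, OAR mean doses and external-dose spill metrics.
#'
#' @param profile `"instA"` or `"instB"`.
#' @return list of metric specs (see [navigate_metrics()]).
#' @export
study_metric_panel <- function(profile = c("instA", "instB")) {
  profile <- match.arg(profile)
  sp <- list()
  presc <- c("PTV60" = 60, "PTV57.5" = 57.5, "PTV48" = 48)
  for (ptv in names(presc)) {
    sp <- c(sp, list(
      list(kind = "D_percent", roi = ptv, param = 98, subtract = TRUE),
      list(kind = "D_percent", roi = ptv, param = 99, subtract = TRUE),
      list(kind = "D_percent", roi = ptv, param = 2, subtract = TRUE),
      list(kind = "HI", roi = ptv, subtract = TRUE),
      list(kind = "CI", roi = ptv, param = 0.95 * presc[[ptv]])
    ))
  }
  for (lev in c(24.3, 32.4, 40.5, 48.6, 52.7, 56.8, 60.0))
    sp <- c(sp, list(list(kind = "V_dose_percent", roi = "Rectum", param = lev)))
  sp <- c(sp, list(list(kind = "Dmean", roi = "Rectum")))
  for (lev in c(40.5, 48.6, 60.0))
    sp <- c(sp, list(list(kind = "V_dose_percent", roi = "Bladder", param = lev)))
  sp <- c(sp, list(
    list(kind = "Dmean", roi = "Bladder"),
    list(kind = "D_abs_volume", roi = "External", param = 1.8),
    list(kind = "V_dose_percent", roi = "External", param = 5.0)
  ))
  if (profile == "instB") {
    sp <- c(sp, list(
      list(kind = "V_dose_abs", roi = "Bowel", param = 40.5),
      list(kind = "V_dose_percent", roi = "FemoralHead_L", param = 40.5),
      list(kind = "V_dose_percent", roi = "FemoralHead_R", param = 40.5)
    ))
  }
  sp
}

evaluate_metric_panel <- function(dose, geometry, specs) {
  data.frame(
    metric = vapply(specs, metric_label, character(1)),
    value = vapply(specs, function(s) evaluate_metric(dose, geometry, s),
                   numeric(1)),
    stringsAsFactors = FALSE
  )
}

# ---- utility (calibration propagation) experiment ----------------------

#' Configuration of the calibration-propagation experiment
#'
#' A four-dimension navigation on the first calibration patient -- PTV60
#' min-dose target, PTV60 max-dose target, rectum mean-dose WF and external
#' normal-tissue falloff WF -- from which two calibrations are committed:
#' Cal1 spares the rectum at the expense of homogeneity and conformality
#' (relaxed PTV60 targets, maximum rectum WF, minimum falloff WF) and Cal2
#' is the balanced nominal protocol.  Both are then propagated to the whole
#' cohort.
#'
#' @param n_patients cohort size (default 10; patient 1 is navigated).
#' @param seed base seed; patient k uses seed `seed + k - 1`.
#' @param grid_shape,spacing phantom grid used for the experiment.
#' @param beam_cfg,pbaio_cfg engine and loop settings for every plan.
#' @export
utility_config <- function(n_patients = 10L, seed = 1L,
                           grid_shape = c(48L, 48L, 48L),
                           spacing = c(4, 4, 4),
                           beam_cfg = beam_config(n_beams = 24L),
                           pbaio_cfg = pbaio_config(inner_iterations = 30L,
                                                    outer_loops = 5L)) {
  list(n_patients = as.integer(n_patients), seed = as.integer(seed),
       grid_shape = grid_shape, spacing = spacing,
       beam_cfg = beam_cfg, pbaio_cfg = pbaio_cfg)
}

utility_dimensions <- function(protocol) {
  list(
    navigation_dimension("PTV60|min_dose|", "target", c(94.0, 98.7),
                         label = "ptv60_dmin"),
    navigation_dimension("PTV60|max_dose|", "target", c(101.7, 106.0),
                         label = "ptv60_dmax"),
    navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                         c(5.84, 58.4), label = "rectum_dmean_wf"),
    navigation_dimension("External|dose_falloff_external|",
                         "weighting_factor", c(20.4, 204), label = "falloff_wf")
  )
}

#' Run the calibration-propagation experiment
#'
#' Generates the four-dimension Pareto dataset on patient 1, commits the
#' rectum-sparing (Cal1) and balanced (Cal2) calibrations, generates an
#' automated plan for every cohort patient under both, and reports rectum
#' mean dose, PTV60 homogeneity and PTV48 Paddick conformity per patient
#' with Cal1 - Cal2 deltas and cohort means.
#'
#' @param config a [utility_config()].
#' @param progress print per-plan progress.
#' @return list with `per_patient` (data.frame), `cohort_means`, the two
#'   committed protocols, and the navigated `dataset`.
#' @export
run_utility_experiment <- function(config = utility_config(),
                                   progress = FALSE) {
  protocol <- chhip_protocol("instA")
  dims <- utility_dimensions(protocol)
  anat <- list(grid_shape = config$grid_shape, spacing = config$spacing)
  patients <- lapply(seq_len(config$n_patients), function(k)
    build_ptvs(generate_patient(config$seed + k - 1L, anat)))

  if (progress) message("generating navigation dataset on patient 1")
  infl1 <- build_influence_matrix(patients[[1]], config$beam_cfg)
  dataset <- generate_dataset(patients[[1]], protocol, dims,
                              config$beam_cfg, config$pbaio_cfg,
                              influence = infl1)

  cal1_pos <- c(ptv60_dmin = 94.0, ptv60_dmax = 106.0,
                rectum_dmean_wf = 58.4, falloff_wf = 20.4)
  cal2_pos <- c(ptv60_dmin = 98.7, ptv60_dmax = 101.7,
                rectum_dmean_wf = 5.84, falloff_wf = 204)
  proto_cal1 <- commit_calibration(dataset, cal1_pos)
  proto_cal2 <- commit_calibration(dataset, cal2_pos)

  eval_plan <- function(plan, geom) {
    c(rectum_dmean = mean(plan$dose[geom$masks$Rectum]),
      hi_ptv60 = homogeneity_index(plan$dose, reporting_mask(geom, "PTV60")),
      ci_ptv48 = paddick_ci(plan$dose, geom$masks$PTV48, 0.95 * 48,
                            geom$masks$External))
  }

  rows <- list()
  for (k in seq_along(patients)) {
    geom <- patients[[k]]
    infl <- if (k == 1) infl1 else build_influence_matrix(geom, config$beam_cfg)
    if (progress) message(sprintf("patient %d: Cal1/Cal2 plans", k))
    m1 <- eval_plan(autoplan(geom, proto_cal1, config$beam_cfg,
                             config$pbaio_cfg, influence = infl), geom)
    m2 <- eval_plan(autoplan(geom, proto_cal2, config$beam_cfg,
                             config$pbaio_cfg, influence = infl), geom)
    rows[[k]] <- data.frame(
      patient = k,
      rectum_dmean_cal1 = m1[["rectum_dmean"]],
      rectum_dmean_cal2 = m2[["rectum_dmean"]],
      hi_ptv60_cal1 = m1[["hi_ptv60"]], hi_ptv60_cal2 = m2[["hi_ptv60"]],
      ci_ptv48_cal1 = m1[["ci_ptv48"]], ci_ptv48_cal2 = m2[["ci_ptv48"]]
    )
  }
  per_patient <- do.call(rbind, rows)
  per_patient$delta_rectum_dmean <-
    per_patient$rectum_dmean_cal1 - per_patient$rectum_dmean_cal2
  per_patient$delta_hi_ptv60 <-
    per_patient$hi_ptv60_cal1 - per_patient$hi_ptv60_cal2
  per_patient$delta_ci_ptv48 <-
    per_patient$ci_ptv48_cal1 - per_patient$ci_ptv48_cal2
  cohort_means <- colMeans(per_patient[, -1])
  list(per_patient = per_patient, cohort_means = cohort_means,
       protocol_cal1 = proto_cal1, protocol_cal2 = proto_cal2,
       dataset = dataset, config = config)
}

# ---- the end-to-end synthetic study ------------------------------------

#' Configuration of the synthetic evaluative study
#'
#' There is no clinical comparator at desk scale, so the study exercises the
#' comparison machinery against a deliberately mis-prioritised protocol arm
#' (rectum trade-off weights divided by `comparator_factor`), not against
#' clinical plan values.
#'
#' @param n_calibration,n_validation cohort sizes (defaults 10 / 20).
#' @param seed base seed; calibration patient k uses `seed + k - 1`,
#'   validation patient k uses `seed + 100 + k - 1`.
#' @param profile institution profile for phantoms, protocol and metrics.
#' @param grid_shape,spacing phantom grid.
#' @param beam_cfg,pbaio_cfg engine and loop settings.
#' @param navigation_values weighting-factor samples of the two calibration
#'   dimensions (rectum mean-dose WF, external falloff WF).
#' @param calibration_position the scripted navigated position committed as
#'   the calibrated protocol.
#' @param comparator_factor rectum WF divisor for the comparator arm.
#' @export
study_config <- function(n_calibration = 10L, n_validation = 20L, seed = 1L,
                         profile = "instA",
                         grid_shape = c(48L, 48L, 48L), spacing = c(4, 4, 4),
                         beam_cfg = beam_config(n_beams = 24L),
                         pbaio_cfg = pbaio_config(inner_iterations = 30L,
                                                  outer_loops = 5L),
                         navigation_values = list(
                           rectum_dmean_wf = c(5.84, 58.4),
                           falloff_wf = c(51, 204)),
                         calibration_position = c(rectum_dmean_wf = 29.2,
                                                  falloff_wf = 204),
                         comparator_factor = 10) {
  list(n_calibration = as.integer(n_calibration),
       n_validation = as.integer(n_validation), seed = as.integer(seed),
       profile = profile, grid_shape = grid_shape, spacing = spacing,
       beam_cfg = beam_cfg, pbaio_cfg = pbaio_cfg,
       navigation_values = navigation_values,
       calibration_position = calibration_position,
       comparator_factor = comparator_factor)
}

mis_prioritised_protocol <- function(protocol, factor) {
  for (i in seq_along(protocol$goals)) {
    g <- protocol$goals[[i]]
    if (g$priority == "P3" && g$roi == "Rectum")
      protocol$goals[[i]]$weighting_factor <- g$weighting_factor / factor
  }
  protocol$name <- paste0(protocol$name, "-comparator")
  protocol
}

#' Run the synthetic evaluative study
#'
#' Generates calibration and validation cohorts, calibrates the protocol by
#' a scripted two-dimension Pareto navigation on the first calibration
#' patient, plans every validation patient under the calibrated protocol
#' (the automated arm) and under a mis-prioritised comparator protocol, and
#' emits the paired comparison table, clinical-goal pass rates, 1-1 plot
#' data and a reproducibility manifest.  When `out_dir` is given, CSV
#' tables, plots and the JSON manifest are written there.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @param progress print progress messages.
#' @return list with `comparison`, `metrics` (the long per-patient table),
#'   `goal_pass`, `calibrated_protocol`, `comparator_protocol`, `manifest`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      progress = FALSE) {
  profile <- config$profile
  protocol <- chhip_protocol(profile)
  anat <- list(grid_shape = config$grid_shape, spacing = config$spacing,
               profile = profile)

  cal_geom <- build_ptvs(generate_patient(config$seed, anat))
  dims <- list(
    navigation_dimension("Rectum|mean_dose|", "weighting_factor",
                         config$navigation_values$rectum_dmean_wf,
                         label = "rectum_dmean_wf"),
    navigation_dimension("External|dose_falloff_external|",
                         "weighting_factor",
                         config$navigation_values$falloff_wf,
                         label = "falloff_wf")
  )
  if (progress) message("calibration navigation dataset")
  dataset <- generate_dataset(cal_geom, protocol, dims,
                              config$beam_cfg, config$pbaio_cfg)
  calibrated <- commit_calibration(dataset, config$calibration_position)
  comparator <- mis_prioritised_protocol(calibrated, config$comparator_factor)

  panel <- study_metric_panel(profile)
  goals <- chhip_clinical_goals(profile)
  arms <- c("auto", "comparator")
  rows <- list(); pass_rows <- list()
  val_seeds <- config$seed + 100L + seq_len(config$n_validation) - 1L
  for (k in seq_len(config$n_validation)) {
    geom <- build_ptvs(generate_patient(val_seeds[k], anat))
    infl <- build_influence_matrix(geom, config$beam_cfg)
    for (arm in arms) {
      proto <- if (arm == "auto") calibrated else comparator
      if (progress) message(sprintf("validation patient %d, %s arm", k, arm))
      plan <- autoplan(geom, proto, config$beam_cfg, config$pbaio_cfg,
                       influence = infl)
      pm <- evaluate_metric_panel(plan$dose, geom, panel)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = k, arm = arm, metric = pm$metric, value = pm$value,
        stringsAsFactors = FALSE)
      gt <- evaluate_goal_table(plan$dose, geom, goals)
      pass_rows[[length(pass_rows) + 1L]] <- data.frame(
        patient = k, arm = arm, label = gt$label, pass = gt$pass,
        stringsAsFactors = FALSE)
    }
  }
  metrics_tb <- do.call(rbind, rows)
  result <- cohort_result(metrics_tb, arms, seeds = val_seeds)
  comparison <- compare_cohorts(result)
  pass_tb <- do.call(rbind, pass_rows)
  goal_pass <- stats::aggregate(pass ~ arm + label, pass_tb, mean)
  names(goal_pass)[3] <- "pass_rate"

  manifest <- list(
    package_version = as.character(utils::packageVersion("pgap")),
    r_version = R.version.string,
    seed = config$seed, validation_seeds = val_seeds,
    n_calibration = config$n_calibration,
    n_validation = config$n_validation,
    profile = profile, grid_shape = config$grid_shape,
    spacing = config$spacing,
    calibration_position = as.list(config$calibration_position),
    comparator_factor = config$comparator_factor,
    beam_config = unclass(config$beam_cfg),
    pbaio_config = unclass(config$pbaio_cfg)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics_tb, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(goal_pass, file.path(out_dir, "goal_pass_rates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_one_one_plots(attr(comparison, "pairs"), arms, out_dir)
  }

  list(comparison = comparison, metrics = metrics_tb, goal_pass = goal_pass,
       calibrated_protocol = calibrated, comparator_protocol = comparator,
       manifest = manifest)
}

# 1-1 scatter plots per metric, unity line for reference.
write_one_one_plots <- function(pairs, arms, out_dir) {
  keep <- c("Rectum Dmean", "Bladder Dmean", "PTV60 D98%", "PTV60 HI",
            "PTV48 CI")
  sub <- pairs[pairs$metric %in% keep, , drop = FALSE]
  if (!nrow(sub)) return(invisible(NULL))
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$value_2, y = .data$value_1)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = arms[2], y = arms[1],
                  title = "Per-patient metric comparison") +
    ggplot2::theme_bw()
  path_png <- file.path(out_dir, "one_one_plots.png")
  ok <- tryCatch({
    grDevices::png(path_png, width = 1400, height = 900, res = 150)
    print(p); grDevices::dev.off(); TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    try(grDevices::dev.off(), silent = TRUE)
    grDevices::pdf(file.path(out_dir, "one_one_plots.pdf"), width = 9,
                   height = 6)
    print(p); grDevices::dev.off()
  }
  invisible(NULL)
}
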