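#' @title End-to-end biomarker pipeline
#' @description
#' Orchestrates the full analysis from one config: negative-control
#' thresholds -> per-replicate quadrant scoring -> technical-replicate
#' averaging -> group comparison -> ROC/AUC, producing a machine-readable
#' run report. Counts are always referred to the analysed volume
#' (volumetric endpoint); all defaults are materialised into the report so
#' a run is reproducible from its config echo alone.
#' @name pipeline_cli
NULL

#' Assemble a pipeline config
#'
#' Exactly one input route must be given: a `simulate` block (event-level
#' simulation of a two-group cohort) or `samples` + `control` file paths.
#'
#' @param seed Integer seed driving every random stage.
#' @param simulate List with elements `cohort` (a [cohort_config()]),
#'   `events_per_replicate` (expected EV events per technical replicate,
#'   default 2000) and `control_events` (expected events in the negative
#'   control, default 5000). Each biological sample draws its true display
#'   probability from its group's distribution; each replicate then
#'   simulates events with that probability under a saturating antibody.
#' @param samples data.frame with columns `path`, `sample_id`, `group`,
#'   `replicate` pointing at event CSVs (alternative to `simulate`).
#' @param control Path to the negative-control event CSV (file route).
#' @param positive_group Group label treated as the condition to detect
#'   (default `"pregnant"`).
#' @param threshold_rule Rule for both thresholds (see
#'   [threshold_from_control()]).
#' @param alpha Significance level for comparisons (default 0.05).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, simulate = NULL, samples = NULL,
                            control = NULL, positive_group = "pregnant",
                            threshold_rule = "max-of-control", alpha = 0.05) {
  if (is.null(simulate) == is.null(samples)) {
    stop("configuration error: give exactly one of `simulate` or `samples`")
  }
  if (!is.null(samples)) {
    stopifnot(is.data.frame(samples),
              all(c("path", "sample_id", "group", "replicate") %in% names(samples)))
    if (is.null(control)) stop("configuration error: missing control event file")
    if (any(!nzchar(samples$group))) stop("every sample needs a group label")
  }
  if (!is.null(simulate)) {
    if (is.null(simulate$cohort)) simulate$cohort <- cohort_config()
    if (!inherits(simulate$cohort, "cohort_config")) {
      stop("`simulate$cohort` must be a cohort_config")
    }
    simulate$events_per_replicate <- simulate$events_per_replicate %||% 2000
    simulate$control_events <- simulate$control_events %||% 5000
  }
  structure(list(seed = as.integer(seed), simulate = simulate,
                 samples = samples, control = control,
                 positive_group = positive_group,
                 threshold_rule = threshold_rule, alpha = alpha),
            class = "pipeline_config")
}

#' Load a pipeline config from YAML
#'
#' Schema mirrors [pipeline_config()]; the `simulate.cohort` mapping takes
#' the [cohort_config()] argument names, `samples` is a list of records
#' with `path`/`sample_id`/`group`/`replicate`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- y$simulate
  if (!is.null(sim)) {
    sim$cohort <- do.call(cohort_config, sim$cohort %||% list())
  }
  samples <- y$samples
  if (!is.null(samples)) {
    samples <- do.call(rbind, lapply(samples, as.data.frame))
  }
  pipeline_config(seed = y$seed %||% 1L, simulate = sim, samples = samples,
                  control = y$control,
                  positive_group = y$positive_group %||% "pregnant",
                  threshold_rule = y$threshold_rule %||% "max-of-control",
                  alpha = y$alpha %||% 0.05)
}

sim_replicate_tables <- function(config) {
  sim <- config$simulate
  cc <- sim$cohort
  n_tabs <- 2L * cc$n_per_group * cc$n_replicates
  seeds <- derive_seeds(config$seed, 1L + 2L * cc$n_per_group + n_tabs)
  control <- gen_sample_events(sample_config(
    population_spec("noise", n_events_expected = sim$control_events),
    seed = seeds[1L], sample_id = "control"))
  rows <- list(); tabs <- list()
  si <- 1L; ti <- 0L
  for (grp in c("pregnant", "control")) {
    mu <- if (grp == "pregnant") cc$mean_pregnant else cc$mean_control
    sd <- if (grp == "pregnant") cc$sd_pregnant else cc$sd_control
    for (i in seq_len(cc$n_per_group)) {
      si <- si + 1L
      sid <- sprintf("%s_%02d", grp, i)
      p_true <- min(1, max(0, with_seed(seeds[si], stats::rnorm(1, mu, sd)) / 100))
      for (r in seq_len(cc$n_replicates)) {
        ti <- ti + 1L
        tab <- gen_sample_events(sample_config(
          population_spec("ev", n_events_expected = sim$events_per_replicate),
          antibody = antibody_model(display_prob = p_true),
          seed = seeds[1L + 2L * cc$n_per_group + ti],
          sample_id = sprintf("%s_r%d", sid, r)))
        tabs[[length(tabs) + 1L]] <- tab
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, group = grp, replicate = r)
      }
    }
  }
  list(control = control, tables = tabs, index = do.call(rbind, rows))
}

read_replicate_tables <- function(config) {
  control <- read_events(config$control, sample_id = "control")
  tabs <- lapply(config$samples$path, read_events)
  list(control = control, tables = tabs,
       index = config$samples[c("sample_id", "group", "replicate")])
}

#' Run the full pipeline
#'
#' Stages, in order: event acquisition (simulation or file ingestion) ->
#' FL1/FL4 thresholds from the negative control -> quadrant scoring per
#' technical replicate -> replicate averaging per biological sample ->
#' group comparison (test-selection rule) -> ROC direction, curve, AUC and
#' Youden-optimal operating point. Deterministic given config + seed.
#' Fails with a stage-named error when the control is missing or when more
#' than half the samples have undefined display percentages.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list (see [render_report()]).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("`config` must be a pipeline_config")
  acq <- if (!is.null(config$simulate)) sim_replicate_tables(config)
         else read_replicate_tables(config)

  thr_fl1 <- threshold_from_control(acq$control, "fl1", rule = config$threshold_rule)
  thr_fl4 <- threshold_from_control(acq$control, "fl4", rule = config$threshold_rule)

  quads <- lapply(acq$tables, quadrant, thr_fl1 = thr_fl1, thr_fl4 = thr_fl4)
  rep_tab <- cbind(acq$index, do.call(rbind, lapply(seq_along(quads), function(i) {
    q <- quads[[i]]
    data.frame(n_events = q$n_total, n_trigger_dropped = events_dropped(acq$tables[[i]]),
               n_fl1_pos = q$n_fl1_pos, n_fl4_pos = q$n_fl4_pos,
               n_double = q$n_double, pct_cfda = q$pct_cfda,
               display_pct = q$display_pct)
  })))

  # stage: replicate averaging (undefined display stays missing, never 0)
  per_sample <- stats::aggregate(
    display_pct ~ sample_id + group, data = rep_tab, FUN = mean,
    na.action = stats::na.pass)
  n_undef <- sum(is.na(per_sample$display_pct))
  if (n_undef > nrow(per_sample) / 2) {
    stop(sprintf("pipeline stage 'replicate averaging': display_pct undefined in %d of %d samples",
                 n_undef, nrow(per_sample)))
  }
  per_sample <- per_sample[!is.na(per_sample$display_pct), , drop = FALSE]
  per_sample <- per_sample[order(per_sample$group, per_sample$sample_id), ]

  groups <- unique(per_sample$group)
  if (length(groups) != 2L) {
    stop("pipeline stage 'comparison': exactly two groups required, got ",
         length(groups))
  }
  if (!config$positive_group %in% groups) {
    stop("configuration error: positive_group not present in data")
  }
  pos <- per_sample$display_pct[per_sample$group == config$positive_group]
  neg <- per_sample$display_pct[per_sample$group != config$positive_group]
  cmp <- compare_groups(pos, neg, alpha = config$alpha)
  direction <- choose_direction(mean(pos), mean(neg))
  curve <- roc_points(pos, neg, direction)
  opt <- optimal_threshold(curve)

  structure(list(
    version = as.character(utils::packageVersion("evquant")),
    config = config,
    thresholds = list(fl1 = thr_fl1, fl4 = thr_fl4),
    replicates = rep_tab,
    samples = per_sample,
    group_summary = do.call(rbind, lapply(split(per_sample, per_sample$group),
      function(d) data.frame(group = d$group[1], n = nrow(d),
                             mean = mean(d$display_pct),
                             sd = stats::sd(d$display_pct)))),
    comparison = cmp,
    direction = direction,
    roc = list(threshold = curve$threshold, tpr = curve$tpr, fpr = curve$fpr,
               direction = curve$direction, n_pos = curve$n_pos,
               n_neg = curve$n_neg),
    auc = auc(curve),
    optimal = opt),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$group_summary, row.names = FALSE)
  cat(sprintf("  %s p = %.4g; direction %s; AUC %.3f\n",
              x$comparison$test_used, x$comparison$p_value, x$direction, x$auc))
  cat(sprintf("  optimal threshold %.2f: sensitivity %.2f, specificity %.2f\n",
              x$optimal$threshold, x$optimal$sensitivity, x$optimal$specificity))
  invisible(x)
}

report_body <- function(report) {
  cfg <- report$config
  list(
    version = report$version,
    seed = cfg$seed,
    positive_group = cfg$positive_group,
    threshold_rule = cfg$threshold_rule,
    alpha = cfg$alpha,
    thresholds = list(fl1 = report$thresholds$fl1[c("channel", "value", "provenance", "rule")],
                      fl4 = report$thresholds$fl4[c("channel", "value", "provenance", "rule")]),
    replicates = report$replicates,
    samples = report$samples,
    group_summary = report$group_summary,
    comparison = unclass(report$comparison),
    direction = report$direction,
    roc = report$roc,
    auc = report$auc,
    optimal = report$optimal)
}

#' Render a run report
#'
#' JSON output is lossless (full numeric precision); markdown mirrors the
#' cohort figure layout: a per-group mean +/- SD table, the test used with
#' its p-value, and the ROC summary.
#'
#' @param report A `run_report`.
#' @param format `"json"` or `"markdown"`.
#' @param path Optional output file; when NULL the text is returned.
#' @return The rendered text (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "markdown"), path = NULL) {
  format <- match.arg(format)
  if (!inherits(report, "run_report")) stop("`report` must be a run_report")
  if (!nrow(report$samples)) stop("empty cohort: nothing to render")
  if (format == "json") {
    txt <- jsonlite::toJSON(report_body(report), auto_unbox = TRUE, digits = NA,
                            dataframe = "rows", null = "null", pretty = TRUE)
    txt <- as.character(txt)
  } else {
    gs <- report$group_summary
    lines <- c(
      "# evquant run report", "",
      sprintf("Software version %s, seed %d.", report$version,
              report$config$seed), "",
      "| group | n | display % (mean ± SD) |",
      "|---|---|---|",
      sprintf("| %s | %d | %.1f ± %.1f |", gs$group, gs$n, gs$mean, gs$sd),
      "",
      sprintf("Comparison (%s): statistic %.3f, p = %.4g.",
              report$comparison$test_used, report$comparison$statistic,
              report$comparison$p_value),
      sprintf("ROC direction: %s; AUC = %.3f.", report$direction, report$auc),
      sprintf("Optimal threshold %.2f%%: sensitivity %.2f, specificity %.2f.",
              report$optimal$threshold, report$optimal$sensitivity,
              report$optimal$specificity))
    txt <- paste(lines, collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
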