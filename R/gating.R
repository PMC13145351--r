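#' @title Threshold gating and the quadrant display statistic
#' @description
#' The assay defines an EV as any particle whose FL1 (dye channel) signal
#' exceeds a threshold placed at the maximum signal observed in a negative
#' control; a second threshold on FL4 (antibody channel), set from a
#' no-antibody control, splits EVs into biomarker-positive and -negative.
#' The assay statistic is the *display percentage*: the proportion of
#' FL1-positive particles that are also FL4-positive.
#' @name gating_quadrant
NULL

#' Set a channel threshold from a negative control
#'
#' The default rule is "max-of-control": the threshold is the maximum
#' intensity observed on the channel in the negative control, so that every
#' control event is classified negative under the strict-inequality gate.
#' A percentile rule is available as a deliberately non-default option for
#' users worried about outlier fragility.
#'
#' @param control Negative-control `ev_events` table (non-empty).
#' @param channel Channel name, e.g. `"fl1"` or `"fl4"`.
#' @param rule `"max-of-control"` (default) or `"percentile"`.
#' @param percentile Percentile in (0, 100\] used when `rule = "percentile"`
#'   (default 99.9).
#' @return A `threshold_spec` list: `channel`, `value`, `provenance`
#'   (control sample id), `rule`.
#' @export
threshold_from_control <- function(control, channel,
                                   rule = c("max-of-control", "percentile"),
                                   percentile = 99.9) {
  rule <- match.arg(rule)
  if (!inherits(control, "ev_events")) stop("`control` must be an ev_events table")
  if (!channel %in% EV_CHANNELS) stop("unknown channel: ", channel)
  if (nrow(control) == 0L) stop("empty control: no threshold definable")
  v <- control[[channel]]
  value <- switch(rule,
    "max-of-control" = max(v),
    "percentile" = unname(stats::quantile(v, percentile / 100, type = 1)))
  structure(list(channel = channel, value = value,
                 provenance = events_meta(control)$sample_id, rule = rule),
            class = "threshold_spec")
}

#' Manually specified threshold
#' @param channel Channel name.
#' @param value Threshold intensity (>= 0).
#' @param provenance Free-text origin note.
#' @return A `threshold_spec`.
#' @export
threshold_spec <- function(channel, value, provenance = "manual") {
  if (!channel %in% EV_CHANNELS) stop("unknown channel: ", channel)
  stopifnot_scalar_num(value, "value", 0)
  structure(list(channel = channel, value = value, provenance = provenance,
                 rule = "manual"),
            class = "threshold_spec")
}

#' Percentage of events above a threshold
#'
#' "Above" is strict (`>`): the control's own maximum event counts as
#' negative under a max-of-control threshold.
#'
#' @param sample An `ev_events` table.
#' @param thr A `threshold_spec`.
#' @return Percentage in \[0, 100\]; 0 with a warning for an empty table.
#' @export
percent_positive <- function(sample, thr) {
  stopifnot(inherits(sample, "ev_events"), inherits(thr, "threshold_spec"))
  if (nrow(sample) == 0L) {
    warning("percent_positive: empty event table, returning 0")
    return(0)
  }
  100 * mean(sample[[thr$channel]] > thr$value)
}

#' Quadrant double-positive analysis
#'
#' Applies the FL1 (EV definition) and FL4 (biomarker) thresholds and
#' counts events per quadrant. The display percentage is computed over the
#' FL1-positive subset only; when there are no FL1-positive events it is
#' `NA` (undefined), never 0, so that group means are not biased.
#'
#' @param sample An `ev_events` table.
#' @param thr_fl1,thr_fl4 `threshold_spec`s on distinct channels
#'   (conventionally `fl1` and `fl4`).
#' @return A `quadrant_result` list: `n_total`, `n_fl1_pos`, `n_fl4_pos`,
#'   `n_double`, `display_pct` (`100 * n_double / n_fl1_pos`), `pct_cfda`
#'   (`100 * n_fl1_pos / n_total`).
#' @export
quadrant <- function(sample, thr_fl1, thr_fl4) {
  stopifnot(inherits(sample, "ev_events"),
            inherits(thr_fl1, "threshold_spec"),
            inherits(thr_fl4, "threshold_spec"))
  if (thr_fl1$channel == thr_fl4$channel) {
    stop("quadrant thresholds must be on distinct channels")
  }
  pos1 <- sample[[thr_fl1$channel]] > thr_fl1$value
  pos4 <- sample[[thr_fl4$channel]] > thr_fl4$value
  n_fl1_pos <- sum(pos1)
  res <- list(n_total = nrow(sample),
              n_fl1_pos = n_fl1_pos,
              n_fl4_pos = sum(pos4),
              n_double = sum(pos1 & pos4),
              display_pct = if (n_fl1_pos > 0) 100 * sum(pos1 & pos4) / n_fl1_pos else NA_real_,
              pct_cfda = if (nrow(sample) > 0) 100 * n_fl1_pos / nrow(sample) else NA_real_,
              thr_fl1 = thr_fl1, thr_fl4 = thr_fl4)
  structure(res, class = "quadrant_result")
}

#' @export
print.quadrant_result <- function(x, ...) {
  cat(sprintf("<quadrant_result> %d events: FL1+ %d (%.1f%%), FL4+ %d, double+ %d; display %.1f%%\n",
              x$n_total, x$n_fl1_pos, x$pct_cfda, x$n_fl4_pos, x$n_double,
              x$display_pct))
  invisible(x)
}

#' Detergent specificity verdict
#'
#' Membrane lysis abolishes a genuinely vesicular dye signal but leaves
#' protein-activated (false-positive) signal intact. Given percent-positive
#' values for the untreated sample, the detergent-treated sample and the
#' negative control:
#' * `ev_specific` — sample elevated over control, treated back at control;
#' * `protein_contaminated` — sample and treated both elevated;
#' * `no_signal` — otherwise.
#'
#' @param pct_sample,pct_detergent_treated,pct_control Percent-positive
#'   values in \[0, 100\].
#' @param tolerance Elevation margin in percentage points (default 5).
#' @return One of `"ev_specific"`, `"protein_contaminated"`, `"no_signal"`.
#' @export
detergent_specificity <- function(pct_sample, pct_detergent_treated,
                                  pct_control, tolerance = 5) {
  for (v in list(pct_sample, pct_detergent_treated, pct_control)) {
    if (!is.numeric(v) || v < 0 || v > 100) stop("percentages must lie in [0, 100]")
  }
  lim <- pct_control + tolerance
  if (pct_sample > lim && pct_detergent_treated <= lim) return("ev_specific")
  if (pct_sample > lim && pct_detergent_treated > lim) return("protein_contaminated")
  "no_signal"
}
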