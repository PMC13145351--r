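#' @title Per-event flow cytometry tables
#' @description
#' The central container of the package is the *event table*: one row per
#' detected particle, with forward/side scatter pulse heights (`fsc_h`,
#' `ssc_h`) and four fluorescence channels (`fl1`..`fl4`) on the instrument's
#' linear arbitrary-unit scale, plus acquisition metadata (analysed volume,
#' trigger thresholds, condition tags). Intensities are never log-transformed
#' at I/O time.
#' @name events_io
NULL

EV_CHANNELS <- c("fsc_h", "ssc_h", "fl1", "fl2", "fl3", "fl4")

#' Default logical-channel to column mapping
#'
#' Maps the instrument's logical channel names (FSC-H, SSC-H, FL1-FL4; the
#' FL channels differ by excitation laser and emission filter) to the
#' canonical column names used by [event_table()]. Override entries to adapt
#' FCS files whose `$PnN` names differ.
#'
#' @param ... Named overrides, e.g. `"FL1" = "FITC-A"`.
#' @return Named character vector (logical name -> column identifier).
#' @examples
#' channel_map("FL1" = "GFP-H")
#' @export
channel_map <- function(...) {
  cm <- c("FSC-H" = "fsc_h", "SSC-H" = "ssc_h",
          "FL1" = "fl1", "FL2" = "fl2", "FL3" = "fl3", "FL4" = "fl4")
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cm))
    if (length(bad)) stop("unknown logical channel(s): ", paste(bad, collapse = ", "))
    cm[names(over)] <- over
  }
  if (anyDuplicated(cm)) stop("each logical channel must map to exactly one column")
  cm
}

#' Construct an event table
#'
#' Validates intensities (finite, non-negative) and applies the acquisition
#' trigger contract: an event is only recorded by the instrument if
#' `fsc_h >= trigger_fsc_h` OR `ssc_h >= trigger_ssc_h`. Rows violating the
#' contract are dropped (mirroring instrument behaviour), and the dropped
#' count is kept in the `n_dropped` attribute.
#'
#' @param events data.frame with columns `fsc_h, ssc_h, fl1, fl2, fl3, fl4`.
#' @param sample_id Sample identifier.
#' @param analyzed_volume_ul Acquired volume in microlitres (> 0). The assay
#'   endpoint is volumetric, so concentration arithmetic depends on it.
#' @param trigger_fsc_h,trigger_ssc_h Instrument trigger thresholds
#'   (defaults 500 and 1000 arbitrary units).
#' @param condition_tags Character vector of condition labels
#'   (e.g. `"pregnant"`, `"isotype"`, `"detergent"`).
#' @return An object of class `ev_events`: the event data.frame with metadata
#'   attributes (`meta`, `n_dropped`).
#' @export
event_table <- function(events, sample_id = "sample",
                        analyzed_volume_ul = 20,
                        trigger_fsc_h = 500, trigger_ssc_h = 1000,
                        condition_tags = character()) {
  if (!is.data.frame(events)) stop("`events` must be a data.frame")
  missing_cols <- setdiff(EV_CHANNELS, names(events))
  if (length(missing_cols)) {
    stop("missing event column(s): ", paste(missing_cols, collapse = ", "))
  }
  events <- as.data.frame(events)[EV_CHANNELS]
  if (nrow(events) == 0L) {
    events[] <- lapply(events, as.numeric)  # header-only files read as logical
  }
  stopifnot_scalar_num(analyzed_volume_ul, "analyzed_volume_ul", 0, strict = TRUE)
  for (ch in EV_CHANNELS) {
    v <- events[[ch]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("channel `%s` must be finite and >= 0", ch))
    }
  }
  keep <- events$fsc_h >= trigger_fsc_h | events$ssc_h >= trigger_ssc_h
  n_dropped <- sum(!keep)
  events <- events[keep, , drop = FALSE]
  rownames(events) <- NULL
  structure(events,
            class = c("ev_events", "data.frame"),
            meta = list(sample_id = as.character(sample_id),
                        analyzed_volume_ul = analyzed_volume_ul,
                        trigger_fsc_h = trigger_fsc_h,
                        trigger_ssc_h = trigger_ssc_h,
                        condition_tags = as.character(condition_tags)),
            n_dropped = n_dropped)
}

#' @export
print.ev_events <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<ev_events> %s: %d events in %g uL (triggers FSC-H %g / SSC-H %g)\n",
              m$sample_id, nrow(x), m$analyzed_volume_ul,
              m$trigger_fsc_h, m$trigger_ssc_h))
  if (length(m$condition_tags)) {
    cat("  tags:", paste(m$condition_tags, collapse = ", "), "\n")
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Event-table metadata
#' @param table An `ev_events` object.
#' @return Named list of acquisition metadata.
#' @export
events_meta <- function(table) attr(table, "meta")

#' Number of events dropped by the trigger contract on construction/ingestion
#' @param table An `ev_events` object.
#' @export
events_dropped <- function(table) attr(table, "n_dropped")

#' Write an event table to columnar text
#'
#' Lossless CSV with a commented metadata header block (`# key: value`
#' lines), the package's canonical interchange format.
#'
#' @param table An `ev_events` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path) {
  if (!inherits(table, "ev_events")) stop("`table` must be an ev_events object")
  m <- attr(table, "meta")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sample_id: %s", m$sample_id),
    sprintf("# analyzed_volume_ul: %.17g", m$analyzed_volume_ul),
    sprintf("# trigger_fsc_h: %.17g", m$trigger_fsc_h),
    sprintf("# trigger_ssc_h: %.17g", m$trigger_ssc_h),
    sprintf("# condition_tags: %s", paste(m$condition_tags, collapse = ","))
  ), con)
  # %.17g round-trips doubles exactly, keeping read(write(x)) == x bitwise
  df <- as.data.frame(lapply(as.data.frame(table), sprintf, fmt = "%.17g"))
  names(df) <- EV_CHANNELS
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header_meta <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' Read an event table
#'
#' Reads the canonical CSV format (see [write_events()]) or, when `path`
#' ends in `.fcs`, delegates to the FCS adapter [read_fcs()]. Columns are
#' renamed through `channel_map`; events violating the trigger contract are
#' dropped with a message giving the count.
#'
#' @param path File path (CSV with `# key: value` header lines, or FCS).
#' @param channel_map Mapping from logical channels to file columns,
#'   see [channel_map()].
#' @param ... Metadata overrides passed to [event_table()]
#'   (`sample_id`, `analyzed_volume_ul`, trigger values, `condition_tags`).
#' @return An `ev_events` object.
#' @export
read_events <- function(path, channel_map = evquant::channel_map(), ...) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    return(read_fcs(path, channel_map = channel_map, ...))
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body)) stop("empty event file (no data rows or header): ", path)
  df <- utils::read.csv(text = body, check.names = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) stop("empty event file: ", path)
  # map logical channel names to canonical columns
  cm <- channel_map
  canonical <- evquant::channel_map()
  for (logical_name in names(cm)) {
    col <- cm[[logical_name]]
    target <- canonical[[logical_name]]
    if (!col %in% names(df)) {
      if (target %in% names(df)) next  # already canonical
      stop(sprintf("format error: column `%s` (channel %s) not found in %s",
                   col, logical_name, path))
    }
    names(df)[names(df) == col] <- target
  }
  meta <- parse_header_meta(hdr)
  args <- list(...)
  take <- function(key, default, cast = as.numeric) {
    if (!is.null(args[[key]])) return(args[[key]])
    if (!is.null(meta[[key]]) && nzchar(meta[[key]])) return(cast(meta[[key]]))
    default
  }
  tags <- take("condition_tags", character(),
               function(x) strsplit(x, ",", fixed = TRUE)[[1]])
  tab <- event_table(df,
                     sample_id = take("sample_id", "sample", as.character),
                     analyzed_volume_ul = take("analyzed_volume_ul", 20),
                     trigger_fsc_h = take("trigger_fsc_h", 500),
                     trigger_ssc_h = take("trigger_ssc_h", 1000),
                     condition_tags = tags)
  if (events_dropped(tab) > 0) {
    message(sprintf("read_events: dropped %d event(s) below acquisition trigger",
                    events_dropped(tab)))
  }
  tab
}
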