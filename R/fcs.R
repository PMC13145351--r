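# Minimal read-only FCS 3.0/3.1 adapter.
#
# Parses the 58-byte ASCII header, the delimited TEXT segment and a
# list-mode DATA segment of type F (float32), D (float64) or I (integer
# with $PnB bits, 8/16/32). Log-amplified ($PnE) or correlated-mode files
# are out of scope. Channel names come from $PnN and are mapped to the
# package's canonical columns via a channel map.

read_fcs_text <- function(raw_all, beg, end) {
  txt <- rawToChar(raw_all[(beg + 1L):(end + 1L)])
  delim <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1L, length(parts), by = 2L)])
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(vals), toupper(keys))
}

#' Read an FCS 3.0/3.1 file as an event table
#'
#' Thin adapter for list-mode FCS files: `$PnN` parameter names are matched
#' (case-insensitively, with `-H`/`-A` suffix intact) against the column
#' identifiers of `channel_map`; mapped channels become the canonical event
#' columns. Unmapped FCS parameters are ignored. FCS writing is not
#' supported anywhere in the package.
#'
#' @inheritParams read_events
#' @return An `ev_events` object.
#' @export
read_fcs <- function(path, channel_map = evquant::channel_map(), ...) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  version <- rawToChar(raw_all[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version)
  }
  off <- function(i) as.integer(trimws(rawToChar(raw_all[i:(i + 7L)])))
  text_beg <- off(11L); text_end <- off(19L)
  data_beg <- off(27L); data_end <- off(35L)
  kw <- read_fcs_text(raw_all, text_beg, text_end)
  # offsets may live in TEXT when too large for the header
  if (data_beg == 0L) data_beg <- as.integer(kw[["$BEGINDATA"]])
  if (data_end == 0L) data_end <- as.integer(kw[["$ENDDATA"]])
  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  mode <- toupper(kw[["$MODE"]])
  if (!identical(mode, "L")) stop("only list-mode ($MODE L) FCS is supported")
  endian <- if (startsWith(kw[["$BYTEORD"]], "1")) "little" else "big"
  pnn <- vapply(seq_len(n_par), function(i) kw[[sprintf("$P%dN", i)]], "")
  pnb <- vapply(seq_len(n_par),
                function(i) as.integer(kw[[sprintf("$P%dB", i)]]), 0L)
  con <- rawConnection(raw_all[(data_beg + 1L):(data_end + 1L)])
  on.exit(close(con))
  n_values <- n_par * n_tot
  mat <- switch(dtype,
    F = readBin(con, "numeric", n = n_values, size = 4L, endian = endian),
    D = readBin(con, "numeric", n = n_values, size = 8L, endian = endian),
    I = {
      if (length(unique(pnb)) != 1L) {
        stop("integer FCS with mixed $PnB widths is not supported")
      }
      readBin(con, "integer", n = n_values, size = pnb[1L] / 8L,
              endian = endian, signed = pnb[1L] > 16L)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(mat) != n_values) stop("truncated FCS DATA segment")
  df <- as.data.frame(matrix(mat, nrow = n_tot, ncol = n_par, byrow = TRUE))
  names(df) <- pnn
  canonical <- evquant::channel_map()
  out <- list()
  for (logical_name in names(channel_map)) {
    col <- channel_map[[logical_name]]
    hit <- which(toupper(pnn) == toupper(col))
    if (length(hit) != 1L) {
      stop(sprintf("format error: FCS parameter `%s` (channel %s) not found",
                   col, logical_name))
    }
    out[[canonical[[logical_name]]]] <- df[[hit]]
  }
  tab <- event_table(as.data.frame(out), ...)
  if (events_dropped(tab) > 0) {
    message(sprintf("read_fcs: dropped %d event(s) below acquisition trigger",
                    events_dropped(tab)))
  }
  tab
}
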