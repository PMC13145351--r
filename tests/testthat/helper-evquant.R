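# Shared fixtures and independent oracles.

# A small valid event table; all events clear the FSC trigger.
toy_events <- function(n = 5, fsc = 600, ssc = 100, fl1 = 10, fl4 = 10,
                       ...) {
  event_table(data.frame(fsc_h = rep_len(fsc, n), ssc_h = rep_len(ssc, n),
                         fl1 = rep_len(fl1, n), fl2 = rep_len(1, n),
                         fl3 = rep_len(1, n), fl4 = rep_len(fl4, n)),
              ...)
}

random_events <- function(n, seed) {
  withr::with_seed(seed, {
    event_table(data.frame(
      fsc_h = runif(n, 500, 5000), ssc_h = runif(n, 0, 5000),
      fl1 = rlnorm(n, 3, 1), fl2 = rlnorm(n, 2, 1), fl3 = rlnorm(n, 2, 1),
      fl4 = rlnorm(n, 3, 1)),
      sample_id = paste0("rand", seed),
      analyzed_volume_ul = runif(1, 5, 50),
      condition_tags = c("a", "b"))
  })
}

# Event columns only, stripped of metadata attributes, for comparisons.
plain_df <- function(tab) {
  d <- as.data.frame(tab)
  attributes(d) <- attributes(d)[c("names", "class", "row.names")]
  d
}

# Tie-adjusted rank-statistic AUC: #{pos beats neg} + 1/2 #{ties}, / n1 n2.
# Independent of the trapezoid-sweep path it checks.
mwu_auc <- function(pos, neg, direction = "positive_if_above") {
  cmp <- if (direction == "positive_if_above") {
    outer(pos, neg, ">")
  } else {
    outer(pos, neg, "<")
  }
  ties <- outer(pos, neg, "==")
  (sum(cmp) + 0.5 * sum(ties)) / (length(pos) * length(neg))
}

# Minimal FCS 3.0 writer used only to exercise the read adapter; emits a
# list-mode float32 file with the given channel names.
write_tiny_fcs <- function(path, mat, names_pnn, endian = "little") {
  n_par <- ncol(mat); n_tot <- nrow(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L",
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR", as.character(n_par), "$TOT", as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw <- c(kw, sprintf("$P%dN", i), names_pnn[i], sprintf("$P%dB", i), "32")
  }
  text <- paste0("/", paste(kw, collapse = "/"), "/")
  text_beg <- 58L
  text_end <- text_beg + nchar(text) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_beg, text_end, data_beg, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  writeBin(as.numeric(t(mat)), con, size = 4L, endian = endian)
  invisible(path)
}
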