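#' @title Size-exclusion chromatography fraction profiles
#' @description
#' A fraction profile is a series of 20 readings over consecutive SEC
#' elution fractions (45 uL each by default): protein absorbance at 280 nm,
#' percent dye-positive particles, or raw FL1 intensity. Large particles
#' (EVs) elute before small solutes (free dye, albumin), so comparing the
#' elution windows of an EV profile and a protein profile quantifies how
#' cleanly the column separates them.
#' @name sec_fractions
NULL

N_FRACTIONS <- 20L

#' Construct a fraction profile
#'
#' @param values Exactly 20 non-negative readings, fractions 1..20.
#' @param value_kind What the readings measure.
#' @param fraction_volume_ul Volume per fraction (uL, > 0; default 45).
#' @return A `fraction_profile` list.
#' @export
fraction_profile <- function(values,
                             value_kind = c("protein_a280",
                                            "pct_cfda_positive",
                                            "fl1_intensity"),
                             fraction_volume_ul = 45) {
  value_kind <- match.arg(value_kind)
  if (length(values) != N_FRACTIONS) {
    stop(sprintf("a fraction profile has exactly %d values", N_FRACTIONS))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("fraction values must be finite and >= 0")
  }
  stopifnot_scalar_num(fraction_volume_ul, "fraction_volume_ul", 0, strict = TRUE)
  structure(list(values = as.numeric(values), value_kind = value_kind,
                 fraction_volume_ul = fraction_volume_ul),
            class = "fraction_profile")
}

#' Scale a profile to unit maximum
#' @param p A `fraction_profile` with a positive maximum.
#' @return A `fraction_profile` whose maximum value is 1.
#' @export
normalize_profile <- function(p) {
  stopifnot(inherits(p, "fraction_profile"))
  m <- max(p$values)
  if (m <= 0) stop("cannot normalize an all-zero profile")
  fraction_profile(p$values / m, value_kind = p$value_kind,
                   fraction_volume_ul = p$fraction_volume_ul)
}

#' Fraction of maximum signal (peak position)
#'
#' Ties break toward the earlier fraction.
#'
#' @param p A `fraction_profile`.
#' @return Integer fraction index in 1..20.
#' @export
peak_fraction <- function(p) {
  stopifnot(inherits(p, "fraction_profile"))
  which.max(p$values)  # which.max takes the first maximum
}

#' Elution window at a relative threshold
#'
#' The maximal contiguous run of fractions around the peak in which every
#' value is at least `rel_threshold` times the profile maximum. The window
#' rule is a package definition (reported elution ranges are typically set
#' by inspection); the threshold is configurable and echoed in the result.
#'
#' @param p A `fraction_profile`.
#' @param rel_threshold Fraction of the maximum, in (0, 1); default 0.1.
#' @return An `elution_window` list: `from`, `to`, `rel_threshold`,
#'   `tail_mass` (sum of values outside the window as a fraction of total).
#' @export
elution_window <- function(p, rel_threshold = 0.1) {
  stopifnot(inherits(p, "fraction_profile"))
  if (rel_threshold <= 0 || rel_threshold >= 1) {
    stop("`rel_threshold` must lie in (0, 1)")
  }
  v <- p$values
  if (max(v) <= 0) stop("degenerate all-zero profile")
  cut <- rel_threshold * max(v)
  pk <- peak_fraction(p)
  from <- pk
  while (from > 1L && v[from - 1L] >= cut) from <- from - 1L
  to <- pk
  while (to < N_FRACTIONS && v[to + 1L] >= cut) to <- to + 1L
  total <- sum(v)
  inside <- sum(v[from:to])
  structure(list(from = from, to = to, rel_threshold = rel_threshold,
                 tail_mass = if (total > 0) 1 - inside / total else 0),
            class = "elution_window")
}

#' Overlap coefficient of two profiles
#'
#' `sum(min(a_i, b_i)) / min(sum(a), sum(b))`: 1 when one peak is fully
#' nested in the other (maximal co-elution risk), 0 for disjoint supports.
#' Normalising by the smaller mass keeps a narrow peak inside a broad one
#' at 1, which is the co-elution question the statistic answers.
#'
#' @param a,b `fraction_profile`s on the same grid, each with positive
#'   total mass.
#' @return Overlap coefficient in \[0, 1\].
#' @export
profile_overlap <- function(a, b) {
  stopifnot(inherits(a, "fraction_profile"), inherits(b, "fraction_profile"))
  sa <- sum(a$values); sb <- sum(b$values)
  if (sa <= 0 || sb <= 0) stop("profiles must have positive total mass")
  sum(pmin(a$values, b$values)) / min(sa, sb)
}

#' Convert a fraction interval to eluate volume
#'
#' @param from,to Inclusive fraction interval within 1..20 (`from <= to`).
#' @param p A `fraction_profile` (supplies the per-fraction volume).
#' @return Volume in uL, e.g. fractions 1-4 at 45 uL give the standard
#'   180 uL EV collection.
#' @export
fractions_to_volume <- function(from, to, p) {
  stopifnot(inherits(p, "fraction_profile"))
  if (from < 1 || to > N_FRACTIONS) stop("interval must lie within 1..20")
  if (from > to) stop("inverted interval: `from` must be <= `to`")
  (to - from + 1) * p$fraction_volume_ul
}
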