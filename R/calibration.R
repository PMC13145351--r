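#' @title Bead calibration, concentration arithmetic and size summaries
#' @description
#' Sizing beads of known diameter anchor a least-squares line in
#' (log10 diameter, log10 FSC-H) space; the inverse map estimates particle
#' diameter from scatter. Companion tools cover instrument validation with
#' multi-peak fluorescence beads (CV of the brightest peak < 5%), staining
#' mixture arithmetic, per-mL-of-source concentration back-calculation
#' through a dilution chain, dilution-series linearity with swarm
#' (coincidence) flagging, and D10/D50/D90 size-distribution summaries.
#' @name calibration_quant
NULL

#' Fit a bead size calibration
#'
#' Ordinary least squares of log10(FSC-H statistic) on log10(size). Scatter
#' intensity scales as a power of diameter, so the fit is done log-log;
#' a semilog variant (`size_scale = "linear"`, regressing log10 FSC-H on
#' untransformed size) is provided because the instrument write-up that
#' motivated this tool leaves the size-axis transform ambiguous.
#'
#' @param beads data.frame with columns `size_nm` and `fsc_stat` (the mean
#'   or median FSC-H of each bead population; both bases supported).
#' @param basis `"median"` or `"mean"` — recorded, not acted on.
#' @param size_scale `"log10"` (default) or `"linear"`.
#' @return A `size_calibration` list: `slope`, `intercept`, `r_squared`,
#'   `basis`, `size_scale`, `beads`.
#' @export
fit_size_calibration <- function(beads, basis = c("median", "mean"),
                                 size_scale = c("log10", "linear")) {
  basis <- match.arg(basis)
  size_scale <- match.arg(size_scale)
  stopifnot(is.data.frame(beads), all(c("size_nm", "fsc_stat") %in% names(beads)))
  if (any(beads$size_nm <= 0) || any(beads$fsc_stat <= 0)) {
    stop("bead sizes and FSC statistics must be > 0")
  }
  if (length(unique(beads$size_nm)) < 2L) stop("need >= 2 distinct bead sizes")
  x <- if (size_scale == "log10") log10(beads$size_nm) else beads$size_nm
  y <- log10(beads$fsc_stat)
  # closed-form OLS: the primitive is the point here, cross-checked in tests
  xbar <- mean(x); ybar <- mean(y)
  slope <- sum((x - xbar) * (y - ybar)) / sum((x - xbar)^2)
  intercept <- ybar - slope * xbar
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)),
                 basis = basis, size_scale = size_scale, beads = beads),
            class = "size_calibration")
}

#' Summarise bead FSC-H per true cluster
#'
#' Convenience bridge from [gen_bead_events()] (or labelled bead data) to
#' [fit_size_calibration()].
#'
#' @param events An `ev_events` table of bead events.
#' @param labels True bead size per event (nm).
#' @param basis `"median"` or `"mean"`.
#' @return data.frame with `size_nm`, `fsc_stat`.
#' @export
bead_stats <- function(events, labels, basis = c("median", "mean")) {
  basis <- match.arg(basis)
  stopifnot(inherits(events, "ev_events"), length(labels) == nrow(events))
  f <- if (basis == "median") stats::median else mean
  agg <- tapply(events$fsc_h, labels, f)
  data.frame(size_nm = as.numeric(names(agg)), fsc_stat = as.numeric(agg))
}

#' Estimate particle size from an FSC-H statistic
#'
#' Inverse of the calibration line:
#' `10^((log10 fsc - intercept) / slope)` on the log-log scale, or
#' `(log10 fsc - intercept) / slope` directly on the semilog scale.
#'
#' @param fsc_stat FSC-H value(s) > 0.
#' @param cal A `size_calibration`.
#' @return Estimated diameter(s) in nm.
#' @export
estimate_size <- function(fsc_stat, cal) {
  stopifnot(inherits(cal, "size_calibration"))
  if (any(fsc_stat <= 0)) stop("`fsc_stat` must be > 0")
  if (cal$slope == 0) stop("degenerate calibration: slope is 0")
  z <- (log10(fsc_stat) - cal$intercept) / cal$slope
  if (cal$size_scale == "log10") 10^z else z
}

#' Validate multi-peak calibration beads
#'
#' One-dimensional clustering of log10 intensities into the expected number
#' of peaks (k-means with deterministic quantile initialisation, so no seed
#' is needed), then a coefficient of variation (SD/mean on the linear
#' scale) per peak. The run passes when the expected number of non-empty,
#' separated peaks is resolved and the brightest peak's CV is below
#' `cv_limit` (default 5%).
#'
#' @param beads An `ev_events` table of validation-bead events.
#' @param n_expected_peaks Expected number of peaks (6 or 8 for the usual
#'   validation bead sets).
#' @param channel Intensity channel to cluster on (default `"fl1"`).
#' @param cv_limit CV pass limit for the brightest peak.
#' @return A `peak_validation` list: per-peak table (`peak`, `n`, `mean`,
#'   `sd`, `cv`), `brightest_cv`, `n_resolved`, `pass`, `reason`.
#' @export
validate_peak_beads <- function(beads, n_expected_peaks, channel = "fl1",
                                cv_limit = 0.05) {
  stopifnot(inherits(beads, "ev_events"))
  stopifnot_scalar_num(n_expected_peaks, "n_expected_peaks", 1)
  v <- beads[[channel]]
  if (any(v <= 0)) stop("intensities must be > 0 for log clustering")
  lx <- log10(v)
  k <- as.integer(n_expected_peaks)
  if (k == 1L) {
    cluster <- rep(1L, length(lx))
  } else {
    centers <- matrix(stats::quantile(lx, probs = (seq_len(k) - 0.5) / k,
                                      type = 1))
    centers <- matrix(centers[!duplicated(centers[, 1]), ], ncol = 1)
    if (nrow(centers) < k) {
      return(structure(list(peaks = NULL, brightest_cv = NA_real_,
                            n_resolved = nrow(centers), pass = FALSE,
                            reason = sprintf("only %d resolvable cluster seed(s) for %d expected peaks",
                                             nrow(centers), k)),
                       class = "peak_validation"))
    }
    km <- stats::kmeans(matrix(lx, ncol = 1), centers = centers,
                        iter.max = 100L, algorithm = "Lloyd")
    cluster <- km$cluster
  }
  means <- tapply(v, cluster, mean)
  ord <- order(means)  # report peaks dim -> bright
  peaks <- do.call(rbind, lapply(seq_along(ord), function(i) {
    idx <- cluster == as.integer(names(means)[ord[i]])
    m <- mean(v[idx]); s <- stats::sd(v[idx])
    data.frame(peak = i, n = sum(idx), mean = m,
               sd = ifelse(is.na(s), 0, s),
               cv = ifelse(m > 0, ifelse(is.na(s), 0, s) / m, NA_real_))
  }))
  n_resolved <- sum(peaks$n > 0)
  brightest_cv <- peaks$cv[nrow(peaks)]
  pass <- n_resolved == k && brightest_cv < cv_limit
  reason <- if (n_resolved != k) {
    sprintf("resolved %d peak(s), expected %d", n_resolved, k)
  } else if (!pass) {
    sprintf("brightest peak CV %.3f >= limit %.3f", brightest_cv, cv_limit)
  } else "ok"
  structure(list(peaks = peaks, brightest_cv = brightest_cv,
                 n_resolved = n_resolved, pass = pass, reason = reason),
            class = "peak_validation")
}

#' Volume-weighted mixture concentration
#'
#' `sum(v_i * c_i) / sum(v_i)` — the concentration of a labelling mix
#' assembled from parts, e.g. 25 uL of 40 uM dye into 175 uL diluent gives
#' a 5 uM working solution.
#'
#' @param volumes_ul Part volumes (uL, >= 0, total > 0).
#' @param concentrations Part concentrations (same unit for all parts,
#'   >= 0).
#' @return Mixture concentration in the input unit.
#' @export
mixture_concentration <- function(volumes_ul, concentrations) {
  if (length(volumes_ul) != length(concentrations)) {
    stop("`volumes_ul` and `concentrations` must have the same length")
  }
  if (any(volumes_ul < 0) || any(concentrations < 0)) {
    stop("volumes and concentrations must be >= 0")
  }
  total <- sum(volumes_ul)
  if (total <= 0) stop("total volume must be > 0")
  sum(volumes_ul * concentrations) / total
}

#' Dilution chain
#'
#' An ordered list of transfer steps, each taking `aliquot_ul` of the
#' current solution into a final volume `final_ul`. The overall dilution
#' factor is the product of `aliquot/final` ratios, order-independent.
#'
#' @param steps data.frame with columns `aliquot_ul`, `final_ul`
#'   (aliquot <= final, both > 0), or NULL for the identity chain.
#' @return A `dilution_chain` list with `steps` and `factor`.
#' @export
dilution_chain <- function(steps = NULL) {
  if (is.null(steps) || (is.data.frame(steps) && nrow(steps) == 0L)) {
    return(structure(list(steps = data.frame(aliquot_ul = numeric(),
                                             final_ul = numeric()),
                          factor = 1),
                     class = "dilution_chain"))
  }
  stopifnot(is.data.frame(steps), all(c("aliquot_ul", "final_ul") %in% names(steps)))
  if (any(steps$aliquot_ul <= 0) || any(steps$final_ul <= 0)) {
    stop("all volumes must be > 0")
  }
  if (any(steps$aliquot_ul > steps$final_ul)) stop("aliquot must be <= final volume")
  structure(list(steps = steps, factor = prod(steps$aliquot_ul / steps$final_ul)),
            class = "dilution_chain")
}

#' Back-calculate particle concentration in the source fluid
#'
#' `(count / analyzed_volume_ul) * 1000 / chain$factor`: events per uL of
#' the acquired sample, converted to per mL, then divided by the cumulative
#' dilution factor to refer the concentration back to the undiluted source
#' (e.g. plasma).
#'
#' @param count_above_threshold Number of dye-positive events acquired.
#' @param analyzed_volume_ul Acquired volume (uL, > 0).
#' @param chain A [dilution_chain()] (default identity).
#' @return Particles per mL of source fluid.
#' @export
particles_per_ml_source <- function(count_above_threshold, analyzed_volume_ul,
                                    chain = dilution_chain()) {
  stopifnot_scalar_num(analyzed_volume_ul, "analyzed_volume_ul", 0, strict = TRUE)
  stopifnot(inherits(chain, "dilution_chain"))
  (count_above_threshold / analyzed_volume_ul) * 1000 / chain$factor
}

#' Dilution-series linearity and swarm assessment
#'
#' Counts are normalised to the series maximum, then a zero-intercept least
#' squares line (a blank holds zero particles, so the fit must pass through
#' the origin) of count versus dilution factor is fitted over `fit_range`.
#' Points outside the fit range are flagged `"swarm"` when their observed
#' count falls below `1 - tolerance` of the fit's prediction — the
#' signature of coincidence undercounting at high concentration. `r_squared`
#' is the squared Pearson correlation of count and factor within the fit
#' range (0 for a degenerate constant series).
#'
#' @param series data.frame with `dilution_factor` and `count`.
#' @param fit_range Length-2 numeric: inclusive factor interval used for
#'   the fit (default `c(1/80, 1/5)`, the range over which the assay is
#'   expected to be linear).
#' @param tolerance Relative shortfall beyond which an out-of-range point
#'   is flagged (default 0.2).
#' @return A `linearity_assessment` list: per-point table (`dilution_factor`,
#'   `count`, `normalized`, `in_fit_range`, `predicted`, `obs_over_pred`,
#'   `swarm_flag`), `slope`, `r_squared`.
#' @export
linearity_assessment <- function(series, fit_range = c(1/80, 1/5),
                                 tolerance = 0.2) {
  stopifnot(is.data.frame(series),
            all(c("dilution_factor", "count") %in% names(series)))
  if (length(fit_range) != 2L || fit_range[1] >= fit_range[2]) {
    stop("`fit_range` must be an increasing length-2 interval")
  }
  x <- series$dilution_factor
  y <- series$count
  inr <- x >= fit_range[1] & x <= fit_range[2]
  if (sum(inr) < 3L) stop("need >= 3 points inside `fit_range`")
  slope <- sum(x[inr] * y[inr]) / sum(x[inr]^2)  # zero-intercept OLS
  r <- suppressWarnings(stats::cor(x[inr], y[inr]))
  r2 <- if (is.na(r)) 0 else r^2
  pred <- slope * x
  ratio <- ifelse(pred > 0, y / pred, NA_real_)
  flag <- !inr & !is.na(ratio) & ratio < 1 - tolerance
  tab <- data.frame(dilution_factor = x, count = y,
                    normalized = if (max(y) > 0) y / max(y) else y,
                    in_fit_range = inr, predicted = pred,
                    obs_over_pred = ratio, swarm_flag = flag)
  structure(list(points = tab, slope = slope, r_squared = r2,
                 fit_range = fit_range, tolerance = tolerance),
            class = "linearity_assessment")
}

#' Size-distribution summary (mean, mode, D10/D50/D90)
#'
#' D-values follow the order-statistic convention: `D_p` is the smallest
#' observed size such that at least p% of observations are <= it, i.e. the
#' `ceiling(p * n / 100)`-th order statistic, with no interpolation. The
#' mode is the midpoint of the fullest histogram bin (`bin_width` nm wide,
#' default 1 nm, anchored at 0).
#'
#' @param sizes_nm Non-empty numeric vector of particle sizes (nm).
#' @param bin_width Histogram bin width for the mode (nm).
#' @return A `size_summary` list: `mean`, `mode`, `d10`, `d50`, `d90`, `n`.
#' @export
size_summary <- function(sizes_nm, bin_width = 1) {
  if (!length(sizes_nm)) stop("`sizes_nm` must be non-empty")
  if (any(!is.finite(sizes_nm))) stop("sizes must be finite")
  stopifnot_scalar_num(bin_width, "bin_width", 0, strict = TRUE)
  s <- sort(sizes_nm)
  n <- length(s)
  dval <- function(p) s[ceiling(p * n / 100)]
  bins <- floor(s / bin_width)
  counts <- table(bins)
  top_bin <- as.numeric(names(counts)[which.max(counts)])
  structure(list(mean = mean(s),
                 mode = (top_bin + 0.5) * bin_width,
                 d10 = dval(10), d50 = dval(50), d90 = dval(90), n = n),
            class = "size_summary")
}

#' @export
print.size_summary <- function(x, ...) {
  cat(sprintf("<size_summary> n=%d  mean %.1f  mode %.1f  D10 %.1f  D50 %.1f  D90 %.1f nm\n",
              x$n, x$mean, x$mode, x$d10, x$d50, x$d90))
  invisible(x)
}
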