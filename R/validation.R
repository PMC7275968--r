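#' Prediction figures of merit
#'
#' Quality of predicted vs known concentrations over a validation set:
#' \deqn{RMSEP = \sqrt{\sum (c_i - \hat c_i)^2 / n}}
#' \deqn{bias = \sum (c_i - \hat c_i) / n}
#' \deqn{SEP = \sqrt{\sum (c_i - \hat c_i - bias)^2 / (n - 1)}}
#' \deqn{RE\% = 100 \sqrt{\sum (c_i - \hat c_i)^2 / \sum c_i^2}}
#' plus the OLS fit of predicted on known (slope, intercept, r2). The
#' identity `RMSEP^2 = bias^2 + SEP^2 (n-1)/n` holds exactly.
#'
#' @param known,predicted numeric vectors of equal length `n >= 2` (ug/mL).
#' @return object of class `"fom"`: `rmsep`, `bias`, `sep`, `re_pct`,
#'   `slope`, `intercept`, `r2`, `n`.
#' @export
prediction_fom <- function(known, predicted) {
  n <- length(known)
  if (n < 2 || length(predicted) != n)
    stop("known and predicted must have equal length >= 2")
  if (!sum(known^2)) stop("all-zero known vector: RE% undefined")
  e <- known - predicted
  bias <- mean(e)
  fit <- stats::lm(predicted ~ known)
  structure(list(rmsep = sqrt(sum(e^2) / n),
                 bias = bias,
                 sep = sqrt(sum((e - bias)^2) / (n - 1)),
                 re_pct = 100 * sqrt(sum(e^2) / sum(known^2)),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 n = n),
            class = "fom")
}

#' @export
print.fom <- function(x, ...) {
  cat(sprintf("prediction figures of merit (n = %d)\n", x$n))
  cat(sprintf("  RMSEP %.4g  SEP %.4g  bias %.4g  RE%% %.4g\n",
              x$rmsep, x$sep, x$bias, x$re_pct))
  cat(sprintf("  predicted ~ known: slope %.6g, intercept %.4g, r2 %.6f\n",
              x$slope, x$intercept, x$r2))
  invisible(x)
}

#' ICH detection and quantification limits
#'
#' `LOD = 3.3 * S_a / |b|` and `LOQ = 10 * S_a / |b|`, with `S_a` the
#' standard deviation of the calibration intercept and `b` the slope.
#'
#' @param S_a intercept standard deviation.
#' @param b calibration slope (non-zero).
#' @return named vector `c(lod =, loq =)` in concentration units.
#' @examples
#' lod_loq(1.22e-3, 0.0053)  # lod 0.76 ug/mL
#' @export
lod_loq <- function(S_a, b) {
  if (b == 0) stop("zero slope")
  c(lod = 3.3 * S_a / abs(b), loq = 10 * S_a / abs(b))
}

#' Percentage recoveries with mean and SD
#'
#' `recovery_i = 100 * found_i / nominal_i`; mean and sample standard
#' deviation (n - 1 denominator).
#'
#' @param nominal nominal (spiked/claimed) concentrations, all > 0.
#' @param found determined concentrations.
#' @return list with `recovery` (per-sample %), `mean`, `sd`.
#' @export
recovery_stats <- function(nominal, found) {
  if (length(nominal) != length(found)) stop("length mismatch")
  if (any(nominal <= 0)) stop("nominal concentrations must be > 0")
  r <- 100 * found / nominal
  list(recovery = r, mean = mean(r), sd = stats::sd(r))
}

#' Percentage relative standard deviation
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation; the ICH
#' precision measure.
#'
#' @param values numeric vector, `n >= 2`, non-zero mean.
#' @return RSD in percent.
#' @export
rsd_pct <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("zero mean")
  100 * stats::sd(values) / m
}

#' Two-method comparison: t and F statistics from summary statistics
#'
#' `F = max(sd1, sd2)^2 / min(sd1, sd2)^2` (always >= 1, symmetric in the
#' two methods) and the pooled-variance two-sample t statistic. The caller
#' compares against the appropriate critical values (4.30 and 19.00 at the
#' 95\% level for n1 = n2 = 3).
#'
#' @param mean1,sd1,n1 summary statistics of method 1 (`sd1 > 0`,
#'   `n1 >= 2`).
#' @param mean2,sd2,n2 summary statistics of method 2.
#' @return named vector `c(t =, F =)`.
#' @export
compare_methods <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be > 0")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tstat <- abs(mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  c(t = tstat, F = max(sd1, sd2)^2 / min(sd1, sd2)^2)
}

#' Paired t statistic from raw paired values
#'
#' Companion to [compare_methods()] when the raw per-sample results of the
#' two methods are available.
#'
#' @param x1,x2 paired measurement vectors.
#' @return the paired t statistic (absolute value).
#' @export
paired_t <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("length mismatch")
  d <- x1 - x2
  abs(mean(d)) / (stats::sd(d) / sqrt(length(d)))
}

#' Urinary excretion from a measured urine concentration
#'
#' `excreted_mg = conc * urine_volume / 1000 * dilution_factor` and
#' `pct_of_dose = 100 * excreted_mg / dose_mg`. With the standard workup
#' (100 uL urine diluted to 10 mL) the measured concentration already
#' reflects the 1:100 dilution, so `dilution_factor = 1` applies to the
#' back-calculated urine concentration.
#'
#' @param conc analyte concentration in the (back-calculated) urine
#'   (ug/mL).
#' @param urine_volume collected urine volume (mL).
#' @param dose_mg administered dose (mg, > 0).
#' @param dilution_factor extra multiplicative factor if `conc` is the
#'   diluted reading (default 1).
#' @return named vector `c(excreted_mg =, pct_of_dose =)`.
#' @examples
#' urinary_excretion(454.5, 980, 500)  # ~89.1 % of a 500 mg dose
#' @export
urinary_excretion <- function(conc, urine_volume, dose_mg,
                              dilution_factor = 1) {
  if (dose_mg <= 0) stop("dose must be > 0")
  if (conc < 0 || urine_volume < 0 || dilution_factor < 0)
    stop("inputs must be non-negative")
  ex <- conc * urine_volume / 1000 * dilution_factor
  c(excreted_mg = ex, pct_of_dose = 100 * ex / dose_mg)
}

#' Percentage of dose excreted
#'
#' @param excreted_mg cumulative amount excreted (mg).
#' @param dose_mg administered dose (mg, > 0).
#' @return percent of dose.
#' @examples
#' excretion_pct(445.4, 500)  # 89.08
#' @export
excretion_pct <- function(excreted_mg, dose_mg) {
  if (dose_mg <= 0) stop("dose must be > 0")
  100 * excreted_mg / dose_mg
}
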