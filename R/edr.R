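#' Default EDR recipe and derivative settings for a target analyte
#'
#' For each analyte the divisor is a ternary mixture of the other three
#' analytes; the ratio spectrum is differentiated (Savitzky-Golay) at the
#' stated order and interval and read at the analytical wavelength:
#' \describe{
#'   \item{AT}{divisor PR 7 / HZ 2 / LV 4 ug/mL, 2nd derivative,
#'     delta-lambda 4 nm, 281.6 nm}
#'   \item{PR}{divisor AT 15 / HZ 3 / LV 5, 1st derivative, 4 nm, 237.6 nm}
#'   \item{HZ}{divisor AT 15 / PR 10 / LV 5, 1st derivative, 2 nm, 279.2 nm}
#'   \item{LV}{divisor AT 15 / PR 7 / HZ 2, 2nd derivative, 4 nm, 282.8 nm}
#' }
#' All use a scaling factor of 10 applied after differentiation.
#'
#' @param target one of `"AT"`, `"PR"`, `"HZ"`, `"LV"`.
#' @return list with `target`, `divisor_concs` (named numeric),
#'   `order`, `delta_lambda_nm`, `scaling_factor`, `wavelength_nm`,
#'   `range` (calibration range, ug/mL).
#' @export
edr_defaults <- function(target = c("AT", "PR", "HZ", "LV")) {
  target <- match.arg(target)
  defs <- list(
    AT = list(divisor_concs = c(PR = 7, HZ = 2, LV = 4), order = 2L,
              delta_lambda_nm = 4, wavelength_nm = 281.6, range = c(5, 40)),
    PR = list(divisor_concs = c(AT = 15, HZ = 3, LV = 5), order = 1L,
              delta_lambda_nm = 4, wavelength_nm = 237.6, range = c(1, 25)),
    HZ = list(divisor_concs = c(AT = 15, PR = 10, LV = 5), order = 1L,
              delta_lambda_nm = 2, wavelength_nm = 279.2, range = c(1, 15)),
    LV = list(divisor_concs = c(AT = 15, PR = 7, HZ = 2), order = 2L,
              delta_lambda_nm = 4, wavelength_nm = 282.8, range = c(1, 15)))
  c(list(target = target), defs[[target]], list(scaling_factor = 10))
}

#' Synthesise a divisor spectrum from a recipe
#'
#' @param library named list of [component_model()]s.
#' @param divisor_concs named concentrations of the three interferents
#'   (ug/mL).
#' @param grid a [wl_grid()].
#' @return a single-sample `"spectra"` object (noiseless; a measured mixture
#'   read with [read_spectra()] can be used instead).
#' @export
divisor_spectrum <- function(library, divisor_concs, grid = acquisition_grid()) {
  mixture_spectrum(library, divisor_concs, grid, sigma = 0, label = "divisor")
}

#' Ratio spectrum (sample divided by divisor)
#'
#' Point-wise quotient on a shared grid. Grid points where the divisor
#' magnitude falls below `guard` are unusable and returned as `NA`; they are
#' excluded from all downstream amplitude reads.
#'
#' @param sample single-sample `"spectra"` object.
#' @param divisor single-sample `"spectra"` object on the same grid.
#' @param guard divisor magnitude threshold in AU (default 1e-3).
#' @return a `"spectra"` object (quotient; `NA` at guarded points).
#' @export
ratio_spectrum <- function(sample, divisor, guard = 1e-3) {
  stopifnot(inherits(sample, "spectra"), inherits(divisor, "spectra"))
  if (!identical(unclass(sample$grid), unclass(divisor$grid)))
    stop("sample and divisor are on different grids")
  d <- divisor$values[1, ]
  if (all(abs(d) < guard)) stop("divisor is below the guard everywhere")
  r <- sweep(sample$values, 2, d, "/")
  r[, abs(d) < guard] <- NA_real_
  spectra(sample$grid, r, sample$samples)
}

# Central Savitzky-Golay derivative kernel: window spans delta_lambda nm
# (round(dl/step)+1 points, forced odd), polynomial order = derivative
# order + 1, derivative in per-nm units (ts = grid step).
.sg_kernel <- function(order, delta_lambda_nm, step_nm) {
  n <- as.integer(round(delta_lambda_nm / step_nm)) + 1L
  if (n %% 2L == 0L) n <- n + 1L
  F <- signal::sgolay(p = order + 1L, n = n, m = order, ts = step_nm)
  list(coef = F[(n + 1L) / 2L, ], half = (n - 1L) %/% 2L, n = n)
}

#' Smoothed derivative of a (ratio) spectrum
#'
#' Savitzky-Golay derivative whose window spans `delta_lambda_nm`
#' (`round(delta_lambda/step) + 1` points), polynomial order = derivative
#' order + 1, reported in per-nm units and multiplied by `scaling_factor`.
#' Points whose window is incomplete (spectrum ends, or any `NA` from the
#' divisor guard) are returned as `NA`.
#'
#' @param ratio a `"spectra"` object on a uniform grid.
#' @param order derivative order, 1 or 2.
#' @param delta_lambda_nm differentiation interval in nm.
#' @param scaling_factor multiplier applied after differentiation
#'   (default 10).
#' @return a `"spectra"` object of derivative amplitudes.
#' @export
spec_derivative <- function(ratio, order, delta_lambda_nm, scaling_factor = 10) {
  stopifnot(inherits(ratio, "spectra"), order %in% c(1L, 2L))
  k <- .sg_kernel(order, delta_lambda_nm, ratio$grid$step_nm)
  np <- ratio$grid$n_points
  if (k$n > np) stop("derivative window longer than spectrum")
  vals <- t(apply(ratio$values, 1, function(y) {
    out <- rep(NA_real_, np)
    conv <- stats::filter(y, rev(k$coef), sides = 2)
    out[(k$half + 1):(np - k$half)] <- conv[(k$half + 1):(np - k$half)]
    out
  }))
  vals[is.nan(vals)] <- NA_real_
  spectra(ratio$grid, vals * scaling_factor, ratio$samples)
}

.amplitude_at <- function(deriv, wavelength_nm) {
  i <- wl_index(deriv$grid, wavelength_nm, "analytical wavelength")
  a <- deriv$values[, i]
  if (anyNA(a))
    stop("analytical wavelength ", wavelength_nm,
         " nm is unusable (guarded divisor or incomplete window)")
  a
}

#' Calibrate the extended derivative ratio method for one analyte
#'
#' Divides each standard spectrum by the divisor, differentiates, reads the
#' amplitude at the analytical wavelength and fits ordinary least squares of
#' amplitude on concentration. Detection and quantification limits follow
#' the ICH intercept-deviation formula ([lod_loq()]).
#'
#' @param standards `"spectra"` object of pure-target standards (>= 3).
#' @param concs their concentrations (ug/mL).
#' @param divisor single-sample `"spectra"` divisor (same grid), e.g. from
#'   [divisor_spectrum()].
#' @param target analyte name (defaults used for settings when omitted).
#' @param order,delta_lambda_nm,scaling_factor,wavelength_nm derivative
#'   settings and analytical wavelength; defaults from [edr_defaults()].
#' @param guard divisor guard threshold (AU).
#' @return object of class `"edr_cal"`: regression coefficients `a`
#'   (intercept) and `b` (slope), their standard errors `S_a`, `S_b`, `r2`,
#'   `lod`, `loq`, the settings and the divisor.
#' @seealso [predict.edr_cal()]
#' @export
edr_calibrate <- function(standards, concs, divisor,
                          target = c("AT", "PR", "HZ", "LV"),
                          order = NULL, delta_lambda_nm = NULL,
                          scaling_factor = NULL, wavelength_nm = NULL,
                          guard = 1e-3) {
  target <- match.arg(target)
  def <- edr_defaults(target)
  if (is.null(order)) order <- def$order
  if (is.null(delta_lambda_nm)) delta_lambda_nm <- def$delta_lambda_nm
  if (is.null(scaling_factor)) scaling_factor <- def$scaling_factor
  if (is.null(wavelength_nm)) wavelength_nm <- def$wavelength_nm
  if (n_samples(standards) < 3) stop("need at least 3 calibration standards")
  if (length(concs) != n_samples(standards))
    stop("length(concs) must match the number of standards")
  r <- ratio_spectrum(standards, divisor, guard)
  d <- spec_derivative(r, order, delta_lambda_nm, scaling_factor)
  amp <- .amplitude_at(d, wavelength_nm)
  fit <- stats::lm(amp ~ concs)
  sm <- suppressWarnings(summary(fit))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  S_a <- sm$coefficients[1, 2]; S_b <- sm$coefficients[2, 2]
  ll <- lod_loq(S_a, b)
  structure(list(target = target, divisor = divisor, order = order,
                 delta_lambda_nm = delta_lambda_nm,
                 scaling_factor = scaling_factor,
                 wavelength_nm = wavelength_nm, guard = guard,
                 a = a, b = b, S_a = S_a, S_b = S_b,
                 r2 = sm$r.squared, lod = ll[["lod"]], loq = ll[["loq"]],
                 range = range(concs), n = length(concs),
                 amplitudes = amp, concs = concs),
            class = "edr_cal")
}

#' @export
print.edr_cal <- function(x, ...) {
  cat(sprintf("EDR calibration for %s\n", x$target))
  cat(sprintf("  derivative order %d, delta-lambda %g nm, scaling %g\n",
              x$order, x$delta_lambda_nm, x$scaling_factor))
  cat(sprintf("  amplitude at %.1f nm = %.6g + %.6g x conc  (r2 = %.6f)\n",
              x$wavelength_nm, x$a, x$b, x$r2))
  cat(sprintf("  S_a = %.3g, S_b = %.3g, LOD = %.3g, LOQ = %.3g ug/mL\n",
              x$S_a, x$S_b, x$lod, x$loq))
  cat(sprintf("  calibration range %g-%g ug/mL (n = %d)\n",
              x$range[1], x$range[2], x$n))
  invisible(x)
}

#' @export
coef.edr_cal <- function(object, ...) c(intercept = object$a, slope = object$b)

#' Predict concentrations with a fitted EDR calibration
#'
#' Applies the stored divisor, derivative settings and regression to new
#' mixture spectra: `(amplitude - a) / b`. Negative predictions are returned
#' as-is with a warning (truncation is the caller's policy).
#'
#' @param object an `"edr_cal"` fit.
#' @param newdata a `"spectra"` object on the calibration grid.
#' @param ... unused.
#' @return named numeric vector of concentrations (ug/mL).
#' @export
predict.edr_cal <- function(object, newdata, ...) {
  r <- ratio_spectrum(newdata, object$divisor, object$guard)
  d <- spec_derivative(r, object$order, object$delta_lambda_nm,
                       object$scaling_factor)
  amp <- .amplitude_at(d, object$wavelength_nm)
  out <- (amp - object$a) / object$b
  if (any(out < 0)) warning("negative predicted concentration(s) returned as-is")
  stats::setNames(out, newdata$samples)
}

#' @export
plot.edr_cal <- function(x, ...) {
  graphics::plot(x$concs, x$amplitudes,
                 xlab = sprintf("%s concentration (ug/mL)", x$target),
                 ylab = sprintf("amplitude at %.1f nm", x$wavelength_nm), ...)
  graphics::abline(x$a, x$b)
  invisible(x)
}

#' Serialise an EDR calibration to JSON
#' @param cal an `"edr_cal"` fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edr_model <- function(cal, path) {
  obj <- list(target = cal$target, order = cal$order,
              delta_lambda_nm = cal$delta_lambda_nm,
              scaling_factor = cal$scaling_factor,
              wavelength_nm = cal$wavelength_nm, guard = cal$guard,
              a = cal$a, b = cal$b, S_a = cal$S_a, S_b = cal$S_b,
              r2 = cal$r2, lod = cal$lod, loq = cal$loq, range = cal$range,
              n = cal$n,
              divisor = list(start_nm = cal$divisor$grid$start_nm,
                             end_nm = cal$divisor$grid$end_nm,
                             step_nm = cal$divisor$grid$step_nm,
                             absorbance = as.numeric(cal$divisor$values[1, ])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an EDR calibration from JSON
#' @param path path written by [write_edr_model()].
#' @return an `"edr_cal"` object (without stored calibration amplitudes).
#' @export
read_edr_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- wl_grid(o$divisor$start_nm, o$divisor$end_nm, o$divisor$step_nm)
  div <- spectra(g, o$divisor$absorbance, "divisor")
  structure(list(target = o$target, divisor = div, order = o$order,
                 delta_lambda_nm = o$delta_lambda_nm,
                 scaling_factor = o$scaling_factor,
                 wavelength_nm = o$wavelength_nm, guard = o$guard,
                 a = o$a, b = o$b, S_a = o$S_a, S_b = o$S_b, r2 = o$r2,
                 lod = o$lod, loq = o$loq, range = o$range, n = o$n,
                 amplitudes = NULL, concs = NULL),
            class = "edr_cal")
}
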