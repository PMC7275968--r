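#' Wavelength grid
#'
#' A uniformly spaced, closed wavelength interval. Both endpoints are
#' included; all user-facing selection is by physical nanometres, never by
#' raw index, so 0.2 nm and 0.4 nm grids interoperate without off-by-one
#' drift.
#'
#' @param start_nm,end_nm interval endpoints in nm (`start_nm < end_nm`).
#' @param step_nm grid spacing in nm (> 0). The interval length must be an
#'   integer multiple of the step (to within numerical tolerance).
#' @return An object of class `"wl_grid"` with fields `start_nm`, `end_nm`,
#'   `step_nm`, `n_points`.
#' @examples
#' g <- wl_grid(200, 330, 0.2)
#' g$n_points  # 651
#' @export
wl_grid <- function(start_nm, end_nm, step_nm) {
  stopifnot(is.numeric(start_nm), is.numeric(end_nm), is.numeric(step_nm))
  if (!(start_nm < end_nm)) stop("start_nm must be < end_nm")
  if (step_nm <= 0) stop("step_nm must be > 0")
  n <- (end_nm - start_nm) / step_nm
  if (abs(n - round(n)) > 1e-8)
    stop("interval length is not an integer multiple of step_nm")
  structure(list(start_nm = as.numeric(start_nm), end_nm = as.numeric(end_nm),
                 step_nm = as.numeric(step_nm),
                 n_points = as.integer(round(n)) + 1L),
            class = "wl_grid")
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("wavelength grid: %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$end_nm, x$step_nm, x$n_points))
  invisible(x)
}

#' Wavelength vector of a grid
#' @param grid a [wl_grid()].
#' @return numeric vector of the grid wavelengths (nm).
#' @export
wavelengths <- function(grid) {
  grid$start_nm + grid$step_nm * (seq_len(grid$n_points) - 1L)
}

#' Default acquisition grid (200-330 nm at 0.2 nm, 651 points)
#' @return a [wl_grid()].
#' @export
acquisition_grid <- function() wl_grid(200, 330, 0.2)

#' Default multivariate working grid (220-290 nm at 0.4 nm, 176 points)
#' @return a [wl_grid()].
#' @export
mcr_grid <- function() wl_grid(220, 290, 0.4)

#' Spectra matrix
#'
#' Absorbance spectra for one or more samples on a common wavelength grid:
#' the data matrix D of the bilinear model, stored samples x wavelengths.
#'
#' @param grid a [wl_grid()].
#' @param values numeric matrix, samples x wavelengths (a vector is taken as
#'   a single sample), absorbance in AU. Infinite or NaN values are
#'   rejected; `NA` marks grid points flagged unusable by downstream
#'   operations (ratio guard, incomplete derivative windows).
#' @param samples character vector of sample identifiers (default `"s1"`,
#'   `"s2"`, ...).
#' @return An object of class `"spectra"` with fields `grid`, `values`
#'   (dimnamed matrix) and `samples`.
#' @examples
#' g <- wl_grid(220, 290, 0.4)
#' s <- spectra(g, matrix(runif(2 * g$n_points), 2), c("a", "b"))
#' @export
spectra <- function(grid, values, samples = NULL) {
  stopifnot(inherits(grid, "wl_grid"))
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  values <- as.matrix(values)
  if (ncol(values) != grid$n_points)
    stop("ncol(values) must equal grid$n_points (", grid$n_points, ")")
  if (any(is.infinite(values)) || any(is.nan(values)))
    stop("absorbance values must be finite")
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(values)))
  if (length(samples) != nrow(values))
    stop("length(samples) must equal nrow(values)")
  dimnames(values) <- list(samples, format_nm(wavelengths(grid)))
  structure(list(grid = grid, values = values, samples = samples),
            class = "spectra")
}

format_nm <- function(x) formatC(x, format = "fg", digits = 12)

#' @export
print.spectra <- function(x, ...) {
  cat(sprintf("spectra: %d sample(s), %g-%g nm @ %g nm (%d points)\n",
              nrow(x$values), x$grid$start_nm, x$grid$end_nm,
              x$grid$step_nm, x$grid$n_points))
  cat("samples:", paste(utils::head(x$samples, 6), collapse = ", "),
      if (length(x$samples) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
`[.spectra` <- function(x, i, ...) {
  spectra(x$grid, x$values[i, , drop = FALSE], x$samples[i])
}

#' @export
plot.spectra <- function(x, ...) {
  graphics::matplot(wavelengths(x$grid), t(x$values), type = "l", lty = 1,
                    xlab = "wavelength (nm)", ylab = "absorbance (AU)", ...)
  invisible(x)
}

#' Number of samples / wavelengths
#' @param x a `"spectra"` object.
#' @export
n_samples <- function(x) nrow(x$values)

#' Grid index of a physical wavelength
#'
#' @param grid a [wl_grid()].
#' @param nm wavelength in nm; must coincide with a grid point.
#' @param what label used in the error message.
#' @return 1-based column index of the grid point at `nm`.
#' @export
wl_index <- function(grid, nm, what = "wavelength") {
  i <- round((nm - grid$start_nm) / grid$step_nm) + 1
  if (i < 1 || i > grid$n_points ||
      abs(grid$start_nm + (i - 1) * grid$step_nm - nm) > grid$step_nm / 2 + 1e-9)
    stop(what, " ", nm, " nm is not on the grid")
  as.integer(i)
}

#' Extract a wavelength window
#'
#' Inclusive sub-grid between `lo` and `hi` nm; sample order is preserved.
#' The default multivariate window is 220-290 nm.
#'
#' @param s a `"spectra"` object.
#' @param lo,hi window bounds in nm, inside the grid.
#' @return a `"spectra"` object on the windowed grid.
#' @export
spec_window <- function(s, lo, hi) {
  stopifnot(inherits(s, "spectra"))
  if (lo >= hi) stop("empty window: lo must be < hi")
  if (lo < s$grid$start_nm - 1e-9 || hi > s$grid$end_nm + 1e-9)
    stop("window [", lo, ", ", hi, "] outside grid")
  wv <- wavelengths(s$grid)
  keep <- which(wv >= lo - 1e-9 & wv <= hi + 1e-9)
  if (!length(keep)) stop("empty window")
  g <- wl_grid(wv[keep[1]], wv[keep[length(keep)]], s$grid$step_nm)
  spectra(g, s$values[, keep, drop = FALSE], s$samples)
}

#' Resample onto a coarser (or interpolated) grid
#'
#' Decimation keeps every k-th point starting at the window start when the
#' new step is an integer multiple of the native step; otherwise linear
#' interpolation must be enabled explicitly.
#'
#' @param s a `"spectra"` object.
#' @param new_step target step in nm.
#' @param interpolate allow linear interpolation for non-multiple steps.
#' @return a `"spectra"` object on the new grid.
#' @export
spec_resample <- function(s, new_step, interpolate = FALSE) {
  stopifnot(inherits(s, "spectra"))
  r <- new_step / s$grid$step_nm
  if (abs(r - round(r)) < 1e-8 && round(r) >= 1) {
    k <- as.integer(round(r))
    if (k == 1L) return(s)
    keep <- seq(1L, s$grid$n_points, by = k)
    g <- wl_grid(s$grid$start_nm,
                 s$grid$start_nm + (length(keep) - 1L) * new_step, new_step)
    return(spectra(g, s$values[, keep, drop = FALSE], s$samples))
  }
  if (!interpolate)
    stop("new_step is not an integer multiple of the native step; ",
         "set interpolate = TRUE for linear interpolation")
  wv <- wavelengths(s$grid)
  nend <- s$grid$start_nm + floor((s$grid$end_nm - s$grid$start_nm) / new_step) * new_step
  g <- wl_grid(s$grid$start_nm, nend, new_step)
  nw <- wavelengths(g)
  vals <- t(apply(s$values, 1, function(y) stats::approx(wv, y, xout = nw)$y))
  spectra(g, vals, s$samples)
}

#' Read spectra from a wide-form CSV file
#'
#' Expected header: `wavelength_nm,<sample_id>,...`, one row per grid point,
#' wavelengths strictly increasing and uniformly spaced.
#'
#' @param path CSV file path.
#' @return a `"spectra"` object.
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop("missing 'wavelength_nm' column in ", path)
  wv <- df$wavelength_nm
  if (anyNA(df)) stop("NaN/NA cells in ", path)
  d <- diff(wv)
  if (any(d <= 0)) stop("wavelengths must be strictly increasing (duplicated or non-monotone rows)")
  if (max(d) - min(d) > 1e-6 * stats::median(d))
    stop("non-uniform wavelength spacing; resample the source data first")
  step <- stats::median(d)
  g <- wl_grid(wv[1], wv[length(wv)], step)
  vals <- t(as.matrix(df[setdiff(names(df), "wavelength_nm")]))
  spectra(g, vals, rownames(vals))
}

#' Write spectra to a wide-form CSV file
#'
#' Values are written with 15 significant digits so a read/write round trip
#' is lossless at double precision.
#'
#' @param s a `"spectra"` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra"))
  df <- data.frame(wavelength_nm = wavelengths(s$grid), t(s$values),
                   check.names = FALSE)
  names(df) <- c("wavelength_nm", s$samples)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample x analyte concentration table
#'
#' Expected header: `sample_id,<analyte>,...`; concentrations in ug/mL,
#' all non-negative.
#'
#' @param path CSV file path.
#' @return numeric matrix with sample rownames and analyte colnames.
#' @export
read_concentrations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("missing 'sample_id' column in ", path)
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  rownames(m) <- df$sample_id
  if (anyNA(m)) stop("NA concentrations in ", path)
  if (any(m < 0)) stop("negative concentrations in ", path)
  m
}

#' Write a sample x analyte concentration table
#' @param conc numeric matrix, samples x analytes (rownames = sample ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentrations <- function(conc, path) {
  df <- data.frame(sample_id = rownames(conc), conc, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
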