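#' Gaussian absorption band
#'
#' @param center_nm band centre (nm).
#' @param width_nm Gaussian sigma (nm, > 0).
#' @param height absorbance per unit concentration at the centre
#'   (AU per ug/mL, >= 0).
#' @return a named numeric vector of class `"gaussian_band"`.
#' @export
gaussian_band <- function(center_nm, width_nm, height) {
  if (width_nm <= 0) stop("width_nm must be > 0")
  if (height < 0) stop("height must be >= 0")
  structure(c(center_nm = center_nm, width_nm = width_nm, height = height),
            class = "gaussian_band")
}

#' Component absorption model
#'
#' A pure component as a sum of Gaussian bands, linear in concentration
#' (ideal Beer-Lambert behaviour at 1 cm path).
#'
#' @param name analyte identifier.
#' @param bands list of [gaussian_band()]s (at least one).
#' @return an object of class `"component_model"`.
#' @export
component_model <- function(name, bands) {
  if (!length(bands)) stop("at least one band required")
  bands <- lapply(bands, function(b) {
    if (!inherits(b, "gaussian_band")) do.call(gaussian_band, as.list(b)) else b
  })
  structure(list(name = name, bands = bands), class = "component_model")
}

#' @export
print.component_model <- function(x, ...) {
  cat("component", x$name, "-", length(x$bands), "band(s)\n")
  for (b in x$bands)
    cat(sprintf("  %7.2f nm  sigma %5.2f  height %.4f\n", b[1], b[2], b[3]))
  invisible(x)
}

# Band tables for the built-in five-component library. Versioned constants:
# positions/widths follow the qualitative band layout of the four drugs
# (AT weak, maxima near 225/275; PR strong near 240s; HZ 226/273/317;
# LV strong 283-290) over a shared rising end-absorption edge and a broad
# common backbone; the sharp bands near the four analytical wavelengths were
# calibrated once so that each wavelength is informative for its target and
# the derivative-ratio leakage of the other three components is nulled there.
# The urine background is a broad featureless envelope of the same family.
.band_table <- function() {
  end <- c(205, 7.5, 0.85)
  bk <- list(c(227, 8, 0.15), c(247, 10, 0.125), c(278, 10, 0.125))
  list(
    AT = c(list(end, c(225, 5.5, 0.40), c(274, 4, 0.10),
                c(280.2, 2.1, 0.352)), bk),
    PR = c(list(end, c(227, 6, 0.20), c(238, 4.5, 0.35), c(246, 8, 0.30),
                c(284.031, 1.927, 0.28)), bk),
    HZ = c(list(end, c(226, 6, 0.60), c(273, 4.5, 0.35), c(317, 12, 0.10),
                c(279.409, 3.205, 0.342), c(240.753, 2.707, 0.049)), bk),
    LV = c(list(end, c(226, 8, 0.35), c(285.8, 1.5, 0.525), c(289.5, 5, 0.32),
                c(280.455, 3.265, 0.5), c(236.738, 3.262, 0.413)), bk),
    URINE = list(c(205, 10.3, 0.31), c(227, 8, 0.24), c(247, 10, 0.25),
                 c(278, 10, 0.10), c(284.5, 20.3, 0.21))
  )
}

#' Built-in component library
#'
#' Returns the five built-in component models: the four analytes (AT
#' atenolol, PR paracetamol, HZ hydrochlorothiazide, LV levofloxacin) and a
#' broad URINE background. All five spectra are non-negative, strongly
#' overlapped over 220-290 nm (pairwise positive correlation), and each
#' analyte carries informative structure at its analytical wavelength
#' (281.6, 237.6, 279.2, 282.8 nm).
#'
#' @return named list of [component_model()]s.
#' @examples
#' lib <- default_library()
#' names(lib)
#' @export
default_library <- function() {
  tb <- .band_table()
  out <- lapply(names(tb), function(n)
    component_model(n, lapply(tb[[n]], function(b)
      gaussian_band(b[1], b[2], b[3]))))
  names(out) <- names(tb)
  out
}

#' Unit spectrum of a component (1 ug/mL)
#' @param m a [component_model()].
#' @param grid a [wl_grid()].
#' @return numeric vector, absorbance per ug/mL at each grid point.
#' @export
unit_spectrum <- function(m, grid) {
  wv <- wavelengths(grid)
  Reduce(`+`, lapply(m$bands, function(b)
    b[["height"]] * exp(-(wv - b[["center_nm"]])^2 / (2 * b[["width_nm"]]^2))))
}

#' Pure-component spectrum at a given concentration
#'
#' Exactly linear in concentration: `conc` times the unit spectrum.
#'
#' @param m a [component_model()].
#' @param conc concentration in ug/mL (>= 0).
#' @param grid a [wl_grid()].
#' @return a single-sample `"spectra"` object.
#' @export
pure_spectrum <- function(m, conc, grid = acquisition_grid()) {
  if (conc < 0) stop("negative concentration")
  spectra(grid, conc * unit_spectrum(m, grid), m$name)
}

# Deterministic per-spectrum seed derived from the dataset seed: row i of a
# dataset uses seed + i, so any single spectrum is reproducible in isolation.
.row_seed <- function(seed, i) as.integer((seed + i) %% .Machine$integer.max)

#' Mixture spectrum under additive Beer-Lambert absorbance
#'
#' The noiseless part is the exact sum of the pure-component spectra;
#' optional i.i.d. Gaussian photometric noise is added per grid point from a
#' seeded RNG.
#'
#' @param library named list of [component_model()]s.
#' @param concs named concentrations (ug/mL); names must exist in `library`.
#' @param grid a [wl_grid()].
#' @param sigma additive noise s.d. in AU (default 0: noiseless).
#' @param seed RNG seed used when `sigma > 0`.
#' @param label sample id.
#' @return a single-sample `"spectra"` object.
#' @export
mixture_spectrum <- function(library, concs, grid = acquisition_grid(),
                             sigma = 0, seed = NULL, label = "mix") {
  unknown <- setdiff(names(concs), names(library))
  if (length(unknown)) stop("unknown component(s): ", paste(unknown, collapse = ", "))
  if (any(concs < 0)) stop("negative concentration")
  y <- numeric(grid$n_points)
  for (nm in names(concs))
    y <- y + concs[[nm]] * unit_spectrum(library[[nm]], grid)
  if (sigma > 0) {
    if (is.null(seed)) stop("seed required when sigma > 0")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    y <- y + stats::rnorm(grid$n_points, 0, sigma)
  }
  spectra(grid, y, label)
}

#' Simulate a spectra dataset from a concentration design
#'
#' One spectrum per design row via [mixture_spectrum()], preserving row
#' order. Per-row seeds are derived deterministically from the dataset seed
#' (`seed + row index`), so individual spectra are reproducible in
#' isolation.
#'
#' @param design numeric matrix, samples x analytes (colnames must exist in
#'   `library`; rownames become sample ids).
#' @param library named list of [component_model()]s.
#' @param grid a [wl_grid()].
#' @param sigma additive noise s.d. in AU (default 0.002, typical
#'   photometric noise).
#' @param seed dataset seed (required when `sigma > 0`).
#' @return a `"spectra"` object with `nrow(design)` samples.
#' @export
simulate_dataset <- function(design, library, grid = acquisition_grid(),
                             sigma = 0.002, seed = NULL) {
  design <- as.matrix(design)
  if (is.null(colnames(design))) stop("design must have analyte colnames")
  ids <- rownames(design)
  if (is.null(ids)) ids <- paste0("mix", seq_len(nrow(design)))
  vals <- matrix(NA_real_, nrow(design), grid$n_points)
  for (i in seq_len(nrow(design))) {
    cc <- design[i, ]
    vals[i, ] <- mixture_spectrum(library, stats::setNames(as.numeric(cc), colnames(design)),
                                  grid, sigma = sigma,
                                  seed = if (sigma > 0) .row_seed(seed, i) else NULL,
                                  label = ids[i])$values[1, ]
  }
  spectra(grid, vals, ids)
}

#' Draw urine background levels for a design
#'
#' Uniform levels on `range`, seeded. The wide default range (near-zero to
#' 1.5 units) emulates the strong sample-to-sample variability of a diluted
#' urine matrix; rows with near-zero background are what anchors the free
#' MCR component (see the methods vignette).
#'
#' @param n number of samples.
#' @param seed RNG seed.
#' @param range level range (dimensionless units of the URINE unit
#'   spectrum).
#' @return numeric vector of length `n`.
#' @export
urine_levels <- function(n, seed, range = c(0.05, 1.5)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::runif(n, range[1], range[2])
}
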