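test_that("ratio spectra follow the closed-form quotient with a guard", {
  lib <- default_library()
  g <- acquisition_grid()
  def <- edr_defaults("AT")
  div <- divisor_spectrum(lib, def$divisor_concs, g)
  # spectrum divided by itself is 1 at every usable point
  self <- ratio_spectrum(div, div)
  expect_equal(range(self$values, na.rm = TRUE), c(1, 1))
  # a proportional mixture gives the constant alpha
  prop <- mixture_spectrum(lib, 1.7 * def$divisor_concs, g)
  r <- ratio_spectrum(prop, div)
  expect_equal(range(r$values, na.rm = TRUE), c(1.7, 1.7), tolerance = 1e-12)
  # four-component mixture matches the analytic band-library expression
  concs <- c(AT = 15, PR = 10, HZ = 3, LV = 6)
  mix <- mixture_spectrum(lib, concs, g)
  rm_ <- ratio_spectrum(mix, div)
  U <- library_matrix(g)
  num <- as.vector(U[, names(concs)] %*% concs)
  den <- as.vector(U[, names(def$divisor_concs)] %*% def$divisor_concs)
  expected <- ifelse(abs(den) < 1e-3, NA_real_, num / den)
  expect_equal(rm_$values[1, ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  # grid mismatch is an error
  expect_error(ratio_spectrum(spec_window(mix, 220, 290), div), "grids")
})

test_that("the smoothed derivative annihilates constants and is exact on polynomials", {
  g <- wl_grid(220, 290, 0.2)
  wv <- wavelengths(g)
  const <- spectra(g, rep(3.2, g$n_points))
  d0 <- spec_derivative(const, 1, 4)
  expect_lt(max(abs(d0$values), na.rm = TRUE), 1e-12)
  # first derivative of a linear ratio = scaling x slope at interior points
  lin <- spectra(g, 0.25 * wv - 7)
  d1 <- spec_derivative(lin, 1, 4, scaling_factor = 10)
  expect_equal(unique(round(d1$values[1, !is.na(d1$values[1, ])], 9)),
               10 * 0.25)
  # endpoints with incomplete windows are flagged unusable
  expect_true(all(is.na(d1$values[1, 1:10])))
  expect_true(all(is.na(d1$values[1, (g$n_points - 9):g$n_points])))
  expect_error(spec_derivative(spectra(wl_grid(220, 221, 0.2), rep(1, 6)), 2, 4),
               "window longer")
})

test_that("derivative amplitude is homogeneous of degree 1 in target concentration", {
  lib <- default_library()
  g <- acquisition_grid()
  for (tg in c("AT", "PR", "HZ", "LV")) {
    def <- edr_defaults(tg)
    div <- divisor_spectrum(lib, def$divisor_concs, g)
    amps <- sapply(c(5, 10, 20), function(cc) {
      s <- pure_spectrum(lib[[tg]], cc, g)
      d <- spec_derivative(ratio_spectrum(s, div), def$order,
                           def$delta_lambda_nm, def$scaling_factor)
      d$values[1, wl_index(g, def$wavelength_nm)]
    })
    fit <- lm(amps ~ 0 + c(5, 10, 20))
    expect_lt(max(abs(residuals(fit))) / abs(coef(fit)[1]), 1e-10)
  }
})

test_that("EDR calibration matches a normal-equations oracle and is exact when noiseless", {
  lib <- default_library()
  g <- acquisition_grid()
  def <- edr_defaults("HZ")
  concs <- c(1, 3, 7, 11, 15)
  stds <- simulate_dataset(matrix(concs, ncol = 1, dimnames = list(NULL, "HZ")),
                           lib, g, sigma = 0)
  div <- divisor_spectrum(lib, def$divisor_concs, g)
  cal <- edr_calibrate(stds, concs, div, "HZ")
  expect_equal(cal$r2, 1, tolerance = 1e-12)
  expect_lt(abs(cal$a), 1e-10)
  # brute-force normal equations on the same amplitudes
  x <- cbind(1, concs)
  beta <- solve(t(x) %*% x, t(x) %*% cal$amplitudes)
  expect_equal(unname(c(cal$a, cal$b)), as.numeric(beta), tolerance = 1e-10)
  expect_error(edr_calibrate(stds[1:2], concs[1:2], div, "HZ"), "at least 3")
})

test_that("predictions invert the calibration and flag negative results", {
  lib <- default_library()
  g <- acquisition_grid()
  def <- edr_defaults("LV")
  concs <- seq(1, 15, 2)
  stds <- simulate_dataset(matrix(concs, ncol = 1, dimnames = list(NULL, "LV")),
                           lib, g, sigma = 0)
  div <- divisor_spectrum(lib, def$divisor_concs, g)
  cal <- edr_calibrate(stds, concs, div, "LV")
  expect_equal(unname(predict(cal, stds)), concs, tolerance = 1e-8)
  # blank sample: amplitude equals the (near-zero) intercept -> ~0
  blank <- mixture_spectrum(lib, c(LV = 0), g)
  expect_lt(abs(suppressWarnings(predict(cal, blank))), 1e-8)
})

test_that("EDR is invariant to scaling the interferent background", {
  # the core derivative-ratio claim: backgrounds proportional to the divisor
  # recipe drop out exactly
  lib <- default_library()
  g <- acquisition_grid()
  for (tg in c("AT", "PR", "HZ", "LV")) {
    def <- edr_defaults(tg)
    div <- divisor_spectrum(lib, def$divisor_concs, g)
    concs <- seq(def$range[1], def$range[2], length.out = 5)
    stds <- simulate_dataset(matrix(concs, ncol = 1, dimnames = list(NULL, tg)),
                             lib, g, sigma = 0)
    cal <- edr_calibrate(stds, concs, div, tg)
    preds <- sapply(c(0.5, 1, 2), function(alpha) {
      cc <- c(8, alpha * def$divisor_concs)
      names(cc)[1] <- tg
      predict(cal, mixture_spectrum(lib, cc, g))
    })
    expect_lt(max(abs(diff(preds))) / 8, 1e-8)
  }
})

test_that("doubling the divisor halves the slope but leaves predictions unchanged", {
  lib <- default_library()
  g <- acquisition_grid()
  def <- edr_defaults("PR")
  concs <- c(1, seq(5, 25, 5))
  stds <- simulate_dataset(matrix(concs, ncol = 1, dimnames = list(NULL, "PR")),
                           lib, g, sigma = 0)
  div1 <- divisor_spectrum(lib, def$divisor_concs, g)
  div2 <- divisor_spectrum(lib, 2 * def$divisor_concs, g)
  cal1 <- edr_calibrate(stds, concs, div1, "PR")
  cal2 <- edr_calibrate(stds, concs, div2, "PR")
  expect_equal(cal2$b, cal1$b / 2, tolerance = 1e-10)
  mix <- mixture_spectrum(lib, c(AT = 15, PR = 10, HZ = 3, LV = 6), g)
  expect_equal(unname(predict(cal1, mix)), unname(predict(cal2, mix)),
               tolerance = 1e-8)
})

test_that("EDR models survive a JSON round trip", {
  lib <- default_library()
  g <- acquisition_grid()
  def <- edr_defaults("AT")
  concs <- seq(5, 40, 5)
  stds <- simulate_dataset(matrix(concs, ncol = 1, dimnames = list(NULL, "AT")),
                           lib, g, sigma = 0)
  div <- divisor_spectrum(lib, def$divisor_concs, g)
  cal <- edr_calibrate(stds, concs, div, "AT")
  path <- withr::local_tempfile(fileext = ".json")
  write_edr_model(cal, path)
  cal2 <- read_edr_model(path)
  mix <- mixture_spectrum(lib, c(AT = 15, PR = 10, HZ = 3, LV = 6), g)
  expect_equal(unname(predict(cal, mix)), unname(predict(cal2, mix)),
               tolerance = 1e-12)
})
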