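test_that("SIMPLISMA finds the band centres of disjoint components", {
  lib <- toy_disjoint_library()
  g <- wl_grid(220, 290, 1)
  design <- matrix(c(1, 3, 2, 5, 4, 1), 3, 2,
                   dimnames = list(NULL, c("A", "B")))
  D <- simulate_dataset(design, lib, g, sigma = 0)
  out <- simplisma(D$values, 2)
  wv <- wavelengths(g)
  picked <- sort(wv[out$pure])
  expect_true(abs(picked[1] - 240) <= 1)
  expect_true(abs(picked[2] - 280) <= 1)
  # deflation never repeats a pick
  expect_equal(anyDuplicated(out$pure), 0L)
})

test_that("SIMPLISMA purity ranking matches an exhaustive residual-volume oracle", {
  lib <- default_library()
  g <- wl_grid(230, 287, 3)  # 20-wavelength toy
  design <- standard_design()[1:8, ]
  D <- simulate_dataset(design, lib, g, sigma = 0.002, seed = 3)$values
  expect_equal(simplisma(D, 4)$pure, simplisma_oracle(D, 4))
  expect_error(simplisma(D, 50), "dimensions")
})

test_that("lack of fit and explained variance follow their definitions", {
  D <- matrix(c(1, 0, 0, 1), 2)
  C <- diag(2)
  S_exact <- diag(2)           # wavelengths x components
  expect_equal(lack_of_fit(D, C, S_exact), 0)
  expect_equal(explained_variance(D, C, S_exact), 100)
  expect_equal(lack_of_fit(D, 0 * C, S_exact), 100)
  S9 <- diag(c(0.9, 0.9))
  expect_equal(lack_of_fit(D, C, S9), 100 * sqrt(0.02 / 2))  # 10 %
  expect_equal(explained_variance(D, C, S9), 100 * (2 - 0.02) / 2)  # 99 %
  expect_error(lack_of_fit(matrix(0, 2, 2), C, S_exact), "all-zero")
})

test_that("explained variance is identically 100 - lof^2/100", {
  set.seed(5)
  for (i in 1:10) {
    D <- matrix(rexp(30), 5)
    C <- matrix(runif(10), 5)
    S <- matrix(runif(12), 6)
    expect_equal(explained_variance(D, C, S),
                 100 - lack_of_fit(D, C, S)^2 / 100, tolerance = 1e-12)
  }
})

test_that("the correlation constraint recovers affine maps", {
  refs <- c(2, 4, 6, 8)
  # resolved equals the references: identity regression, column unchanged
  cc <- correlation_constraint(refs, refs)
  expect_equal(cc$slope, 1, tolerance = 1e-12)
  expect_equal(cc$intercept, 0, tolerance = 1e-12)
  expect_equal(cc$corrected, refs)
  # affine case: slope/intercept recovered, calibration rows -> references
  resolved <- c(2 * refs + 3, 12)          # one unknown row appended
  cc2 <- correlation_constraint(resolved, refs, cal_rows = 1:4)
  expect_equal(cc2$slope, 2, tolerance = 1e-12)
  expect_equal(cc2$intercept, 3, tolerance = 1e-12)
  expect_equal(cc2$corrected[1:4], refs)
  # unknown midway between two calibration rows maps to the midway conc
  mid <- correlation_constraint(c(2 * refs + 3, mean(2 * c(4, 6) + 3)),
                                refs, cal_rows = 1:4)
  expect_equal(mid$corrected[5], 5, tolerance = 1e-12)
  expect_error(correlation_constraint(rep(1, 4), refs), "zero-variance")
})

test_that("truth is a fixed point of the constrained alternating updates", {
  sim <- simulate_mcr_dataset(sigma = 0)
  U <- library_matrix(mcr_grid())
  D <- sim$spectra$values
  C_true <- sim$full
  # given the true spectra, one NNLS pass recovers the true concentrations
  C_hat <- t(nnls(U, t(D)))
  expect_equal(unname(C_hat), unname(C_true), tolerance = 1e-8)
  expect_equal(lack_of_fit(D, C_hat, U), 0, tolerance = 1e-8)
})

test_that("MCR-ALS resolves the five-component system from SIMPLISMA init", {
  sim <- simulate_mcr_dataset(sigma = 0)
  sp <- split_calibration_validation(sim$design)
  m <- mcr_als(sim$spectra[sp$calibration_rows], sp$calibration,
               max_iter = 150)
  expect_lt(m$lof_pct, 0.1)
  expect_gt(m$explained_var_pct, 99.99)
  # all profiles non-negative
  expect_true(all(m$C >= 0))
  expect_true(all(m$S >= 0))
  # resolved spectra match the generating unit spectra after assignment
  U <- library_matrix(mcr_grid())
  for (a in names(m$assignment))
    expect_gt(cor(m$S[, m$assignment[a]], U[, a]), 0.999)
  # lack of fit never increases across iterations
  expect_true(all(diff(m$lof_history[-(1:2)]) <= 1e-9))
  # Eq. identity on the fitted model
  expect_equal(m$explained_var_pct, 100 - m$lof_pct^2 / 100)
  # validation rows predicted to < 0.5 % relative error
  pred <- predict(m, sim$spectra[sp$validation_rows])
  expect_lt(max(abs(pred - sp$validation) / sp$validation), 0.005)
  # in-sample consistency
  insample <- predict(m, sim$spectra[sp$calibration_rows])
  expect_lt(max(abs(insample - sp$calibration) / sp$calibration), 0.005)
})

test_that("the regression-mapping constraint variant is available", {
  sim <- simulate_mcr_dataset(sigma = 0.002, seed = 23)
  sp <- split_calibration_validation(sim$design)
  m <- mcr_als(sim$spectra[sp$calibration_rows], sp$calibration,
               variant = "regression", max_iter = 150)
  expect_s3_class(m, "mcr_als")
  expect_true(all(vapply(m$regressions, function(r) r[["slope"]], 1) > 0))
  pred <- predict(m, sim$spectra[sp$validation_rows])
  expect_equal(dim(pred), c(7L, 4L))
})

test_that("analytes are recovered in the presence of an uncalibrated interferent", {
  # urine backgrounds differ between calibration and unknowns; the free
  # fifth component absorbs them
  sim <- simulate_mcr_dataset(sigma = 0.002, seed = 31)
  sp <- split_calibration_validation(sim$design)
  m <- mcr_als(sim$spectra[sp$calibration_rows], sp$calibration)
  unknown_design <- cbind(AT = 12, PR = 6, HZ = 4, LV = 3, URINE = 2.5)
  unk <- simulate_dataset(unknown_design, default_library(),
                          acquisition_grid(), sigma = 0.002, seed = 77)
  unkw <- spec_resample(spec_window(unk, 220, 290), 0.4)
  pred <- predict(m, unkw)
  expect_true(all(abs(pred / unknown_design[, 1:4] - 1) < 0.05))
})

test_that("grid mismatches are rejected at prediction time", {
  sim <- simulate_mcr_dataset(sigma = 0)
  sp <- split_calibration_validation(sim$design)
  m <- mcr_als(sim$spectra[sp$calibration_rows], sp$calibration, max_iter = 30)
  bad <- spec_window(sim$spectra, 230, 280)
  expect_error(predict(m, bad), "grid")
})
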