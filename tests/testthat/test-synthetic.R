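test_that("the built-in library has five overlapped non-negative components", {
  lib <- default_library()
  expect_named(lib, c("AT", "PR", "HZ", "LV", "URINE"))
  g <- acquisition_grid()
  U <- sapply(lib, unit_spectrum, grid = g)
  expect_true(all(U >= 0))
  # pairwise overlap over the multivariate window
  wv <- wavelengths(g)
  Uw <- U[wv >= 220 & wv <= 290, ]
  cm <- cor(Uw)
  expect_true(all(cm[upper.tri(cm)] > 0))
})

test_that("analyte spectra carry their characteristic band maxima", {
  g <- acquisition_grid()
  wv <- wavelengths(g)
  U <- library_matrix(g)
  has_peak <- function(u, lo, hi) {
    i <- which(wv >= lo & wv <= hi)
    any(diff(sign(diff(u[i]))) == -2)
  }
  expect_true(has_peak(U[, "AT"], 221, 230))  # weak aromatic band near 225
  expect_true(has_peak(U[, "AT"], 270, 285))
  expect_true(has_peak(U[, "PR"], 234, 250))  # strong band in the low 240s
  expect_true(has_peak(U[, "HZ"], 221, 231))
  expect_true(has_peak(U[, "HZ"], 265, 281))
  expect_true(has_peak(U[, "HZ"], 309, 325))
  expect_true(has_peak(U[, "LV"], 280, 293))  # strong band in the high 280s
})

test_that("pure spectra are exactly linear in concentration", {
  lib <- default_library()
  g <- mcr_grid()
  expect_equal(pure_spectrum(lib$AT, 0, g)$values[1, ],
               rep(0, g$n_points), ignore_attr = TRUE)
  p1 <- pure_spectrum(lib$PR, 3, g)$values
  p2 <- pure_spectrum(lib$PR, 6, g)$values
  expect_equal(p2, 2 * p1, tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(pure_spectrum(lib$PR, -1, g), "negative")
  # a single band evaluated at its centre equals conc x height
  m <- component_model("X", list(gaussian_band(250, 5, 0.2)))
  s <- pure_spectrum(m, 7, g)
  expect_equal(s$values[1, index_of <- which(wavelengths(g) == 250)], 7 * 0.2)
})

test_that("mixtures are additive and reproducible under a fixed seed", {
  lib <- default_library()
  g <- mcr_grid()
  concs <- c(AT = 15, PR = 10, HZ = 3, LV = 6)
  mix <- mixture_spectrum(lib, concs, g)
  manual <- Reduce(`+`, lapply(names(concs), function(nm)
    pure_spectrum(lib[[nm]], concs[[nm]], g)$values[1, ]))
  expect_equal(mix$values[1, ], manual, tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(mixture_spectrum(lib, c(AT = 0, PR = 0), g)$values[1, ],
               rep(0, g$n_points), ignore_attr = TRUE)
  expect_error(mixture_spectrum(lib, c(XX = 1), g), "unknown component")
  n1 <- mixture_spectrum(lib, concs, g, sigma = 0.002, seed = 99)
  n2 <- mixture_spectrum(lib, concs, g, sigma = 0.002, seed = 99)
  expect_identical(n1$values, n2$values)
  n3 <- mixture_spectrum(lib, concs, g, sigma = 0.002, seed = 100)
  expect_false(identical(n1$values, n3$values))
})

test_that("simulated datasets are exactly bilinear with the design rank", {
  design <- standard_design()
  lib <- default_library()
  g <- mcr_grid()
  ds <- simulate_dataset(design, lib, g, sigma = 0)
  expect_equal(n_samples(ds), 25L)
  U <- library_matrix(g)[, colnames(design)]
  expect_equal(ds$values, design %*% t(U), tolerance = 1e-12,
               ignore_attr = TRUE)
  # noiseless rank equals the number of components present
  sv <- svd(ds$values)$d
  expect_lt(sv[5] / sv[1], 1e-10)
  full <- cbind(design, URINE = urine_levels(25, 7))
  sv5 <- svd(simulate_dataset(full, lib, g, sigma = 0)$values)$d
  expect_gt(sv5[5] / sv5[1], 1e-10)
  expect_lt(sv5[6] / sv5[1], 1e-10)
})

test_that("scaling a design column scales that component's contribution", {
  design <- standard_design()
  lib <- default_library()
  g <- mcr_grid()
  d1 <- simulate_dataset(design, lib, g, sigma = 0)
  design2 <- design; design2[, "HZ"] <- 2 * design2[, "HZ"]
  d2 <- simulate_dataset(design2, lib, g, sigma = 0)
  hz <- outer(design[, "HZ"], unit_spectrum(lib$HZ, g))
  expect_equal(d2$values - d1$values, hz, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("per-row seeds make single spectra reproducible in isolation", {
  design <- standard_design()[1:3, ]
  lib <- default_library()
  g <- mcr_grid()
  ds <- simulate_dataset(design, lib, g, sigma = 0.002, seed = 40)
  row2 <- mixture_spectrum(lib, design[2, ], g, sigma = 0.002,
                           seed = 40 + 2, label = "mix2")
  expect_equal(ds$values[2, ], row2$values[1, ], ignore_attr = TRUE)
})
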