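# Shared fixtures built in code.

# two-band toy library with disjoint supports (for SIMPLISMA sanity checks)
toy_disjoint_library <- function() {
  list(A = component_model("A", list(gaussian_band(240, 3, 0.5))),
       B = component_model("B", list(gaussian_band(280, 3, 0.5))))
}

# matrix of unit spectra of the built-in library on a grid
library_matrix <- function(grid = acquisition_grid()) {
  lib <- default_library()
  sapply(lib, unit_spectrum, grid = grid)
}

# the standard 25-run concentration design (ug/mL)
standard_design <- function() {
  scale_design(multilevel_design(5, 4), default_levels())
}

# simulate the 25 design mixtures plus urine background on the working grid
simulate_mcr_dataset <- function(sigma = 0, seed = 11) {
  design <- standard_design()
  full <- cbind(design, URINE = urine_levels(25, seed + 1000L))
  ds <- simulate_dataset(full, default_library(), acquisition_grid(),
                         sigma = sigma, seed = seed)
  list(design = design, full = full,
       spectra = spec_resample(spec_window(ds, 220, 290), 0.4))
}

# independent SIMPLISMA oracle: recompute weighted purity at each pick with
# QR-based residual volumes instead of determinants
simplisma_oracle <- function(D, k, noise_pct = 5) {
  n <- nrow(D)
  mu <- colMeans(D)
  s <- apply(D, 2, function(x) sqrt(mean((x - mean(x))^2)))
  off <- noise_pct / 100 * max(mu)
  Z <- sweep(D, 2, sqrt(n) * sqrt(mu^2 + (s + off)^2), "/")
  pure <- integer(0)
  for (i in seq_len(k)) {
    w <- vapply(seq_len(ncol(D)), function(j) {
      M <- Z[, c(j, pure), drop = FALSE]
      # squared volume of the parallelotope spanned by the columns
      prod(abs(diag(qr.R(qr(M)))))^2
    }, numeric(1))
    p <- (s / (mu + off)) * w
    if (length(pure)) p[pure] <- -Inf
    pure <- c(pure, which.max(p))
  }
  pure
}
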