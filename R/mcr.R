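#' Non-negative least squares
#'
#' Solves `min ||A x - b||` subject to `x >= 0` for each column `b` of `B`
#' by the Lawson-Hanson active-set algorithm (compiled).
#'
#' @param A numeric matrix (n x k).
#' @param B numeric matrix or vector of right-hand sides (n x r).
#' @return k x r matrix of non-negative solutions.
#' @export
nnls <- function(A, B) {
  A <- as.matrix(A)
  if (is.vector(B)) B <- matrix(B, ncol = 1)
  .nnls_solve(A, as.matrix(B))
}

#' Percentage lack of fit
#'
#' `100 * sqrt(sum(E^2) / sum(D^2))` with `E = D - C %*% t(S)`.
#'
#' @param D data matrix (samples x wavelengths) or `"spectra"` object.
#' @param C concentration profiles (samples x components).
#' @param S spectral profiles (wavelengths x components).
#' @return percent lack of fit.
#' @export
lack_of_fit <- function(D, C, S) {
  if (inherits(D, "spectra")) D <- D$values
  if (!sum(D^2)) stop("all-zero data matrix")
  E <- D - C %*% t(S)
  100 * sqrt(sum(E^2) / sum(D^2))
}

#' Percentage of explained variance
#'
#' `100 * (sum(D^2) - sum(E^2)) / sum(D^2)`; identically
#' `100 - lof^2 / 100`.
#'
#' @inheritParams lack_of_fit
#' @return percent explained variance.
#' @export
explained_variance <- function(D, C, S) {
  if (inherits(D, "spectra")) D <- D$values
  if (!sum(D^2)) stop("all-zero data matrix")
  E <- D - C %*% t(S)
  100 * (sum(D^2) - sum(E^2)) / sum(D^2)
}

#' SIMPLISMA purest-variable selection
#'
#' Selects `k` purest wavelengths by the standard purity criterion
#' `p_j = s_j / (mu_j + offset)` with `offset = noise_pct/100 * max(mu)`,
#' deflating after each pick with the determinant-based weight computed on
#' the correlation-around-origin matrix of the length-scaled data.
#'
#' @param D data matrix (samples x wavelengths) or `"spectra"` object;
#'   absorbances, non-negative.
#' @param k number of pure variables (components) to select.
#' @param noise_pct noise offset as a percentage of the largest column mean
#'   (default 5).
#' @return list with `pure` (column indices in pick order), `purity`
#'   (the k purity values at pick time) and `C0` (the data restricted to the
#'   pure variables: samples x k initial concentration estimates).
#' @export
simplisma <- function(D, k, noise_pct = 5) {
  if (inherits(D, "spectra")) D <- D$values
  n <- nrow(D); m <- ncol(D)
  if (k > min(n, m)) stop("k exceeds matrix dimensions")
  mu <- colMeans(D)
  s <- apply(D, 2, function(x) sqrt(mean((x - mean(x))^2)))
  off <- noise_pct / 100 * max(mu)
  lambda <- sqrt(mu^2 + (s + off)^2)
  Z <- sweep(D, 2, sqrt(n) * lambda, "/")
  COO <- crossprod(Z)
  if (k > qr(COO)$rank)
    warning("k exceeds the numerical rank of the data; proceeding")
  pure <- integer(0)
  pvals <- numeric(0)
  base <- s / (mu + off)
  for (i in seq_len(k)) {
    w <- vapply(seq_len(m), function(j)
      det(as.matrix(COO[c(j, pure), c(j, pure)])), numeric(1))
    p <- base * w
    if (length(pure)) p[pure] <- -Inf
    j <- which.max(p)
    pure <- c(pure, j)
    pvals <- c(pvals, p[j])
  }
  list(pure = pure, purity = pvals, C0 = D[, pure, drop = FALSE])
}

#' Per-component correlation constraint
#'
#' Regresses a resolved concentration column on known reference values over
#' the calibration rows (ordinary least squares), maps the column to
#' concentration units through the inverse regression and replaces
#' calibration entries by the regression-mapped references.
#'
#' @param resolved numeric vector: resolved (arbitrary-unit) concentrations,
#'   calibration and unknown rows.
#' @param refs reference concentrations for the calibration rows (ug/mL).
#' @param cal_rows indices of the calibration rows within `resolved`
#'   (default: the first `length(refs)` entries).
#' @return list with `corrected` (full-length vector in concentration
#'   units: references' fit on calibration rows, inverse-regressed values on
#'   unknown rows), `slope` and `intercept` of the resolved-vs-reference
#'   regression.
#' @export
correlation_constraint <- function(resolved, refs,
                                   cal_rows = seq_along(refs)) {
  if (length(refs) < 2) stop("need at least 2 calibration references")
  if (stats::var(resolved[cal_rows]) == 0)
    stop("zero-variance resolved column")
  fit <- stats::lm.fit(cbind(1, refs), resolved[cal_rows])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  corrected <- (resolved - a) / b
  corrected[cal_rows] <- refs
  list(corrected = as.numeric(corrected),
       slope = unname(b), intercept = unname(a))
}

#' Multivariate curve resolution by alternating least squares
#'
#' Bilinear decomposition `D = C %*% t(S) + E` refined by alternating
#' non-negative least squares with SIMPLISMA initial spectral estimates and
#' a correlation constraint anchoring the analyte concentration columns to
#' the calibration references.
#'
#' After a short unconstrained burn-in, components are matched to analytes
#' by maximal absolute correlation between resolved columns and references;
#' from then on each iteration (i) solves the rows of C by NNLS given S,
#' (ii) applies the correlation constraint to the analyte columns,
#' (iii) solves the columns of S by NNLS given C. Iteration stops when the
#' relative change in lack of fit falls below `tol` or at `max_iter`; the
#' best (lowest-lof) model is kept.
#'
#' Two constraint variants are available: `"equality"` (default) pins the
#' calibration entries to the reference values, so resolved concentrations
#' are already in ug/mL; `"regression"` maps them through an ordinary
#' least-squares fit of resolved on reference, retaining a per-analyte
#' slope/intercept that [predict.mcr_als()] inverts.
#'
#' @param D calibration data: `"spectra"` object or matrix (samples x
#'   wavelengths).
#' @param refs reference concentrations for the calibration samples
#'   (samples x analytes matrix with analyte colnames).
#' @param n_components number of components (default `ncol(refs) + 1`:
#'   the analytes plus one free interferent).
#' @param max_iter iteration cap (default 100).
#' @param tol relative lack-of-fit change for convergence (default 1e-4,
#'   i.e. 0.01\%).
#' @param burnin unconstrained iterations before components are assigned
#'   (default 5).
#' @param variant correlation-constraint variant, `"equality"` or
#'   `"regression"`.
#' @param noise_pct SIMPLISMA noise offset (percent).
#' @param nonneg_conc,nonneg_spectra non-negativity flags (both default
#'   `TRUE`; unconstrained least squares is used when off).
#' @return object of class `"mcr_als"` with elements `C` (samples x
#'   components, analyte columns in concentration units for the equality
#'   variant), `S` (wavelengths x components), `lof_pct`,
#'   `explained_var_pct`, `iterations`, `converged`, `assignment` (component
#'   index per analyte), `regressions` (per-analyte slope/intercept),
#'   `lof_history`, `settings`, and the training grid.
#' @export
mcr_als <- function(D, refs, n_components = ncol(refs) + 1L,
                    max_iter = 100L, tol = 1e-4, burnin = 5L,
                    variant = c("equality", "regression"),
                    noise_pct = 5, nonneg_conc = TRUE, nonneg_spectra = TRUE) {
  variant <- match.arg(variant)
  grid <- if (inherits(D, "spectra")) D$grid else NULL
  ids <- if (inherits(D, "spectra")) D$samples else rownames(D)
  Dm <- if (inherits(D, "spectra")) D$values else as.matrix(D)
  refs <- as.matrix(refs)
  if (is.null(colnames(refs))) stop("refs must have analyte colnames")
  if (nrow(refs) != nrow(Dm)) stop("refs rows must match data rows")
  if (n_components < ncol(refs))
    stop("n_components must be at least the number of constrained analytes")
  k <- as.integer(n_components)

  solveC <- function(S) {
    if (nonneg_conc) t(nnls(S, t(Dm))) else t(qr.solve(S, t(Dm)))
  }
  solveS <- function(C) {
    if (nonneg_spectra) t(nnls(C, Dm)) else t(qr.solve(C, Dm))
  }

  init <- simplisma(Dm, k, noise_pct)
  S <- solveS(pmax(init$C0, 0))
  assign <- NULL
  regs <- rep(list(c(intercept = 0, slope = 1)), ncol(refs))
  names(regs) <- colnames(refs)
  lofh <- numeric(0)
  best <- NULL; best_lof <- Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- solveC(S)
    if (it > burnin) {
      if (is.null(assign)) assign <- .assign_components(C, refs)
      for (a in seq_len(ncol(refs))) {
        j <- assign[a]
        if (variant == "equality") {
          C[, j] <- refs[, a]
        } else {
          cc <- correlation_constraint(C[, j], refs[, a])
          regs[[a]] <- c(intercept = cc$intercept, slope = cc$slope)
          C[, j] <- cc$intercept + cc$slope * refs[, a]
        }
      }
      C[C < 0] <- 0
    }
    if (any(colSums(C) == 0))
      stop("degenerate all-zero component during ALS")
    S <- solveS(C)
    lofh <- c(lofh, lack_of_fit(Dm, C, S))
    l <- lofh[length(lofh)]
    if (!is.null(assign) && l < best_lof) {
      best_lof <- l
      best <- list(C = C, S = S, regs = regs, assign = assign)
    }
    if (it > burnin + 1L &&
        abs(lofh[it - 1L] - l) < tol * max(l, 1e-12)) {
      converged <- TRUE
      break
    }
  }
  C <- best$C; S <- best$S
  comp_names <- paste0("comp", seq_len(k))
  comp_names[best$assign] <- colnames(refs)
  colnames(C) <- comp_names; colnames(S) <- comp_names
  rownames(C) <- ids
  structure(list(C = C, S = S,
                 E = Dm - C %*% t(S),
                 lof_pct = best_lof,
                 explained_var_pct = 100 - best_lof^2 / 100,
                 iterations = length(lofh), converged = converged,
                 assignment = stats::setNames(best$assign, colnames(refs)),
                 regressions = best$regs,
                 lof_history = lofh,
                 component_labels = comp_names,
                 grid = grid,
                 settings = list(n_components = k, max_iter = max_iter,
                                 tol = tol, burnin = burnin,
                                 variant = variant, noise_pct = noise_pct,
                                 nonneg_conc = nonneg_conc,
                                 nonneg_spectra = nonneg_spectra)),
            class = "mcr_als")
}

# Greedy component-to-analyte matching by maximal absolute correlation.
.assign_components <- function(C, refs) {
  cors <- abs(stats::cor(C, refs))
  cors[!is.finite(cors)] <- -Inf
  out <- rep(NA_integer_, ncol(refs))
  for (i in seq_len(ncol(refs))) {
    ij <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    out[ij[2]] <- ij[1]
    cors[ij[1], ] <- -Inf; cors[, ij[2]] <- -Inf
  }
  out
}

#' @export
print.mcr_als <- function(x, ...) {
  cat(sprintf("MCR-ALS model: %d components, %d samples x %d wavelengths\n",
              ncol(x$C), nrow(x$C), nrow(x$S)))
  cat(sprintf("  lack of fit %.4g%%, explained variance %s%%\n",
              x$lof_pct,
              formatC(x$explained_var_pct, digits = 8, format = "fg")))
  cat(sprintf("  %d iterations (%s), constraint variant '%s'\n",
              x$iterations,
              if (x$converged) "converged" else "not converged",
              x$settings$variant))
  cat("  analyte components:",
      paste(names(x$assignment), "->", x$component_labels[x$assignment],
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mcr_als <- function(object, ...) {
  cat(sprintf("MCR-ALS (%s constraint), %d components\n",
              object$settings$variant, ncol(object$C)))
  cat(sprintf("lack of fit: %.6g%%   explained variance: %.8g%%\n",
              object$lof_pct, object$explained_var_pct))
  cat(sprintf("iterations: %d (converged: %s)\n", object$iterations,
              object$converged))
  for (a in names(object$regressions)) {
    r <- object$regressions[[a]]
    cat(sprintf("  %s: slope %.6g, intercept %.6g\n", a,
                r[["slope"]], r[["intercept"]]))
  }
  invisible(object)
}

#' @export
residuals.mcr_als <- function(object, ...) object$E

#' @export
plot.mcr_als <- function(x, ...) {
  if (is.null(x$grid)) {
    graphics::matplot(x$S, type = "l", lty = 1, xlab = "variable",
                      ylab = "resolved spectral profile", ...)
  } else {
    graphics::matplot(wavelengths(x$grid), x$S, type = "l", lty = 1,
                      xlab = "wavelength (nm)",
                      ylab = "resolved spectral profile", ...)
  }
  graphics::legend("topright", legend = colnames(x$S), lty = 1,
                   col = seq_len(ncol(x$S)), bty = "n")
  invisible(x)
}

#' Predict analyte concentrations for new spectra
#'
#' Re-solves the concentration profiles of the unknowns by non-negative
#' least squares with the resolved spectral profiles held fixed, then maps
#' the analyte columns to ug/mL through the stored correlation-constraint
#' regressions.
#'
#' @param object a fitted [mcr_als()] model.
#' @param newdata `"spectra"` object or matrix on the training grid.
#' @param ... unused.
#' @return matrix (samples x analytes) of predicted concentrations.
#' @export
predict.mcr_als <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra")) {
    if (!is.null(object$grid) &&
        !identical(unclass(newdata$grid), unclass(object$grid)))
      stop("newdata grid differs from the training grid")
    ids <- newdata$samples
    Dm <- newdata$values
  } else {
    Dm <- as.matrix(newdata)
    ids <- rownames(Dm)
  }
  if (ncol(Dm) != nrow(object$S)) stop("wavelength dimension mismatch")
  Cn <- t(nnls(object$S, t(Dm)))
  out <- sapply(seq_along(object$assignment), function(a) {
    r <- object$regressions[[a]]
    (Cn[, object$assignment[a]] - r[["intercept"]]) / r[["slope"]]
  })
  out <- matrix(out, nrow = nrow(Dm),
                dimnames = list(ids, names(object$assignment)))
  out
}
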