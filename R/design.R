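# Cyclic level sequence for the five-level 25-run construction, coded 0-4
# with 2 the centre level. Run 1 holds every factor at the centre level;
# each subsequent factor repeats the previous one with runs 2..25 rotated up
# by one position. The resulting coded columns are balanced (each level
# exactly five times per factor) and exactly mutually orthogonal.
.gen5 <- c(2L, 0L, 0L, 4L, 1L, 4L, 2L, 1L, 1L, 3L, 4L, 3L,
           2L, 4L, 4L, 0L, 3L, 0L, 2L, 3L, 3L, 1L, 0L, 1L)

#' Multilevel multifactor calibration design (coded levels)
#'
#' Builds the cyclic five-level design with `n_levels^2` runs: factor 1 is
#' the centre level followed by a fixed cyclic level sequence; each further
#' factor repeats the previous one with runs 2..n^2 rotated by one. Every
#' factor takes each level exactly `n_levels` times and distinct coded
#' columns are mutually orthogonal.
#'
#' @param n_levels number of concentration levels (5 supported).
#' @param n_factors number of analytes/factors (1 to `n_levels - 1` for
#'   orthogonality; 4 in the standard design).
#' @return integer matrix (`n_levels^2` x `n_factors`) of coded levels 0 to
#'   `n_levels - 1`, with rownames `"1"`, `"2"`, ....
#' @examples
#' d <- multilevel_design(5, 4)
#' dim(d)          # 25 4
#' colSums(d == 0) # each level appears 5 times per factor
#' @export
multilevel_design <- function(n_levels = 5, n_factors = 4) {
  if (n_levels != 5)
    stop("only the 5-level cyclic generator is implemented")
  if (n_factors < 1) stop("n_factors must be >= 1")
  n_runs <- n_levels^2
  col <- c(2L, .gen5)
  out <- matrix(NA_integer_, n_runs, n_factors)
  for (j in seq_len(n_factors)) {
    out[, j] <- col
    tail_rot <- col[-1][c(2:(n_runs - 1), 1)]
    col <- c(col[1], tail_rot)
  }
  rownames(out) <- as.character(seq_len(n_runs))
  colnames(out) <- paste0("F", seq_len(n_factors))
  out
}

#' Map coded design levels to physical concentrations
#'
#' @param coded integer matrix of coded levels (0-based), e.g. from
#'   [multilevel_design()].
#' @param level_values named list (one entry per factor, in column order) of
#'   ascending concentration vectors (ug/mL), each of length
#'   `max(coded) + 1`. The default reproduces the standard calibration
#'   ranges: AT 5-25, PR 1-10, HZ 1-10, LV 1-7 ug/mL.
#' @return numeric matrix of concentrations with `names(level_values)` as
#'   colnames.
#' @export
scale_design <- function(coded, level_values = default_levels()) {
  coded <- as.matrix(coded)
  if (length(level_values) != ncol(coded))
    stop("need one level set per design column")
  n_lev <- max(coded) + 1L
  out <- matrix(NA_real_, nrow(coded), ncol(coded))
  for (j in seq_along(level_values)) {
    lv <- level_values[[j]]
    if (length(lv) != n_lev)
      stop("level set ", j, " has ", length(lv), " values; expected ", n_lev)
    out[, j] <- lv[coded[, j] + 1L]
  }
  dimnames(out) <- list(rownames(coded), names(level_values))
  out
}

#' Default concentration levels of the four analytes
#' @return named list of five-level concentration sets (ug/mL).
#' @export
default_levels <- function() {
  list(AT = c(5, 10, 15, 20, 25),
       PR = c(1, 3.5, 5.5, 8, 10),
       HZ = c(1, 3.5, 5.5, 8, 10),
       LV = c(1, 2.5, 4, 5.5, 7))
}

#' Default external-validation runs of the 25-run design
#' @return integer vector of 1-based run indices.
#' @export
default_validation_rows <- function() c(3L, 4L, 9L, 15L, 18L, 20L, 23L)

#' Split a design into calibration and validation sets
#'
#' Disjoint partition preserving run order. The default validation rows are
#' the seven starred runs of the standard 25-run design, leaving 18
#' calibration runs.
#'
#' @param design concentration matrix (runs x analytes).
#' @param validation_rows 1-based run indices of the validation set.
#' @return list with elements `calibration` and `validation` (matrices) and
#'   the index vectors `calibration_rows`, `validation_rows`.
#' @export
split_calibration_validation <- function(design,
                                         validation_rows = default_validation_rows()) {
  design <- as.matrix(design)
  if (!length(validation_rows)) stop("validation_rows must be non-empty")
  validation_rows <- as.integer(validation_rows)
  if (any(validation_rows < 1 | validation_rows > nrow(design)))
    stop("validation row index out of range")
  if (anyDuplicated(validation_rows)) stop("duplicated validation rows")
  cal <- setdiff(seq_len(nrow(design)), validation_rows)
  list(calibration = design[cal, , drop = FALSE],
       validation = design[validation_rows, , drop = FALSE],
       calibration_rows = cal,
       validation_rows = sort(validation_rows))
}

#' The reference 25-run concentration table
#'
#' Reads the bundled fixture carrying the reference calibration/validation
#' concentration matrix (ug/mL) with its validation flags — the same matrix
#' that [multilevel_design()] plus [scale_design()] generate.
#'
#' @return data.frame with columns `mix`, `AT`, `PR`, `HZ`, `LV`,
#'   `validation` (logical).
#' @export
reference_design <- function() {
  path <- system.file("extdata", "reference_design25.csv",
                      package = "quadspec", mustWork = TRUE)
  df <- utils::read.csv(path)
  df$validation <- as.logical(df$validation)
  df
}
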