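#' Principal components of control-probe intensities
#'
#' Control probes carry no biological signal, so the leading PCs of their
#' intensities summarize technical variation (plate, slide, reagent batch)
#' and can be regressed out of the methylation data. Intensities are
#' log2-transformed and column-centered before PCA; no variance scaling is
#' applied. The sign of each PC is fixed by making its largest-absolute
#' loading positive.
#'
#' @param control_intensities Samples x control-probe matrix of positive
#'   intensities, samples as rownames.
#' @param n_pcs Number of PCs to return. Default 10.
#' @return Samples x `n_pcs` score matrix (columns `CtrlPC1..`); fewer
#'   columns with a warning if the matrix rank is lower.
#' @export
control_probe_pcs <- function(control_intensities, n_pcs = 10) {
  x <- as.matrix(control_intensities)
  if (any(x <= 0, na.rm = TRUE)) stop_validation("control intensities must be positive")
  if (nrow(x) < n_pcs + 1) {
    stop_validation("need at least n_pcs + 1 samples for ", n_pcs, " control PCs")
  }
  lx <- log2(x)
  centered <- scale(lx, center = TRUE, scale = FALSE)
  r <- qr(centered)$rank
  if (r < n_pcs) {
    warning("control-probe matrix has rank ", r, " < ", n_pcs,
            "; returning ", r, " PCs")
    n_pcs <- r
  }
  if (n_pcs == 0) {
    out <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
    return(out)
  }
  pc <- fix_pc_signs(prcomp(centered, center = FALSE, scale. = FALSE))
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  colnames(scores) <- paste0("CtrlPC", seq_len(n_pcs))
  rownames(scores) <- rownames(x)
  scores
}

#' Principal components of cell-type proportions
#'
#' Cell proportions are compositional (each sample sums to 1), so their
#' centered covariance is rank-deficient by one; with `d` cell types the
#' first `d - 1` PCs carry all the variation and are returned.
#'
#' @param props Samples x cell-type matrix of fractions in `[0, 1]`, rows
#'   summing to 1 within 0.02.
#' @return Samples x `(d - 1)` score matrix (columns `CellPC1..`).
#' @export
cell_proportion_pcs <- function(props) {
  x <- as.matrix(props)
  d <- ncol(x)
  if (d < 2) stop_validation("need at least 2 cell types")
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop_validation("proportions outside [0, 1]")
  row_sums <- rowSums(x)
  if (any(abs(row_sums - 1) > 0.02)) {
    warning("some cell-proportion rows do not sum to 1 within 0.02")
  }
  centered <- scale(x, center = TRUE, scale = FALSE)
  pc <- fix_pc_signs(prcomp(centered, center = FALSE, scale. = FALSE))
  scores <- pc$x[, seq_len(min(d - 1, ncol(pc$x))), drop = FALSE]
  colnames(scores) <- paste0("CellPC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(x)
  scores
}

# deterministic sign convention: the largest-absolute loading of each PC
# is made positive (ties broken by the first such loading)
fix_pc_signs <- function(pc) {
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc
}

#' Assemble the residualization design matrix
#'
#' Columns: intercept, sex (F = 0, M = 1), age in years, all cell-proportion
#' PCs, all control-probe PCs. Samples must appear in the same order in
#' every input; the design must be full column rank (an all-female cohort,
#' for instance, must drop the sex column first).
#'
#' @param sheet Sample sheet `data.frame` with columns `sample_id`,
#'   `individual_id`, `sex` ("F"/"M"), `age`.
#' @param cell_pcs Samples x cell-PC score matrix (from
#'   [cell_proportion_pcs()]).
#' @param control_pcs Samples x control-PC score matrix (from
#'   [control_probe_pcs()]).
#' @return A numeric design matrix with rownames = sample ids, of class
#'   `covariate_design`.
#' @export
build_design <- function(sheet, cell_pcs, control_pcs) {
  cell_pcs <- as.matrix(cell_pcs); control_pcs <- as.matrix(control_pcs)
  ids <- as.character(sheet$sample_id)
  if (!identical(rownames(cell_pcs), ids) || !identical(rownames(control_pcs), ids)) {
    stop_validation("sample order mismatch between sheet and PC matrices")
  }
  bad <- ids[is.na(sheet$sex) | is.na(sheet$age)]
  if (length(bad)) {
    stop_validation("missing sex or age for sample(s): ",
                    paste(utils::head(bad, 10), collapse = ", "))
  }
  if (!all(sheet$sex %in% c("F", "M"))) stop_validation("sex must be 'F' or 'M'")
  design <- cbind(intercept = 1,
                  sex = as.numeric(sheet$sex == "M"),
                  age = as.numeric(sheet$age),
                  cell_pcs, control_pcs)
  rownames(design) <- ids
  dq <- qr(design)
  if (dq$rank < ncol(design)) {
    dropped <- colnames(design)[dq$pivot[(dq$rank + 1):ncol(design)]]
    stop_validation("design matrix is rank deficient; collinear column(s): ",
                    paste(dropped, collapse = ", "),
                    " (drop or recode them, e.g. drop sex in a single-sex cohort)")
  }
  class(design) <- c("covariate_design", class(design))
  design
}
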