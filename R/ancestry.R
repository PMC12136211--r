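#' Residualize SNP-overlapping betas on the covariate design
#'
#' Fits, for every probe, an ordinary least-squares regression of its beta
#' values on the covariate design (intercept, sex, age, cell PCs, control
#' PCs) and keeps the residuals. A single QR decomposition of the design
#' is shared across probes, so the operation is one matrix product.
#' Residual rows are orthogonal to every design column and centered
#' (the intercept is in the design).
#'
#' @param beta Probes x samples matrix with no missing values (run
#'   [impute_knn()] first).
#' @param design A [build_design()] matrix whose rownames match the beta
#'   column names in order.
#' @return Probes x samples residual matrix of class `residual_matrix`.
#' @export
residualize <- function(beta, design) {
  beta <- as.matrix(beta)
  if (anyNA(beta)) stop_validation("beta contains missing values; impute first")
  if (!identical(colnames(beta), rownames(design))) {
    stop_validation("sample mismatch between beta columns and design rows")
  }
  qx <- qr.Q(qr(design))                      # samples x p, orthonormal
  res <- beta - (beta %*% qx) %*% t(qx)
  class(res) <- c("residual_matrix", class(res))
  res
}

#' Call genotypes from rs-probe beta values
#'
#' The dedicated genotyping rs probes on methylation arrays are trimodal:
#' homozygous reference, heterozygous and homozygous alternate samples
#' cluster near beta 0.1, 0.5 and 0.9. Calls use fixed thresholds on the
#' beta scale and are encoded as allele dosage / 2, i.e. 0, 0.5 or 1;
#' boundary values fall into the heterozygote class. Missing betas
#' propagate.
#'
#' @param rs_beta rs-probes x samples beta matrix in `[0, 1]`.
#' @param low,high Thresholds: `beta < low` is 0, `beta > high` is 1,
#'   anything between (inclusive) is 0.5. Defaults 0.25 / 0.75.
#' @return Matrix of the same shape with values in `{0, 0.5, 1, NA}`.
#' @export
call_rs_genotypes <- function(rs_beta, low = 0.25, high = 0.75) {
  if (low >= high) stop_validation("low threshold must be below high threshold")
  rs_beta <- as.matrix(rs_beta)
  if (any(rs_beta < 0 | rs_beta > 1, na.rm = TRUE)) {
    stop_validation("rs betas outside [0, 1]")
  }
  g <- rs_beta
  g[] <- 0.5
  g[rs_beta < low] <- 0
  g[rs_beta > high] <- 1
  g[is.na(rs_beta)] <- NA_real_
  g
}

#' Combine residualized betas with genotype calls
#'
#' Stacks the residualized SNP-overlapping rows on top of the rs-probe
#' genotype rows and centers every row to mean zero, producing the feature
#' matrix for the genotype-augmented PCA. Genotype rows are kept on their
#' 0/0.5/1 dosage scale (then centered), deliberately comparable in range
#' to beta-scale residuals; no variance standardization is applied.
#' Genotype rows containing any missing call are dropped.
#'
#' @param residuals A [residualize()] output.
#' @param genotypes A [call_rs_genotypes()] output over the same samples,
#'   in the same order. May have zero rows, in which case the features are
#'   the centered residuals alone (with a warning).
#' @return Features x samples matrix of class `feature_matrix`.
#' @export
combine_features <- function(residuals, genotypes) {
  residuals <- unclass(residuals)
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) > 0 && !identical(colnames(residuals), colnames(genotypes))) {
    stop_validation("sample mismatch between residuals and genotypes")
  }
  if (nrow(genotypes) > 0) {
    incomplete <- rowSums(is.na(genotypes)) > 0
    if (any(incomplete)) {
      msg(sum(incomplete), " genotype row(s) dropped for missing calls")
      genotypes <- genotypes[!incomplete, , drop = FALSE]
    }
  }
  if (nrow(genotypes) == 0) {
    warning("no usable genotype rows; features are residuals only")
    feats <- residuals
  } else {
    feats <- rbind(residuals, genotypes)
  }
  feats <- feats - rowMeans(feats)
  class(feats) <- c("feature_matrix", class(feats))
  feats
}

#' Ancestry PCA
#'
#' Principal-component analysis with samples as observations and feature
#' rows (residualized betas, genotype dosages) as variables. Rows are
#' already centered, so the PCA is center-only with no variance scaling;
#' sample scores come from the SVD of the samples x features matrix. The
#' sign of each component is fixed by making its largest-absolute feature
#' loading positive, and each score column is then min-max scaled to
#' `[0, 1]` so components are comparable across methods. Explained-variance
#' fractions are computed before scaling.
#'
#' @param features Features x samples matrix with (approximately) zero row
#'   means, e.g. from [combine_features()].
#' @param k Number of PCs to return (clipped to `min(n - 1, n_features)`
#'   with a warning). Default 10.
#' @param method_tag Label stored with the result, one of `"EpiAncOrig"`,
#'   `"EpiAnceR"`, `"EpiAnceRplus"`.
#' @return An object of class `ancestry_pcs`: list with `scores` (samples
#'   x k, each column spanning exactly \[0, 1\]), `scores_raw` (unscaled),
#'   `var_explained` (length-k fractions of total variance,
#'   non-increasing), `loadings`, `sample_ids`, `method`.
#' @export
ancestry_pca <- function(features, k = 10, method_tag = "EpiAnceRplus") {
  x <- t(unclass(as.matrix(features)))        # samples x features
  n <- nrow(x)
  if (n < 2) stop_validation("need at least 2 samples")
  k_max <- min(n - 1, ncol(x))
  if (k > k_max) {
    warning("k = ", k, " clipped to ", k_max)
    k <- k_max
  }
  sv <- svd(x, nu = k, nv = k)
  # sign convention: largest-absolute loading of each PC positive
  for (j in seq_len(k)) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) {
      sv$v[, j] <- -sv$v[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores_raw <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k)
  var_explained <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  scores <- matrix(apply(scores_raw, 2, scale01), nrow = n, ncol = k)
  dimnames(scores) <- dimnames(scores_raw) <-
    list(rownames(x), paste0("PC", seq_len(k)))
  structure(list(scores = scores, scores_raw = scores_raw,
                 var_explained = var_explained,
                 loadings = sv$v, sample_ids = rownames(x),
                 method = method_tag),
            class = "ancestry_pcs")
}

scale01 <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(0, length(v)))
  (v - r[1]) / (r[2] - r[1])
}

#' @export
print.ancestry_pcs <- function(x, ...) {
  cat("ancestry_pcs [", x$method, "]: ", length(x$sample_ids), " samples x ",
      ncol(x$scores), " PCs\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained[seq_len(min(5, length(x$var_explained)))]),
            collapse = " "), "...\n")
  invisible(x)
}

#' Baseline ancestry PCs from raw betas
#'
#' The original SNP-overlap approach: PCA directly on the row-centered raw
#' beta values of the SNP-overlapping probes, with no residualization and
#' no genotype augmentation. Serves as the comparison baseline for the
#' residualized and genotype-augmented variants.
#'
#' @param beta SNP-overlapping probes x samples beta matrix with no
#'   missing values.
#' @param k Number of PCs. Default 10.
#' @return An `ancestry_pcs` object with `method = "EpiAncOrig"`.
#' @export
epianc_orig_pcs <- function(beta, k = 10) {
  beta <- as.matrix(beta)
  if (anyNA(beta)) stop_validation("beta contains missing values; impute first")
  centered <- beta - rowMeans(beta)
  ancestry_pca(centered, k = k, method_tag = "EpiAncOrig")
}

#' Write ancestry PC tables
#'
#' Writes `ancestry_pcs_<method>.tsv` (sample_id + scaled PCs),
#' `ancestry_pcs_raw_<method>.tsv` (unscaled scores) and
#' `variance_explained_<method>.tsv` into a directory.
#'
#' @param pcs An `ancestry_pcs` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_ancestry_pcs <- function(pcs, dir) {
  stopifnot(inherits(pcs, "ancestry_pcs"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- pcs$method
  write_sample_table(data.frame(sample_id = pcs$sample_ids, pcs$scores,
                                check.names = FALSE),
                     file.path(dir, paste0("ancestry_pcs_", tag, ".tsv")))
  write_sample_table(data.frame(sample_id = pcs$sample_ids, pcs$scores_raw,
                                check.names = FALSE),
                     file.path(dir, paste0("ancestry_pcs_raw_", tag, ".tsv")))
  write_sample_table(data.frame(pc = paste0("PC", seq_along(pcs$var_explained)),
                                var_explained = pcs$var_explained),
                     file.path(dir, paste0("variance_explained_", tag, ".tsv")))
  invisible(dir)
}
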