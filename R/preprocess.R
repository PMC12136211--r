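#' Background-correct signal intensities
#'
#' Illumina-style background correction: for each sample and color channel
#' the background estimate is the 5th percentile of that sample's
#' negative-control intensities in that channel, subtracted from every
#' intensity routed to the channel. Corrected intensities are floored at
#' 1 AU so downstream ratios stay defined. Type I probes route both signals
#' through their own channel; type II probes read methylated in green and
#' unmethylated in red.
#'
#' @param signals A [signal_set()].
#' @param floor Minimum corrected intensity (AU). Default 1.
#' @return A `signal_set` with corrected `meth` and `unmeth`.
#' @export
background_correct <- function(signals, floor = 1) {
  stopifnot(inherits(signals, "signal_set"))
  samples <- colnames(signals$meth)
  bg <- vapply(samples, function(s) {
    nc <- signals$neg_controls[[s]]
    if (!length(nc$grn) || !length(nc$red)) {
      stop_validation("empty negative-control list for sample ", s)
    }
    c(grn = unname(quantile(nc$grn, 0.05)),
      red = unname(quantile(nc$red, 0.05)))
  }, c(grn = 0, red = 0))  # 2 x samples

  ch <- signals$probe_channel
  n_probes <- nrow(signals$meth)
  # per-entry background matrices: rows follow probe channel routing
  meth_bg <- matrix(0, n_probes, length(samples))
  unmeth_bg <- matrix(0, n_probes, length(samples))
  fill_rows <- function(target, rows, values) {
    if (any(rows)) {
      target[rows, ] <- matrix(values, sum(rows), length(samples), byrow = TRUE)
    }
    target
  }
  grn_rows <- ch %in% c("grn", "both")
  meth_bg <- fill_rows(meth_bg, grn_rows, bg["grn", ])
  meth_bg <- fill_rows(meth_bg, !grn_rows, bg["red", ])
  red_rows <- ch %in% c("red", "both")
  unmeth_bg <- fill_rows(unmeth_bg, red_rows, bg["red", ])
  unmeth_bg <- fill_rows(unmeth_bg, !red_rows, bg["grn", ])

  out <- signals
  out$meth <- pmax(signals$meth - meth_bg, floor)
  out$unmeth <- pmax(signals$unmeth - unmeth_bg, floor)
  out
}

#' Detection p-values from negative controls
#'
#' For each probe and sample, the probability that the observed total
#' signal (methylated + unmethylated) arises from background, modelled as
#' the upper tail of a normal distribution whose mean and SD come from the
#' sample's negative controls in the probe's channel(s). Type II probes
#' pool the green and red negative controls. Computed on uncorrected
#' signals.
#'
#' @param signals A [signal_set()] of raw (not background-corrected)
#'   intensities.
#' @param sd_floor Lower bound on the background SD, guarding against
#'   degenerate controls. Default 0.01 AU.
#' @return Probes x samples matrix of p-values in `[0, 1]`; missing
#'   intensities propagate as `NA`.
#' @export
detection_pvalues <- function(signals, sd_floor = 0.01) {
  stopifnot(inherits(signals, "signal_set"))
  samples <- colnames(signals$meth)
  ch <- signals$probe_channel
  total <- signals$meth + signals$unmeth
  p <- matrix(NA_real_, nrow(total), ncol(total), dimnames = dimnames(total))
  for (j in seq_along(samples)) {
    nc <- signals$neg_controls[[samples[j]]]
    if (length(nc$grn) < 2 || length(nc$red) < 2) {
      stop_validation("need at least 2 negative controls per channel for sample ",
                      samples[j])
    }
    pooled <- c(nc$grn, nc$red)
    mu <- c(grn = mean(nc$grn), red = mean(nc$red), both = mean(pooled))
    sg <- pmax(c(grn = sd(nc$grn), red = sd(nc$red), both = sd(pooled)), sd_floor)
    p[, j] <- pnorm(total[, j], mean = mu[ch], sd = sg[ch], lower.tail = FALSE)
  }
  p
}

#' Mask entries that failed detection
#'
#' Sets to missing every entry whose detection p-value exceeds the
#' threshold. Works on a beta/intensity matrix or on a whole
#' [signal_set()] (both channels masked together).
#'
#' @param x Numeric matrix or `signal_set` whose entries align with `p`.
#' @param p Detection p-value matrix.
#' @param threshold Detection p-value threshold; entries with `p >
#'   threshold` become `NA`. Default `1e-16`; set `1e-15` for the laxer
#'   reading of the same published threshold.
#' @return `x` with failed entries set to `NA`.
#' @export
mask_failed_detections <- function(x, p, threshold = 1e-16) {
  fail <- p > threshold
  if (inherits(x, "signal_set")) {
    if (!identical(dim(x$meth), dim(p))) stop_validation("shape mismatch between signals and p")
    x$meth[fail] <- NA_real_
    x$unmeth[fail] <- NA_real_
  } else {
    x <- as.matrix(x)
    if (!identical(dim(x), dim(p))) stop_validation("shape mismatch between x and p")
    x[fail] <- NA_real_
  }
  n_masked <- sum(fail, na.rm = TRUE)
  if (n_masked) msg(n_masked, " entries masked at detection p > ", format(threshold))
  x
}

#' Probe-level quality-control filter
#'
#' Excludes probes with unreliable measurements: a probe is dropped when
#' the fraction of samples with a bead count below `bead_min` exceeds
#' `bead_frac`, or the fraction of samples with missing data exceeds
#' `miss_frac`. Both inequalities are strict, so probes sitting exactly on
#' a boundary are retained.
#'
#' @param miss Logical probes x samples matrix, `TRUE` where the
#'   measurement is missing (e.g. failed detection).
#' @param bead_counts Integer matrix of the same shape.
#' @param bead_min Minimum acceptable bead count. Default 3.
#' @param bead_frac Tolerated fraction of low-bead samples. Default 0.05.
#' @param miss_frac Tolerated fraction of missing samples. Default 0.10.
#' @return Character vector of retained probe ids (row order preserved).
#' @export
filter_probes_qc <- function(miss, bead_counts, bead_min = 3,
                             bead_frac = 0.05, miss_frac = 0.10) {
  miss <- as.matrix(miss); bead_counts <- as.matrix(bead_counts)
  if (!identical(dim(miss), dim(bead_counts))) {
    stop_validation("miss and bead_counts shapes differ")
  }
  n <- ncol(miss)
  if (n == 0) stop_validation("zero samples")
  low_bead_frac <- rowMeans(bead_counts < bead_min)
  missing_frac <- rowMeans(miss)
  keep <- !(low_bead_frac > bead_frac | missing_frac > miss_frac)
  dropped <- sum(!keep)
  if (dropped) msg(dropped, " probes removed by bead-count/call-rate QC")
  rownames(miss)[keep]
}

#' Across-sample quantile normalization
#'
#' Forces every sample (column) onto a common intensity distribution: each
#' column's sorted values are replaced by the mean of the order statistics
#' across columns, ties receiving the average of their target quantiles,
#' and missing entries are left out of the ranking and restored as
#' missing. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x Numeric matrix (typically probes x samples intensities), `NA`
#'   allowed.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop_validation("quantile normalization needs >= 2 samples")
  all_missing <- colSums(!is.na(x)) == 0
  if (any(all_missing)) {
    stop_validation("column(s) entirely missing: ",
                    paste(colnames(x)[all_missing], collapse = ", "))
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Compute beta values
#'
#' `beta = meth / (meth + unmeth + offset)`, the standard fraction-methylated
#' estimate; the offset regularizes low-intensity probes. Missing
#' intensities propagate.
#'
#' @param meth,unmeth Non-negative intensity matrices of identical shape.
#' @param offset Regularizing constant (AU). Default 100.
#' @return Matrix of beta values in `[0, 1]` (class-less numeric matrix).
#' @export
compute_beta <- function(meth, unmeth, offset = 100) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (!identical(dim(meth), dim(unmeth))) stop_validation("shape mismatch")
  if (offset < 0) stop_validation("offset must be >= 0")
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop_validation("negative intensities")
  }
  denom <- meth + unmeth + offset
  beta <- meth / denom
  beta[denom == 0] <- 0
  beta
}

#' k-nearest-neighbour imputation of missing betas
#'
#' Each missing entry is replaced by the mean value, at that sample, of the
#' `k` probes nearest to the target probe. Distance between two probes is
#' the root-mean-square difference over the samples where both are
#' observed (so probes with different missingness patterns remain
#' comparable). A neighbour is usable only if it is observed at the target
#' sample and shares at least one observed sample with the target probe;
#' when fewer than `k` usable neighbours exist the probe's row mean is
#' used instead.
#'
#' @param beta Probes x samples matrix in `[0, 1]`, `NA` allowed; every
#'   probe must have at least one observed value.
#' @param k Number of neighbours. Default 5.
#' @return The matrix with no missing entries, values still in `[0, 1]`.
#' @export
impute_knn <- function(beta, k = 5) {
  beta <- as.matrix(beta)
  obs <- !is.na(beta)
  if (any(rowSums(obs) == 0)) {
    stop_validation("probe(s) with zero observed values: ",
                    paste(utils::head(rownames(beta)[rowSums(obs) == 0], 5),
                          collapse = ", "))
  }
  if (!anyNA(beta)) return(beta)

  # pairwise RMS distance over jointly observed samples, via matrix algebra
  x0 <- beta; x0[!obs] <- 0
  o <- obs * 1
  n_joint <- o %*% t(o)
  sq <- x0^2
  ss <- sq %*% t(o) + o %*% t(sq) - 2 * (x0 %*% t(x0))
  d2 <- ss / n_joint                      # NaN where no joint samples
  d <- sqrt(pmax(d2, 0))
  diag(d) <- Inf
  d[n_joint == 0] <- Inf

  row_means <- rowMeans(beta, na.rm = TRUE)
  out <- beta
  need <- which(!obs, arr.ind = TRUE)
  for (col in unique(need[, 2])) {
    rows <- need[need[, 2] == col, 1]
    donors_ok <- obs[, col]
    for (i in rows) {
      cand <- which(donors_ok & is.finite(d[i, ]))
      if (length(cand) < k) {
        out[i, col] <- row_means[i]
      } else {
        nn <- cand[order(d[i, cand], cand)][seq_len(k)]
        out[i, col] <- mean(beta[nn, col])
      }
    }
  }
  out
}
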