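# fixtures and independent oracles shared across test files

write_toy_annotation <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# minimal signal set: one type-I grn, one type-I red, rest type II
make_signals <- function(meth, unmeth, bead = NULL,
                         channels = NULL, bg_grn = 100, bg_red = 100) {
  probes <- rownames(meth)
  samples <- colnames(meth)
  if (is.null(bead)) {
    bead <- matrix(10L, nrow(meth), ncol(meth), dimnames = dimnames(meth))
  }
  if (is.null(channels)) {
    channels <- setNames(rep("both", length(probes)), probes)
  }
  nc <- lapply(samples, function(s) {
    list(grn = rep(bg_grn, 10) + seq(-4.5, 4.5, length.out = 10),
         red = rep(bg_red, 10) + seq(-4.5, 4.5, length.out = 10))
  })
  names(nc) <- samples
  signal_set(meth, unmeth, bead, nc, channels)
}

named_matrix <- function(values, n_probes, n_samples,
                         probe_prefix = "cg", sample_prefix = "s") {
  matrix(values, n_probes, n_samples,
         dimnames = list(paste0(probe_prefix, seq_len(n_probes)),
                         paste0(sample_prefix, seq_len(n_samples))))
}

# brute-force silhouette: direct transcription of the definition
silhouette_oracle <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- function(i, j) sqrt(sum((points[i, ] - points[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), 0))
    b <- Inf
    for (l in setdiff(unique(labels), labels[i])) {
      members <- which(labels == l)
      b <- min(b, mean(vapply(members, function(j) d(i, j), 0)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# mean-of-order-statistics quantile normalization, complete matrices only
qn_oracle <- function(x) {
  target <- rowMeans(apply(x, 2, sort))
  apply(x, 2, function(col) target[rank(col, ties.method = "average")])
}

# exhaustive k-NN imputation following the documented distance/fallback rules
knn_oracle <- function(beta, k) {
  out <- beta
  for (idx in which(is.na(beta))) {
    i <- (idx - 1) %% nrow(beta) + 1
    s <- (idx - 1) %/% nrow(beta) + 1
    dists <- rep(Inf, nrow(beta))
    for (j in seq_len(nrow(beta))) {
      if (j == i || is.na(beta[j, s])) next
      joint <- !is.na(beta[i, ]) & !is.na(beta[j, ])
      if (!any(joint)) next
      dists[j] <- sqrt(mean((beta[i, joint] - beta[j, joint])^2))
    }
    usable <- which(is.finite(dists))
    if (length(usable) < k) {
      out[i, s] <- mean(beta[i, ], na.rm = TRUE)
    } else {
      nn <- usable[order(dists[usable], usable)][seq_len(k)]
      out[i, s] <- mean(beta[nn, s])
    }
  }
  out
}

# small fast simulator config for structural tests
tiny_config <- function(seed = 1, groups = c(A = 12, B = 12, C = 12), ...) {
  sim_config(seed = seed, groups = groups,
             n_snp0bp = 80, n_rs = 10, n_decoy = 10, n_control = 30,
             ...)
}
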