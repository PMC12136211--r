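#' Silhouette scores in ancestry-PC space
#'
#' Classic silhouette with Euclidean distance: for sample i,
#' `s(i) = (b - a) / max(a, b)` where `a` is the mean distance to the other
#' members of its own cluster and `b` the smallest mean distance to any
#' other cluster. Samples in singleton clusters score 0, as does the
#' degenerate `a = b = 0` case. Typically applied to the first three
#' scaled ancestry PCs, with clusters defined by ancestry group or, for
#' repeated samples, by individual.
#'
#' @param points Samples x d coordinate matrix (d is usually 3).
#' @param labels Cluster label per sample (character/factor), same length
#'   and order as `nrow(points)`.
#' @return List with `scores` (per-sample, named) and `mean`.
#' @export
silhouette_scores <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  n <- nrow(points)
  stopifnot(length(labels) == n)
  if (length(unique(labels)) < 2) {
    stop_validation("silhouette undefined for a single cluster")
  }
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), 0))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(s) <- rownames(points)
  list(scores = s, mean = mean(s))
}

#' Cluster centroids and within-cluster density
#'
#' Centroid of each label is the coordinate-wise mean of its members;
#' cluster density is the mean Euclidean distance of members to their own
#' centroid (0 for singletons).
#'
#' @param points Samples x d coordinate matrix.
#' @param labels Cluster label per sample.
#' @return List with `centroids` (labels x d matrix) and `within_distance`
#'   (named numeric).
#' @export
cluster_centroids <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  labs <- sort(unique(labels))
  centroids <- t(vapply(labs, function(l) {
    colMeans(points[labels == l, , drop = FALSE])
  }, numeric(ncol(points))))
  within <- vapply(labs, function(l) {
    pts <- points[labels == l, , drop = FALSE]
    mean(sqrt(rowSums((pts - matrix(centroids[l, ], nrow(pts), ncol(pts),
                                    byrow = TRUE))^2)))
  }, 0)
  list(centroids = centroids, within_distance = within)
}

#' Pairwise distances between cluster centroids
#'
#' @param centroids Labels x d centroid matrix (from
#'   [cluster_centroids()]).
#' @return Symmetric matrix of Euclidean distances with zero diagonal.
#' @export
centroid_distance_matrix <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stop_validation("need at least 2 centroids")
  as.matrix(stats::dist(centroids))
}

#' Assumption-gated test of a PC against group labels
#'
#' Tests whether one ancestry PC differs across groups. The parametric
#' route (one-way ANOVA) is used only when its assumptions hold:
#' Shapiro-Wilk on the one-way-fit residuals for normality and Levene's
#' test (median-centered) for variance homogeneity, both at
#' `alpha_assume`; otherwise the Kruskal-Wallis rank test is used. Groups
#' with fewer than 3 members are excluded (logged) because the assumption
#' tests need within-group replication.
#'
#' @param pc_scores Numeric vector, one value per sample.
#' @param labels Group label per sample.
#' @param alpha_assume Significance level for the assumption checks.
#'   Default 0.05.
#' @return List of class `association_result`: `test_used` ("anova" or
#'   "kruskal_wallis"), `statistic`, `p_value`, `assumption_notes` (the
#'   two assumption-test p-values).
#' @export
pc_group_association <- function(pc_scores, labels, alpha_assume = 0.05) {
  labels <- as.character(labels)
  stopifnot(length(pc_scores) == length(labels))
  tab <- table(labels)
  small <- names(tab)[tab < 3]
  if (length(small)) {
    msg("group(s) with < 3 members excluded from association test: ",
        paste(small, collapse = ", "))
    keep <- !(labels %in% small)
    pc_scores <- pc_scores[keep]; labels <- labels[keep]
  }
  if (length(unique(labels)) < 2) {
    stop_validation("fewer than 2 usable groups for association testing")
  }
  g <- factor(labels)
  fit <- aov(pc_scores ~ g)
  res <- residuals(fit)
  if (sd(res) == 0 || sd(pc_scores) == 0) {
    stop_validation("degenerate (zero-variance) data; assumption tests undefined")
  }
  p_norm <- shapiro.test(res)$p.value
  p_var <- car::leveneTest(pc_scores ~ g)[1, "Pr(>F)"]  # center = median
  if (p_norm > alpha_assume && p_var > alpha_assume) {
    tab_aov <- summary(fit)[[1]]
    out <- list(test_used = "anova",
                statistic = tab_aov[1, "F value"],
                p_value = tab_aov[1, "Pr(>F)"])
  } else {
    kw <- kruskal.test(pc_scores, g)
    out <- list(test_used = "kruskal_wallis",
                statistic = unname(kw$statistic),
                p_value = kw$p.value)
  }
  out$assumption_notes <- list(normality_p = p_norm, variance_homogeneity_p = p_var)
  class(out) <- "association_result"
  out
}

#' Absolute correlation grid between ancestry and genotyping PCs
#'
#' `grid[i, j] = |Pearson r(ancestry PC i, genotyping PC j)|` over the
#' first three PCs of each, plus the mean of the defined cells. Constant
#' columns yield undefined cells (`NA`, excluded from the mean, with a
#' warning).
#'
#' @param ancestry_pcs Samples x 3 matrix of ancestry PC scores.
#' @param geno_pcs Samples x 3 matrix of genotyping PC scores (same
#'   samples, same order).
#' @return List with `grid` (3 x 3) and `mean`.
#' @export
pc_genotype_correlation <- function(ancestry_pcs, geno_pcs) {
  a <- as.matrix(ancestry_pcs)[, 1:3, drop = FALSE]
  g <- as.matrix(geno_pcs)[, 1:3, drop = FALSE]
  if (nrow(a) != nrow(g)) stop_validation("sample mismatch")
  grid <- matrix(NA_real_, 3, 3,
                 dimnames = list(paste0("PC", 1:3), paste0("gt_PC", 1:3)))
  for (i in 1:3) for (j in 1:3) {
    if (sd(a[, i]) == 0 || sd(g[, j]) == 0) next
    grid[i, j] <- abs(cor(a[, i], g[, j]))
  }
  if (anyNA(grid)) warning("constant column(s); undefined correlation cells excluded from mean")
  list(grid = grid, mean = mean(grid, na.rm = TRUE))
}

#' Mixed-model likelihood-ratio test of a group effect
#'
#' For outcomes measured on cohorts with repeated samples per individual
#' (e.g. a control-probe PC or a cell-proportion PC), tests the ancestry
#' group effect with a random-intercept model: full model
#' `outcome ~ group + (1 | individual)` versus null
#' `outcome ~ (1 | individual)`, both fit by maximum likelihood, compared
#' by a likelihood-ratio test against chi-squared with
#' `(number of groups - 1)` degrees of freedom. Without any repeated
#' samples the random intercept is unidentifiable and the function falls
#' back to the fixed-effects ANOVA path with a warning.
#'
#' @param outcome Numeric vector, one value per sample.
#' @param group Group label per sample.
#' @param individual Individual id per sample (repeats share an id).
#' @return An `association_result` with `test_used = "lrt_mixed"` (or the
#'   fallback's own tag).
#' @export
mixed_model_group_lrt <- function(outcome, group, individual) {
  group <- factor(as.character(group))
  individual <- as.character(individual)
  stopifnot(length(outcome) == length(group), length(outcome) == length(individual))
  if (nlevels(group) < 2) {
    # full model is the null model: no evidence either way
    out <- list(test_used = "lrt_mixed", statistic = 0, p_value = 1,
                assumption_notes = list(df = 0))
    class(out) <- "association_result"
    return(out)
  }
  if (!any(duplicated(individual))) {
    warning("no repeated samples; falling back to the fixed-effects test")
    return(pc_group_association(outcome, as.character(group)))
  }
  dat <- data.frame(y = outcome, g = group, ind = individual)
  full <- tryCatch(
    suppressMessages(lme4::lmer(y ~ g + (1 | ind), data = dat, REML = FALSE)),
    error = function(e) stop_validation("mixed-model fit failed: ", conditionMessage(e)))
  null <- tryCatch(
    suppressMessages(lme4::lmer(y ~ (1 | ind), data = dat, REML = FALSE)),
    error = function(e) stop_validation("null mixed-model fit failed: ", conditionMessage(e)))
  lrt <- as.numeric(2 * (logLik(full) - logLik(null)))
  if (lrt < -1e-6) stop_validation("negative LRT statistic (", lrt, "); fit did not converge")
  lrt <- max(lrt, 0)
  df <- nlevels(group) - 1
  out <- list(test_used = "lrt_mixed",
              statistic = lrt,
              p_value = pchisq(lrt, df = df, lower.tail = FALSE),
              assumption_notes = list(df = df))
  class(out) <- "association_result"
  out
}

#' Multiple correlation of a score with a categorical grouping
#'
#' The correlation ratio: square root of the R-squared of a one-way fit of
#' the score on the group factor. Equals the absolute Pearson correlation
#' with the best numeric coding of the groups, so it measures group
#' association without depending on an arbitrary group ordering.
#'
#' @param x Numeric vector.
#' @param group Group label per observation.
#' @return Value in `[0, 1]`.
#' @export
group_correlation <- function(x, group) {
  g <- factor(as.character(group))
  if (nlevels(g) < 2 || sd(x) == 0) return(0)
  sqrt(summary(lm(x ~ g))$r.squared)
}

#' Evaluate ancestry-PC methods against known structure
#'
#' Assembles the comparison battery for one or more ancestry-PC results on
#' the same cohort, all computed on the first three scaled PCs: mean and
#' per-sample silhouettes over ancestry groups, per-group centroids with
#' within-group mean distances, the between-centroid distance matrix,
#' assumption-gated association tests for PCs 1-3, the absolute
#' correlation grid against genotyping PCs (when supplied), and
#' repeated-sample clustering (silhouette over individuals with more than
#' one sample plus mean distance to the individual centroid, when repeats
#' exist).
#'
#' @param pcs_by_method Named list of `ancestry_pcs` objects (same cohort).
#' @param sheet Sample sheet with `sample_id`, `individual_id` and an
#'   `ancestry_label` column.
#' @param geno_pcs Optional samples x 3 genotyping-PC matrix.
#' @param n_dims Number of leading scaled PCs used for the geometric
#'   metrics. Default 3.
#' @return Nested list of class `eval_report`, one entry per method.
#' @export
evaluate_methods <- function(pcs_by_method, sheet, geno_pcs = NULL, n_dims = 3) {
  stopifnot(length(pcs_by_method) >= 1)
  ids <- as.character(sheet$sample_id)
  labels <- as.character(sheet$ancestry_label)
  has_repeats <- any(duplicated(sheet$individual_id))
  report <- list()
  for (tag in names(pcs_by_method)) {
    pcs <- pcs_by_method[[tag]]
    stopifnot(identical(pcs$sample_ids, ids))
    pts <- pcs$scores[, seq_len(min(n_dims, ncol(pcs$scores))), drop = FALSE]
    sil <- silhouette_scores(pts, labels)
    cen <- cluster_centroids(pts, labels)
    entry <- list(
      silhouette_mean = sil$mean,
      silhouette = sil$scores,
      centroids = cen$centroids,
      within_distance = cen$within_distance,
      centroid_distances = centroid_distance_matrix(cen$centroids),
      associations = lapply(seq_len(min(3, ncol(pcs$scores))), function(j) {
        tryCatch(pc_group_association(pcs$scores[, j], labels),
                 error = function(e) NULL)
      })
    )
    if (!is.null(geno_pcs)) {
      entry$genotype_correlation <- pc_genotype_correlation(pcs$scores[, 1:3], geno_pcs)
    }
    if (has_repeats) {
      rep_ind <- names(which(table(sheet$individual_id) > 1))
      sel <- sheet$individual_id %in% rep_ind
      rep_pts <- pts[sel, , drop = FALSE]
      rep_lab <- as.character(sheet$individual_id[sel])
      rep_cen <- cluster_centroids(rep_pts, rep_lab)
      entry$repeated <- list(
        silhouette_mean = silhouette_scores(rep_pts, rep_lab)$mean,
        mean_distance_to_centroid = mean(rep_cen$within_distance)
      )
    }
    report[[tag]] <- entry
  }
  class(report) <- "eval_report"
  report
}

#' Write an evaluation report
#'
#' Writes `report.json` plus flat TSVs (`silhouettes.tsv`,
#' `centroid_distances.tsv`, `associations.tsv`, `correlations.tsv`) into
#' a directory.
#'
#' @param report An [evaluate_methods()] result.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report_to_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sil <- do.call(rbind, lapply(names(report), function(tag) {
    data.frame(method = tag, sample_id = names(report[[tag]]$silhouette),
               silhouette = unname(report[[tag]]$silhouette))
  }))
  write_sample_table(sil, file.path(dir, "silhouettes.tsv"))
  cd <- do.call(rbind, lapply(names(report), function(tag) {
    m <- report[[tag]]$centroid_distances
    data.frame(method = tag, from = rep(rownames(m), ncol(m)),
               to = rep(colnames(m), each = nrow(m)), distance = as.vector(m))
  }))
  write_sample_table(cd, file.path(dir, "centroid_distances.tsv"))
  assoc <- do.call(rbind, lapply(names(report), function(tag) {
    rows <- lapply(seq_along(report[[tag]]$associations), function(j) {
      a <- report[[tag]]$associations[[j]]
      if (is.null(a)) return(NULL)
      data.frame(method = tag, pc = j, test = a$test_used,
                 statistic = a$statistic, p_value = a$p_value)
    })
    do.call(rbind, rows)
  }))
  if (!is.null(assoc)) write_sample_table(assoc, file.path(dir, "associations.tsv"))
  cors <- do.call(rbind, lapply(names(report), function(tag) {
    gc <- report[[tag]]$genotype_correlation
    if (is.null(gc)) return(NULL)
    data.frame(method = tag,
               ancestry_pc = rep(rownames(gc$grid), 3),
               geno_pc = rep(colnames(gc$grid), each = 3),
               abs_r = as.vector(gc$grid))
  }))
  if (!is.null(cors)) write_sample_table(cors, file.path(dir, "correlations.tsv"))
  invisible(dir)
}

# strip classes / convert matrices so jsonlite serializes cleanly
report_to_json <- function(x) {
  if (inherits(x, "association_result")) x <- unclass(x)
  if (is.matrix(x)) {
    return(lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])))
  }
  if (is.list(x)) return(lapply(unclass(x), report_to_json))
  x
}
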