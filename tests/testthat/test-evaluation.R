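test_that("silhouette matches hand-computed and brute-force values", {
  pts <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c("A", "A", "B", "B")
  sil <- silhouette_scores(pts, lab)
  # point 1: a = 0.1, b = mean(10, 10.1) = 10.05 -> (10.05 - 0.1)/10.05
  expect_equal(unname(sil$scores[1]), (10.05 - 0.1) / 10.05)
  expect_equal(sil$mean, 0.99, tolerance = 1e-6)

  same <- matrix(1, 6, 3)
  expect_equal(silhouette_scores(same, rep(c("A", "B"), 3))$scores, rep(0, 6),
               ignore_attr = TRUE)

  # singleton cluster scores zero by convention
  s3 <- silhouette_scores(matrix(c(0, 1, 5), 3, 1), c("A", "A", "B"))
  expect_equal(unname(s3$scores[3]), 0)

  expect_error(silhouette_scores(pts, rep("A", 4)), "single cluster",
               class = "epiance_validation_error")

  set.seed(14)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    k <- sample(2:3, 1)
    pts <- matrix(rnorm(n * 3), n, 3)
    lab <- as.character(sample(k, n, replace = TRUE))
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_scores(pts, lab)$scores,
                 silhouette_oracle(pts, lab), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package on generic instances", {
  skip_if_not_installed("cluster")
  set.seed(15)
  pts <- matrix(rnorm(60), 20, 3)
  lab <- sample(1:3, 20, replace = TRUE)
  ours <- silhouette_scores(pts, as.character(lab))$scores
  ref <- cluster::silhouette(lab, dist(pts))[, "sil_width"]
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("centroids, within-cluster density and centroid distances", {
  pts <- matrix(c(0, 2, 3, 0, 0, 4, 0, 0, 0), 3, 3)
  cen <- cluster_centroids(pts, c("A", "A", "B"))
  expect_equal(unname(cen$centroids["A", ]), c(1, 0, 0))
  expect_equal(unname(cen$within_distance["A"]), 1)
  expect_equal(unname(cen$within_distance["B"]), 0)  # singleton

  dm <- centroid_distance_matrix(rbind(a = c(0, 0, 0), b = c(3, 4, 0)))
  expect_equal(unname(dm["a", "b"]), 5)
  expect_equal(unname(diag(dm)), c(0, 0))
  expect_equal(dm, t(dm))

  set.seed(16)
  for (i in 1:10) {
    cs <- matrix(rnorm(9), 3, 3, dimnames = list(c("x", "y", "z"), NULL))
    m <- centroid_distance_matrix(cs)
    expect_lte(m["x", "z"], m["x", "y"] + m["y", "z"] + 1e-12)
  }
})

test_that("group association gates ANOVA on normality and homogeneity", {
  set.seed(17)
  x <- c(rnorm(20), rnorm(20, 10))
  g <- rep(c("a", "b"), each = 20)
  res <- pc_group_association(x, g)
  expect_equal(res$test_used, "anova")
  expect_lt(res$p_value, 1e-6)
  # statistic agrees with the stock one-way ANOVA
  expect_equal(res$statistic, anova(lm(x ~ factor(g)))[1, "F value"])

  skewed <- c(rexp(30, 1), rexp(30, 1) + 3)
  gs <- rep(c("a", "b"), each = 30)
  res2 <- pc_group_association(skewed, gs)
  expect_equal(res2$test_used, "kruskal_wallis")
  expect_lt(res2$assumption_notes$normality_p, 0.05)
  expect_equal(res2$statistic, unname(kruskal.test(skewed, factor(gs))$statistic))

  # relabeling the groups changes nothing
  res3 <- pc_group_association(x, c(a = "zebra", b = "ant")[g])
  expect_equal(res3$p_value, res$p_value)

  expect_error(pc_group_association(rep(1, 10), rep(c("a", "b"), 5)),
               "degenerate", class = "epiance_validation_error")
  expect_error(suppressMessages(
    pc_group_association(rnorm(4), c("a", "a", "a", "b"))),
    "fewer than 2", class = "epiance_validation_error")
})

test_that("tiny groups are excluded before association testing", {
  set.seed(18)
  x <- c(rnorm(10), rnorm(10, 5), 99)
  g <- c(rep("a", 10), rep("b", 10), "stray")
  res <- suppressMessages(pc_group_association(x, g))
  expect_lt(res$p_value, 1e-4)
})

test_that("genotype-PC correlation grid uses absolute values", {
  set.seed(19)
  a <- matrix(rnorm(300), 100, 3)
  expect_equal(unname(diag(pc_genotype_correlation(a, a)$grid)), rep(1, 3))
  expect_equal(unname(diag(pc_genotype_correlation(a, -a)$grid)), rep(1, 3))

  b <- matrix(rnorm(300), 100, 3)
  g <- pc_genotype_correlation(a, b)
  expect_lt(max(g$grid), 3 / sqrt(100) + 0.1)

  ac <- a; ac[, 2] <- 1
  expect_warning(gc <- pc_genotype_correlation(ac, b), "constant")
  expect_true(all(is.na(gc$grid[2, ])))
  expect_false(is.na(gc$mean))
})

test_that("mixed-model LRT detects group shifts and degenerates gracefully", {
  set.seed(20)
  ind <- rep(1:30, each = 2)
  g <- rep(rep(c("a", "b"), each = 15), each = 2)
  y_null <- rnorm(30)[ind] + rnorm(60)
  r0 <- mixed_model_group_lrt(y_null, g, ind)
  expect_equal(r0$test_used, "lrt_mixed")
  expect_gte(r0$statistic, 0)
  expect_true(r0$p_value >= 0 && r0$p_value <= 1)

  y_shift <- y_null + 5 * (g == "b")
  expect_lt(mixed_model_group_lrt(y_shift, g, ind)$p_value, 1e-3)

  # single group level: full model == null model
  r1 <- mixed_model_group_lrt(y_null, rep("a", 60), ind)
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_value, 1)

  expect_warning(r2 <- mixed_model_group_lrt(y_null, g, seq_along(y_null)),
                 "no repeated")
  expect_true(r2$test_used %in% c("anova", "kruskal_wallis"))
})

test_that("the evaluation report assembles per-method sections conditionally", {
  co <- simulate_cohort(tiny_config(seed = 22))
  res <- suppressMessages(run_pipeline(co, pipeline_config(k = 3)))
  rep_full <- suppressMessages(
    evaluate_methods(res$pcs, co$sheet, geno_pcs = co$truth$geno_pcs))
  expect_s3_class(rep_full, "eval_report")
  expect_named(rep_full, c("EpiAncOrig", "EpiAnceR", "EpiAnceRplus"))
  for (m in names(rep_full)) {
    e <- rep_full[[m]]
    expect_true(is.numeric(e$silhouette_mean))
    expect_true(all(abs(e$silhouette) <= 1))
    expect_equal(e$centroid_distances, t(e$centroid_distances))
    expect_equal(unname(diag(e$centroid_distances)), rep(0, 3))
    expect_false(is.null(e$genotype_correlation))
    expect_false(is.null(e$repeated))
  }

  # no repeats, no genotyping PCs: sections absent
  co2 <- simulate_cohort(tiny_config(seed = 23, repeat_fraction = 0))
  res2 <- suppressMessages(run_pipeline(
    co2, pipeline_config(k = 3, methods = "EpiAncOrig")))
  rep2 <- suppressMessages(evaluate_methods(res2$pcs, co2$sheet))
  expect_null(rep2$EpiAncOrig$repeated)
  expect_null(rep2$EpiAncOrig$genotype_correlation)

  out <- tempfile()
  write_eval_report(rep_full, out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "silhouettes.tsv")))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$EpiAncOrig$silhouette_mean,
               rep_full$EpiAncOrig$silhouette_mean)
})

test_that("group correlation reduces to |Pearson r| for two balanced groups", {
  set.seed(24)
  g <- rep(c("a", "b"), each = 25)
  x <- rnorm(50) + 2 * (g == "b")
  expect_equal(group_correlation(x, g), abs(cor(x, as.numeric(g == "b"))))
  expect_equal(group_correlation(rep(1, 10), rep(c("a", "b"), 5)), 0)
})
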