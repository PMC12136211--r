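test_that("background correction subtracts the 5th control percentile and floors", {
  meth <- named_matrix(c(500, 50, 120, 300), 2, 2)
  unmeth <- named_matrix(c(200, 400, 90, 150), 2, 2)
  # constant negative controls: background is exactly that constant
  sig <- make_signals(meth, unmeth)
  sig$neg_controls <- lapply(sig$neg_controls, function(x)
    list(grn = rep(100, 10), red = rep(100, 10)))
  out <- background_correct(sig)
  expect_equal(unname(out$meth[1, 1]), 400)   # 500 - 100
  expect_equal(unname(out$meth[2, 1]), 1)     # 50 - 100 floored
  expect_equal(unname(out$unmeth[1, 1]), 100)

  # type-I probes subtract their own channel on both alleles
  chan <- setNames(c("grn", "red"), rownames(meth))
  sig2 <- make_signals(meth, unmeth, channels = chan)
  sig2$neg_controls <- lapply(sig2$neg_controls, function(x)
    list(grn = rep(100, 10), red = rep(40, 10)))
  out2 <- background_correct(sig2)
  expect_equal(unname(out2$unmeth[1, 1]), 100)  # grn probe: 200 - 100
  expect_equal(unname(out2$unmeth[2, 1]), 360)  # red probe: 400 - 40

  sig$neg_controls[[1]]$grn <- numeric(0)
  expect_error(background_correct(sig), "negative-control",
               class = "epiance_validation_error")
})

test_that("detection p is the upper normal tail of total signal vs background", {
  # controls with mean 100, sd 10 (constructed exactly)
  nc_vals <- c(100 - 10 * sqrt(0.5), 100 + 10 * sqrt(0.5))
  totals <- c(100, 1e6, 119.6)
  meth <- named_matrix(totals / 2, 3, 1)
  unmeth <- named_matrix(totals / 2, 3, 1)
  # all probes type-I green so the background is exactly the grn controls
  sig <- make_signals(meth, unmeth,
                      channels = setNames(rep("grn", 3), rownames(meth)))
  sig$neg_controls <- list(s1 = list(grn = nc_vals, red = nc_vals))
  p <- detection_pvalues(sig)
  expect_equal(unname(p[1, 1]), 0.5)                       # at the mean
  expect_lt(p[2, 1], 1e-300)                                # far tail
  expect_equal(unname(p[3, 1]),
               pnorm(119.6, 100, 10, lower.tail = FALSE))   # z = 1.96
  expect_equal(unname(p[3, 1]), 0.025, tolerance = 1e-2)

  sig$neg_controls$s1$grn <- 100
  expect_error(detection_pvalues(sig), "at least 2",
               class = "epiance_validation_error")
})

test_that("type-I probes use their own channel's background distribution", {
  meth <- named_matrix(c(60, 60), 2, 1)
  unmeth <- named_matrix(c(60, 60), 2, 1)
  chan <- setNames(c("grn", "red"), rownames(meth))
  sig <- make_signals(meth, unmeth, channels = chan)
  sig$neg_controls <- list(s1 = list(grn = c(90, 110), red = c(490, 510)))
  p <- detection_pvalues(sig)
  expect_lt(p[1, 1], 0.5)   # total 120 vs grn mean 100
  expect_gt(p[2, 1], 0.99)  # total 120 vs red mean 500
})

test_that("masking respects the threshold and is monotone in it", {
  x <- named_matrix(runif(12), 3, 4)
  p <- named_matrix(c(1e-17, 1e-10, rep(1e-20, 10)), 3, 4)
  masked <- mask_failed_detections(x, p, threshold = 1e-16)
  expect_false(is.na(masked[1, 1]))  # p below threshold: kept
  expect_true(is.na(masked[2, 1]))   # p above threshold: masked
  expect_false(anyNA(mask_failed_detections(x, p, threshold = 1)))

  set.seed(42)
  pr <- named_matrix(10^runif(60, -20, 0), 6, 10)
  xr <- named_matrix(runif(60), 6, 10)
  loose <- is.na(mask_failed_detections(xr, pr, threshold = 1e-8))
  tight <- is.na(mask_failed_detections(xr, pr, threshold = 1e-12))
  expect_true(all(tight[loose]))  # lowering the threshold never unmasks

  expect_error(mask_failed_detections(xr[1:3, ], pr), "shape",
               class = "epiance_validation_error")
})

test_that("probe QC counts low-bead and missing fractions with strict bounds", {
  n <- 100
  miss <- matrix(FALSE, 4, n, dimnames = list(paste0("cg", 1:4), NULL))
  bead <- matrix(10L, 4, n, dimnames = dimnames(miss))
  bead[1, 1:6] <- 2L   # 6% low bead -> excluded
  bead[2, 1:5] <- 2L   # 5% is not > 5% -> retained
  miss[3, 1:11] <- TRUE  # 11% missing -> excluded
  miss[4, 1:10] <- TRUE  # 10% is not > 10% -> retained
  expect_identical(suppressMessages(filter_probes_qc(miss, bead)),
                   c("cg2", "cg4"))
  expect_error(filter_probes_qc(miss[, 0], bead[, 0]), "zero samples",
               class = "epiance_validation_error")
})

test_that("quantile normalization equalizes distributions and keeps ranks", {
  x <- named_matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(unname(quantile_normalize(x)),
               matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  same <- named_matrix(rep(c(5, 1, 3), 4), 3, 4)
  expect_equal(quantile_normalize(same), same)

  set.seed(7)
  y <- named_matrix(rnorm(200), 20, 10)
  qy <- quantile_normalize(y)
  expect_equal(qy, qn_oracle(y), ignore_attr = TRUE)  # order-statistics oracle
  sorted <- apply(qy, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))  # identical multisets
  for (j in 1:10) expect_equal(rank(qy[, j]), rank(y[, j]))

  # missing values stay missing and do not disturb observed ranks
  y[3, 2] <- NA
  qy2 <- quantile_normalize(y)
  expect_true(is.na(qy2[3, 2]))
  obs <- !is.na(y[, 2])
  expect_equal(rank(qy2[obs, 2]), rank(y[obs, 2]))

  y[, 4] <- NA
  expect_error(quantile_normalize(y), "entirely missing",
               class = "epiance_validation_error")
  expect_error(quantile_normalize(y[, 1, drop = FALSE]), ">= 2 samples",
               class = "epiance_validation_error")
})

test_that("beta values follow M / (M + U + offset) and stay in [0, 1]", {
  m <- named_matrix(c(1000, 0, 200), 3, 1)
  u <- named_matrix(c(1000, 0, 0), 3, 1)
  b <- compute_beta(m, u)
  expect_equal(unname(b[, 1]), c(1000 / 2100, 0, 200 / 300))

  set.seed(3)
  mm <- named_matrix(rexp(50, 1 / 1000), 10, 5)
  uu <- named_matrix(rexp(50, 1 / 1000), 10, 5)
  bb <- compute_beta(mm, uu)
  expect_true(all(bb >= 0 & bb <= 1))
  expect_error(compute_beta(-mm, uu), "negative",
               class = "epiance_validation_error")
})

test_that("k-NN imputation matches the exhaustive oracle and its conventions", {
  full <- named_matrix(runif(24), 4, 6)
  expect_identical(impute_knn(full), full)  # nothing to do

  # a probe identical to a complete twin gets the twin's value (k = 1)
  twin <- named_matrix(0, 3, 4)
  twin[1, ] <- c(0.2, 0.4, 0.6, 0.8)
  twin[2, ] <- c(0.2, 0.4, 0.6, 0.8)
  twin[3, ] <- c(0.9, 0.1, 0.9, 0.1)
  twin[1, 3] <- NA
  expect_equal(unname(impute_knn(twin, k = 1)[1, 3]), 0.6)

  set.seed(11)
  beta <- named_matrix(runif(60), 10, 6)
  beta[cbind(c(2, 5, 9), c(1, 4, 6))] <- NA
  expect_equal(impute_knn(beta, k = 2), knn_oracle(beta, k = 2))
  expect_false(anyNA(impute_knn(beta, k = 2)))

  # fewer probes than k + 1: row-mean fallback
  small <- named_matrix(c(0.1, 0.5, 0.9, NA, 0.2, 0.4), 2, 3)
  out <- impute_knn(small, k = 5)
  expect_equal(unname(out[2, 2]), mean(c(0.5, 0.4)))  # row mean of observed

  none <- named_matrix(NA_real_, 2, 3)
  none[2, ] <- 0.5
  expect_error(impute_knn(none), "zero observed",
               class = "epiance_validation_error")
})

test_that("preprocessing chain is deterministic", {
  co <- simulate_cohort(tiny_config(seed = 5))
  run_once <- function() {
    sig <- background_correct(co$signals)
    p <- detection_pvalues(co$signals)
    sig <- suppressMessages(mask_failed_detections(sig, p))
    compute_beta(quantile_normalize(sig$meth), quantile_normalize(sig$unmeth))
  }
  expect_identical(run_once(), run_once())
})
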