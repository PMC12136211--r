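#' Pipeline configuration
#'
#' Collects every threshold the end-to-end pipeline applies, with the
#' published defaults: detection p-value threshold `1e-16` (use `1e-15`
#' for the laxer reading of the same printed value), SNP minor allele
#' frequency at least 0.05 with exact overlap, probes dropped when more
#' than 5% of samples have bead counts below 3 or more than 10% of
#' samples are missing, genotype thresholds 0.25/0.75, ten control-probe
#' PCs, k = 10 ancestry PCs.
#'
#' @param detection_threshold Detection p-value threshold.
#' @param maf_min Minimum minor allele frequency for SNP-overlapping CpGs.
#' @param bead_min,bead_frac,miss_frac Probe QC thresholds (see
#'   [filter_probes_qc()]).
#' @param geno_low,geno_high Genotype-calling beta thresholds.
#' @param n_control_pcs Number of control-probe PCs in the design.
#' @param k Number of ancestry PCs returned.
#' @param offset Beta offset (AU).
#' @param impute_k Neighbours for k-NN imputation.
#' @param methods Which PC variants to compute; any of `"EpiAncOrig"`
#'   (PCA on raw betas), `"EpiAnceR"` (residualized), `"EpiAnceRplus"`
#'   (residualized + genotype calls).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(detection_threshold = 1e-16, maf_min = 0.05,
                            bead_min = 3, bead_frac = 0.05, miss_frac = 0.10,
                            geno_low = 0.25, geno_high = 0.75,
                            n_control_pcs = 10, k = 10, offset = 100,
                            impute_k = 5,
                            methods = c("EpiAncOrig", "EpiAnceR", "EpiAnceRplus")) {
  cfg <- as.list(environment())
  stopifnot(cfg$detection_threshold > 0, cfg$detection_threshold <= 1,
            cfg$maf_min >= 0, cfg$maf_min <= 0.5,
            cfg$bead_frac >= 0, cfg$bead_frac <= 1,
            cfg$miss_frac >= 0, cfg$miss_frac <= 1,
            cfg$geno_low < cfg$geno_high,
            cfg$n_control_pcs >= 0, cfg$k >= 1, cfg$offset >= 0)
  bad <- setdiff(cfg$methods, c("EpiAncOrig", "EpiAnceR", "EpiAnceRplus"))
  if (length(bad)) stop_validation("unknown method(s): ", paste(bad, collapse = ", "))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full ancestry-PC pipeline
#'
#' Executes, in order: probe selection from the annotation (SNP-overlap +
#' MAF rule, rs probes), detection p-values on raw signals, background
#' correction, masking of failed detections, bead-count / call-rate probe
#' QC, quantile normalization of methylated and unmethylated intensities
#' (SNP-overlapping and rs probes jointly), beta computation, k-NN
#' imputation, covariate construction (control-probe PCs, cell-proportion
#' PCs, sex, age), residualization, rs genotype calling, feature
#' combination, and PCA for each requested method.
#'
#' @param x A [simulate_cohort()] result, a directory written by
#'   [write_cohort()], or a list with elements `signals`, `annotation`,
#'   `sheet`, `cell_props`, `control_probes`.
#' @param config A [pipeline_config()].
#' @param detection_p Optional pre-computed detection p-value matrix (same
#'   layout as the signals), skipping the detection stage.
#' @param out_dir Optional directory; when given, per-method PC and
#'   variance tables plus a provenance log are written there.
#' @return A list of class `pipeline_result`: `pcs` (named list of
#'   `ancestry_pcs`), `beta` (imputed beta matrix for the retained
#'   probes), `genotypes`, `design`, and `log` (probe counts at each
#'   stage and every threshold applied).
#' @export
run_pipeline <- function(x, config = pipeline_config(), detection_p = NULL,
                         out_dir = NULL) {
  if (is.character(x) && length(x) == 1L) x <- read_cohort(x)
  stopifnot(is.list(x),
            all(c("signals", "annotation", "sheet", "cell_props",
                  "control_probes") %in% names(x)))
  stopifnot(inherits(config, "pipeline_config"))
  signals <- x$signals
  ann <- x$annotation
  sheet <- x$sheet
  log <- list(thresholds = unclass(config))

  ## probe selection ---------------------------------------------------------
  snp0bp <- select_snp0bp(ann, maf_min = config$maf_min)
  rs_ids <- suppressWarnings(select_rs_probes(ann))
  selected <- c(snp0bp, rs_ids)
  selected <- selected[selected %in% rownames(signals$meth)]
  log$n_probes_annotation <- nrow(ann)
  log$n_snp0bp_selected <- length(snp0bp)
  log$n_rs_selected <- length(rs_ids)
  if (!length(snp0bp)) stop_validation("probe selection: no SNP-overlapping probes selected")

  ## detection p on raw signals, then background correction ------------------
  sel_signals <- subset_probes(signals, selected)
  if (is.null(detection_p)) {
    detection_p <- detection_pvalues(sel_signals)
  } else {
    detection_p <- detection_p[selected, colnames(sel_signals$meth), drop = FALSE]
  }
  sel_signals <- background_correct(sel_signals)
  sel_signals <- mask_failed_detections(sel_signals, detection_p,
                                        threshold = config$detection_threshold)

  ## probe QC ----------------------------------------------------------------
  miss <- is.na(sel_signals$meth)
  retained <- filter_probes_qc(miss, sel_signals$bead_counts,
                               bead_min = config$bead_min,
                               bead_frac = config$bead_frac,
                               miss_frac = config$miss_frac)
  log$n_probes_after_qc <- length(retained)
  if (!length(retained)) stop_validation("probe QC: all probes removed")
  sel_signals <- subset_probes(sel_signals, retained)

  ## normalization, beta, imputation -----------------------------------------
  meth_n <- quantile_normalize(sel_signals$meth)
  unmeth_n <- quantile_normalize(sel_signals$unmeth)
  beta <- compute_beta(meth_n, unmeth_n, offset = config$offset)
  log$n_missing_before_impute <- sum(is.na(beta))
  beta <- impute_knn(beta, k = config$impute_k)

  snp_keep <- intersect(retained, snp0bp)
  rs_keep <- intersect(retained, rs_ids)
  log$n_snp0bp_after_qc <- length(snp_keep)
  log$n_rs_after_qc <- length(rs_keep)
  beta_snp <- beta[snp_keep, , drop = FALSE]
  beta_rs <- beta[rs_keep, , drop = FALSE]

  ## covariates and residualization ------------------------------------------
  ids <- as.character(sheet$sample_id)
  stopifnot(identical(colnames(beta), ids))
  ctrl <- x$control_probes[ids, , drop = FALSE]
  cellp <- x$cell_props[ids, , drop = FALSE]
  ctrl_pcs <- control_probe_pcs(ctrl, n_pcs = config$n_control_pcs)
  cell_pcs <- cell_proportion_pcs(cellp)
  design <- build_design(sheet, cell_pcs, ctrl_pcs)

  need_resid <- any(config$methods %in% c("EpiAnceR", "EpiAnceRplus"))
  residuals <- if (need_resid) residualize(beta_snp, design) else NULL
  genotypes <- if (length(rs_keep)) {
    call_rs_genotypes(beta_rs, low = config$geno_low, high = config$geno_high)
  } else matrix(0, 0, length(ids))

  ## PCA per method ----------------------------------------------------------
  pcs <- list()
  for (m in config$methods) {
    pcs[[m]] <- switch(
      m,
      EpiAncOrig = epianc_orig_pcs(beta_snp, k = config$k),
      EpiAnceR = ancestry_pca(residuals - rowMeans(residuals), k = config$k,
                              method_tag = "EpiAnceR"),
      EpiAnceRplus = {
        feats <- if (nrow(genotypes)) combine_features(residuals, genotypes)
        else suppressWarnings(combine_features(residuals,
                                               matrix(0, 0, length(ids))))
        ancestry_pca(feats, k = config$k, method_tag = "EpiAnceRplus")
      })
  }

  result <- structure(list(pcs = pcs, beta = beta, genotypes = genotypes,
                           design = design, log = log),
                      class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(pcs)) write_ancestry_pcs(pcs[[m]], out_dir)
    write_matrix_tsv(beta, file.path(out_dir, "beta.tsv"))
    writeLines(retained, file.path(out_dir, "retained_probes.txt"))
    jsonlite::write_json(log, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", x$log$n_snp0bp_after_qc, "SNP-overlap probes +",
      x$log$n_rs_after_qc, "rs probes after QC\n")
  for (m in names(x$pcs)) print(x$pcs[[m]])
  invisible(x)
}
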