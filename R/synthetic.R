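#' Configuration for a synthetic methylation cohort
#'
#' Defines the study conditions for [simulate_cohort()]: ancestry groups
#' with Balding-Nichols allele-frequency divergence, genotype-driven
#' trimodal betas at SNP-overlapping and rs probes, batch effects entering
#' methylation and control probes through shared per-sample latent
#' factors, cell-type / sex / age effects, sporadic detection failures and
#' low bead counts, and repeated samples per individual.
#'
#' @param seed Integer RNG seed.
#' @param groups Named integer vector: individuals per ancestry group.
#' @param repeat_fraction Fraction of individuals contributing repeated
#'   samples. Default 0.2.
#' @param repeat_count Samples per repeated individual. Default 2.
#' @param fst Allele-frequency divergence between groups, in (0, 1).
#' @param n_snp0bp,n_rs,n_decoy Numbers of SNP-overlapping CpG probes,
#'   genotyping rs probes, and non-informative decoy CpG probes (present
#'   on the array but failing the SNP-overlap/MAF selection rules).
#' @param n_control Number of control probes. Default 200.
#' @param n_celltypes Number of cell types. Default 6 (blood-like).
#' @param n_batches Number of processing batches. Default 6.
#' @param batch_sd SD of per-probe batch loadings on the beta scale. rs
#'   probes get loadings shrunk by 10x: their betas are intensity ratios,
#'   so channel-level batch shifts largely cancel there.
#' @param cell_sd Scale of cell-composition effects on the beta scale.
#' @param sex_effect_sd,age_effect_sd SDs of per-probe sex (M vs F) and
#'   per-year age effects on the beta scale.
#' @param noise_sd Residual technical noise SD on the beta scale for
#'   SNP-overlapping probes; rs probes use `noise_sd / 2`.
#' @param genotype_means Mean beta for dosage 0 / 0.5 / 1.
#' @param detect_fail_rate Fraction of probe/sample entries forced below
#'   background so they fail detection.
#' @param low_bead_rate Fraction of entries with bead count below 3.
#' @param confounded If `TRUE`, batch membership, cell composition and sex
#'   ratio depend on ancestry group, emulating a non-randomized design in
#'   which residualization also removes ancestry signal.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       groups = c(AFR = 50, EAS = 50, EUR = 50),
                       repeat_fraction = 0.2,
                       repeat_count = 2,
                       fst = 0.1,
                       n_snp0bp = 500, n_rs = 50, n_decoy = 50,
                       n_control = 200, n_celltypes = 6, n_batches = 6,
                       batch_sd = 0.15, cell_sd = 0.1,
                       sex_effect_sd = 0.02, age_effect_sd = 0.002,
                       noise_sd = 0.1,
                       genotype_means = c(0.1, 0.5, 0.9),
                       detect_fail_rate = 0.002, low_bead_rate = 0.005,
                       confounded = FALSE) {
  cfg <- as.list(environment())
  if (length(cfg$groups) < 1 || any(cfg$groups < 1)) {
    stop_validation("need at least one group with at least one individual")
  }
  if (is.null(names(cfg$groups))) names(cfg$groups) <- paste0("G", seq_along(cfg$groups))
  stopifnot(cfg$fst > 0, cfg$fst < 1,
            cfg$repeat_fraction >= 0, cfg$repeat_fraction <= 1,
            cfg$detect_fail_rate >= 0, cfg$detect_fail_rate <= 1,
            cfg$low_bead_rate >= 0, cfg$low_bead_rate <= 1,
            cfg$n_snp0bp > 0, cfg$n_rs >= 0, cfg$n_control > 1,
            cfg$n_celltypes >= 2, cfg$n_batches >= 1,
            length(cfg$genotype_means) == 3)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw group allele frequencies (Balding-Nichols model)
#'
#' Each group's frequency is an independent draw from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, which has mean `p` and
#' variance `F p (1 - p)`: `F` is the divergence (FST) between groups.
#'
#' @param base_freq Ancestral allele frequency in (0, 1).
#' @param fst Divergence parameter in (0, 1).
#' @param n_groups Number of groups.
#' @return Numeric vector of length `n_groups`.
#' @export
draw_group_allele_freqs <- function(base_freq, fst, n_groups) {
  if (base_freq <= 0 || base_freq >= 1) stop_validation("base_freq must be in (0, 1)")
  if (fst <= 0 || fst >= 1) stop_validation("fst must be in (0, 1)")
  if (n_groups < 1) stop_validation("n_groups must be >= 1")
  scale <- (1 - fst) / fst
  rbeta(n_groups, base_freq * scale, (1 - base_freq) * scale)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Simulate a complete synthetic cohort
#'
#' Generates raw array data (signal intensities, bead counts, negative
#' controls), a sample sheet, cell proportions, a control-probe matrix and
#' a probe annotation table for a cohort with known ancestry structure,
#' plus the ground truth needed to score any downstream method.
#'
#' Generative model, per sample s and SNP site p: the individual's
#' genotype dosage is `Binomial(2, q_gp) / 2` with group frequencies `q`
#' from the Balding-Nichols model; the target beta is the trimodal
#' genotype mean plus a batch term (per-probe loading x per-sample latent
#' technical factor, shared with the control probes), cell-composition,
#' sex and age terms, and Gaussian noise, clipped to `[0.001, 0.999]`.
#' Betas are converted to methylated/unmethylated intensities through a
#' log-normal total intensity and the beta offset, and channel backgrounds
#' are added back so the preprocessing chain has real work to do. Repeated
#' samples reuse the individual's genotypes with fresh batch assignment,
#' cell proportions and technical noise.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort`: `signals` ([signal_set()] over
#'   SNP0bp + decoy + rs probes), `annotation`
#'   (`probe_annotation`), `sheet` (sample sheet `data.frame`),
#'   `cell_props`, `control_probes` (samples x control probes), and
#'   `truth` (group, numeric `group_code`, per-sample genotype matrices,
#'   `geno_pcs` computed from the true genotypes, batch assignments,
#'   latent technical factor).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  cfg <- config

  ## individuals and samples -------------------------------------------------
  n_ind <- sum(cfg$groups)
  ind_group <- rep(names(cfg$groups), cfg$groups)
  ind_ids <- sprintf("ind%04d", seq_len(n_ind))
  ind_sex <- sample(c("F", "M"), n_ind, replace = TRUE)
  if (cfg$confounded) {
    # unbalanced sex ratio per group
    p_male <- stats::setNames(seq(0.25, 0.75, length.out = length(cfg$groups)),
                              names(cfg$groups))
    ind_sex <- ifelse(runif(n_ind) < p_male[ind_group], "M", "F")
  }
  ind_age <- pmin(pmax(round(rnorm(n_ind, 35, 10)), 18), 70)
  if (cfg$confounded) {
    ind_age <- ind_age + as.integer(factor(ind_group)) * 4L
  }
  n_rep <- round(cfg$repeat_fraction * n_ind)
  rep_ind <- if (n_rep > 0) sample(ind_ids, n_rep) else character(0)
  samples_per_ind <- ifelse(ind_ids %in% rep_ind, cfg$repeat_count, 1L)
  sample_ind <- rep(ind_ids, samples_per_ind)
  n <- length(sample_ind)
  sample_ids <- sprintf("s%04d", seq_len(n))
  idx <- match(sample_ind, ind_ids)
  sheet <- data.frame(sample_id = sample_ids,
                      individual_id = sample_ind,
                      sex = ind_sex[idx],
                      age = ind_age[idx],
                      ancestry_label = ind_group[idx],
                      stringsAsFactors = FALSE)

  ## batch structure ---------------------------------------------------------
  if (cfg$confounded) {
    # groups concentrated in different batches
    grp_idx <- as.integer(factor(sheet$ancestry_label))
    batch <- ((grp_idx - 1 + rbinom(n, 1, 0.2)) %% cfg$n_batches) + 1L
  } else {
    batch <- sample.int(cfg$n_batches, n, replace = TRUE)
  }
  batch_center <- rnorm(cfg$n_batches)
  if (cfg$n_batches > 1) {
    # standardize so batch_sd alone controls the batch-effect magnitude
    batch_center <- (batch_center - mean(batch_center)) / sd(batch_center)
  }
  tech <- batch_center[batch] + rnorm(n, 0, 0.3)   # latent technical factor
  sheet$batch <- paste0("b", batch)

  ## genotypes ---------------------------------------------------------------
  n_sites <- cfg$n_snp0bp + cfg$n_rs
  base_freq <- runif(n_sites, 0.1, 0.9)
  group_freq <- t(vapply(base_freq, function(p) {
    draw_group_allele_freqs(p, cfg$fst, length(cfg$groups))
  }, numeric(length(cfg$groups))))          # sites x groups
  colnames(group_freq) <- names(cfg$groups)
  g_idx <- match(ind_group, names(cfg$groups))
  geno_ind <- matrix(rbinom(n_sites * n_ind, 2,
                            group_freq[cbind(rep(seq_len(n_sites), n_ind),
                                             rep(g_idx, each = n_sites))]) / 2,
                     nrow = n_sites)        # sites x individuals, dosage/2
  geno <- geno_ind[, idx, drop = FALSE]     # sites x samples
  snp_rows <- seq_len(cfg$n_snp0bp)
  rs_rows <- if (cfg$n_rs > 0) cfg$n_snp0bp + seq_len(cfg$n_rs) else integer(0)

  ## probe effect loadings ---------------------------------------------------
  lambda_snp <- rnorm(cfg$n_snp0bp, 0, cfg$batch_sd)
  lambda_rs <- rnorm(cfg$n_rs, 0, cfg$batch_sd / 10)
  lambda_decoy <- rnorm(cfg$n_decoy, 0, cfg$batch_sd)
  kappa <- matrix(rnorm(cfg$n_snp0bp * cfg$n_celltypes), cfg$n_snp0bp)
  beta_sex <- rnorm(cfg$n_snp0bp, 0, cfg$sex_effect_sd)
  beta_age <- rnorm(cfg$n_snp0bp, 0, cfg$age_effect_sd)

  ## cell proportions --------------------------------------------------------
  alpha <- if (cfg$n_celltypes == 6) c(4, 8, 2, 2, 3, 25) else
    stats::runif(cfg$n_celltypes, 2, 10)
  cell_names <- if (cfg$n_celltypes == 6) {
    c("CD8T", "CD4T", "NK", "B", "Mono", "Neu")
  } else paste0("cell", seq_len(cfg$n_celltypes))
  if (cfg$confounded) {
    grp_idx <- as.integer(factor(sheet$ancestry_label))
    W <- t(vapply(grp_idx, function(gi) {
      a <- alpha; a[1] <- a[1] * (0.5 + gi)   # group-dependent composition
      as.numeric(rdirichlet(1, a))
    }, numeric(cfg$n_celltypes)))
  } else {
    W <- rdirichlet(n, alpha)
  }
  dimnames(W) <- list(sample_ids, cell_names)
  W_centered <- scale(W, center = TRUE, scale = FALSE)

  ## beta values -------------------------------------------------------------
  gm <- cfg$genotype_means
  geno_to_beta <- function(g) gm[1 + 2 * g]   # dosage 0/0.5/1 -> index 1/2/3
  male <- as.numeric(sheet$sex == "M")
  age_c <- sheet$age - 35

  beta_snp <- matrix(geno_to_beta(geno[snp_rows, , drop = FALSE]),
                     nrow = cfg$n_snp0bp) +
    outer(lambda_snp, tech) +
    cfg$cell_sd * (kappa %*% t(W_centered)) +
    outer(beta_sex, male) +
    outer(beta_age, age_c) +
    matrix(rnorm(cfg$n_snp0bp * n, 0, cfg$noise_sd), cfg$n_snp0bp)

  beta_rs <- if (cfg$n_rs > 0) {
    matrix(geno_to_beta(geno[rs_rows, , drop = FALSE]), nrow = cfg$n_rs) +
      outer(lambda_rs, tech) +
      matrix(rnorm(cfg$n_rs * n, 0, cfg$noise_sd / 2), cfg$n_rs)
  } else matrix(0, 0, n)

  decoy_mu <- runif(cfg$n_decoy, 0.05, 0.95)
  beta_decoy <- matrix(decoy_mu, cfg$n_decoy, n) +
    outer(lambda_decoy, tech) +
    matrix(rnorm(cfg$n_decoy * n, 0, cfg$noise_sd), cfg$n_decoy)

  clip <- function(x) pmin(pmax(x, 0.001), 0.999)
  snp_ids <- sprintf("cg%07d", seq_len(cfg$n_snp0bp))
  decoy_ids <- sprintf("cg%07d", 5e6 + seq_len(cfg$n_decoy))
  rs_ids <- if (cfg$n_rs > 0) sprintf("rs%06d", seq_len(cfg$n_rs)) else character(0)
  beta_all <- clip(rbind(beta_snp, beta_decoy, beta_rs))
  probe_ids <- c(snp_ids, decoy_ids, rs_ids)
  rownames(beta_all) <- probe_ids
  colnames(beta_all) <- sample_ids
  n_probes <- nrow(beta_all)

  ## intensities, backgrounds, bead counts -----------------------------------
  probe_channel <- stats::setNames(
    sample(c("grn", "red", "both"), n_probes, replace = TRUE,
           prob = c(0.15, 0.15, 0.70)), probe_ids)
  total <- matrix(rlnorm(n_probes * n, log(4000), 0.25), n_probes)
  offset <- 100
  meth <- pmin(beta_all * (total + offset), total)
  unmeth <- total - meth

  bg_grn <- rnorm(n, 150, 15); bg_red <- rnorm(n, 150, 15)
  neg_controls <- lapply(seq_len(n), function(j) {
    list(grn = pmax(rnorm(30, bg_grn[j], 20), 1),
         red = pmax(rnorm(30, bg_red[j], 20), 1))
  })
  names(neg_controls) <- sample_ids
  bg_for <- function(channel_needed) {
    # per-entry background by the channel each signal is read in
    m <- matrix(0, n_probes, n)
    grn_rows <- probe_channel %in% (if (channel_needed == "meth")
      c("grn", "both") else "grn")
    m[grn_rows, ] <- matrix(bg_grn, sum(grn_rows), n, byrow = TRUE)
    m[!grn_rows, ] <- matrix(bg_red, sum(!grn_rows), n, byrow = TRUE)
    m
  }
  meth_raw <- meth + bg_for("meth")
  unmeth_raw <- unmeth + bg_for("unmeth")

  if (cfg$detect_fail_rate > 0) {
    fail <- matrix(runif(n_probes * n) < cfg$detect_fail_rate, n_probes)
    bg_mat <- matrix((bg_grn + bg_red) / 2, n_probes, n, byrow = TRUE)
    meth_raw[fail] <- 0.3 * bg_mat[fail]
    unmeth_raw[fail] <- 0.3 * bg_mat[fail]
  } else {
    fail <- matrix(FALSE, n_probes, n)
  }

  beads <- matrix(pmax(rpois(n_probes * n, 12), 3), n_probes)
  if (cfg$low_bead_rate > 0) {
    low <- runif(n_probes * n) < cfg$low_bead_rate
    beads[low] <- sample(0:2, sum(low), replace = TRUE)
  }
  dimnames(meth_raw) <- dimnames(unmeth_raw) <- dimnames(beads) <-
    list(probe_ids, sample_ids)

  signals <- signal_set(meth_raw, unmeth_raw, beads, neg_controls, probe_channel)

  ## control probes ----------------------------------------------------------
  gamma <- rnorm(cfg$n_control, 0, 0.3)
  ctrl <- 2^(log2(2000) + outer(tech, gamma) +
               matrix(rnorm(n * cfg$n_control, 0, 0.1), n))
  dimnames(ctrl) <- list(sample_ids, sprintf("ctrl%04d", seq_len(cfg$n_control)))

  ## annotation --------------------------------------------------------------
  half <- cfg$n_decoy %/% 2
  annotation <- data.frame(
    probe_id = probe_ids,
    probe_kind = c(rep("cpg", cfg$n_snp0bp + cfg$n_decoy), rep("rs", cfg$n_rs)),
    array = "EPICv1",
    design_type = ifelse(probe_channel[probe_ids] == "both", "II", "I"),
    channel = unname(probe_channel[probe_ids]),
    snp_distance = c(rep(0, cfg$n_snp0bp),
                     # decoys fail selection: distant SNP or rare SNP
                     c(sample(10:500, half, replace = TRUE),
                       rep(0, cfg$n_decoy - half)),
                     rep(NA_real_, cfg$n_rs)),
    maf = c(pmin(base_freq[snp_rows], 1 - base_freq[snp_rows]),
            c(runif(half, 0.05, 0.5), runif(cfg$n_decoy - half, 0.001, 0.049)),
            rep(NA_real_, cfg$n_rs)),
    control_category = NA_character_,
    stringsAsFactors = FALSE
  )
  class(annotation) <- c("probe_annotation", "data.frame")

  ## ground truth ------------------------------------------------------------
  geno_snp <- geno[snp_rows, , drop = FALSE]
  geno_rs <- geno[rs_rows, , drop = FALSE]
  rownames(geno_snp) <- snp_ids
  if (cfg$n_rs > 0) rownames(geno_rs) <- rs_ids
  colnames(geno_snp) <- sample_ids
  if (cfg$n_rs > 0) colnames(geno_rs) <- sample_ids
  gp <- prcomp(t(geno), center = TRUE, scale. = FALSE)
  geno_pcs <- gp$x[, seq_len(min(3, ncol(gp$x))), drop = FALSE]
  rownames(geno_pcs) <- sample_ids

  truth <- list(group = stats::setNames(sheet$ancestry_label, sample_ids),
                group_code = stats::setNames(as.integer(factor(sheet$ancestry_label)),
                                             sample_ids),
                genotypes_snp0bp = geno_snp,
                genotypes_rs = geno_rs,
                geno_pcs = geno_pcs,
                batch = stats::setNames(sheet$batch, sample_ids),
                tech_factor = stats::setNames(tech, sample_ids),
                detection_failures = fail)

  structure(list(signals = signals, annotation = annotation, sheet = sheet,
                 cell_props = W, control_probes = ctrl, truth = truth,
                 config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", nrow(x$sheet), "samples,",
      length(unique(x$sheet$individual_id)), "individuals,",
      length(unique(x$sheet$ancestry_label)), "groups\n")
  print(x$signals)
  invisible(x)
}
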