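#' Write / read a probe-major matrix as TSV
#'
#' Matrices are stored with probe ids in a leading `probe_id` column,
#' sample ids as the header, `NA` for missing, full float precision
#' (round-trips are exact to the binary representation).
#'
#' @param x Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  x <- as.matrix(x)
  df <- data.frame(probe_id = rownames(x),
                   apply(x, 2, format_full), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

format_full <- function(v) {
  out <- formatC(v, format = "g", digits = 17)
  out[is.na(v)] <- NA
  trimws(out)
}

# generic data.frame TSV writer used for sample-major tables
write_sample_table <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], format_full)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits the same formats the pipeline reads back: `meth.tsv`,
#' `unmeth.tsv`, `beadcounts.tsv` (probes x samples), `negcontrols.tsv`
#' (long: sample_id, channel, intensity), `probe_channel.tsv`,
#' `samplesheet.tsv`, `cellprops.tsv`, `controlprobes.tsv`,
#' `annotation.tsv`, plus ground truth under `truth/`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- cohort$signals
  write_matrix_tsv(s$meth, file.path(dir, "meth.tsv"))
  write_matrix_tsv(s$unmeth, file.path(dir, "unmeth.tsv"))
  write_matrix_tsv(s$bead_counts, file.path(dir, "beadcounts.tsv"))
  nc <- do.call(rbind, lapply(names(s$neg_controls), function(id) {
    rbind(data.frame(sample_id = id, channel = "grn",
                     intensity = s$neg_controls[[id]]$grn),
          data.frame(sample_id = id, channel = "red",
                     intensity = s$neg_controls[[id]]$red))
  }))
  write_sample_table(nc, file.path(dir, "negcontrols.tsv"))
  write_sample_table(data.frame(probe_id = names(s$probe_channel),
                                channel = unname(s$probe_channel)),
                     file.path(dir, "probe_channel.tsv"))
  write_sample_table(cohort$sheet, file.path(dir, "samplesheet.tsv"))
  write_sample_table(data.frame(sample_id = rownames(cohort$cell_props),
                                cohort$cell_props, check.names = FALSE),
                     file.path(dir, "cellprops.tsv"))
  write_sample_table(data.frame(sample_id = rownames(cohort$control_probes),
                                cohort$control_probes, check.names = FALSE),
                     file.path(dir, "controlprobes.tsv"))
  write_sample_table(cohort$annotation, file.path(dir, "annotation.tsv"))
  tdir <- file.path(dir, "truth")
  dir.create(tdir, showWarnings = FALSE)
  write_sample_table(data.frame(sample_id = names(cohort$truth$group),
                                group = unname(cohort$truth$group),
                                group_code = unname(cohort$truth$group_code),
                                batch = unname(cohort$truth$batch)),
                     file.path(tdir, "samples.tsv"))
  write_matrix_tsv(cohort$truth$genotypes_snp0bp, file.path(tdir, "genotypes_snp0bp.tsv"))
  if (nrow(cohort$truth$genotypes_rs)) {
    write_matrix_tsv(cohort$truth$genotypes_rs, file.path(tdir, "genotypes_rs.tsv"))
  }
  write_sample_table(data.frame(sample_id = rownames(cohort$truth$geno_pcs),
                                cohort$truth$geno_pcs, check.names = FALSE),
                     file.path(tdir, "geno_pcs.tsv"))
  invisible(dir)
}

#' Read cohort inputs from a directory of TSV files
#'
#' Inverse of [write_cohort()] for the pipeline-facing inputs (ground
#' truth, if present, is read too).
#'
#' @param dir Directory written by [write_cohort()] (or assembled by hand
#'   in the same layout).
#' @return A list with `signals`, `annotation`, `sheet`, `cell_props`,
#'   `control_probes` and, when available, `truth`.
#' @export
read_cohort <- function(dir) {
  meth <- read_matrix_tsv(file.path(dir, "meth.tsv"))
  unmeth <- read_matrix_tsv(file.path(dir, "unmeth.tsv"))
  beads <- read_matrix_tsv(file.path(dir, "beadcounts.tsv"))
  nc_long <- read.delim(file.path(dir, "negcontrols.tsv"), stringsAsFactors = FALSE)
  neg_controls <- lapply(split(nc_long, nc_long$sample_id), function(d) {
    list(grn = d$intensity[d$channel == "grn"],
         red = d$intensity[d$channel == "red"])
  })
  pc <- read.delim(file.path(dir, "probe_channel.tsv"), stringsAsFactors = FALSE)
  probe_channel <- stats::setNames(pc$channel, pc$probe_id)
  signals <- signal_set(meth, unmeth, beads, neg_controls, probe_channel)
  ann <- read.delim(file.path(dir, "annotation.tsv"), stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  sheet <- read.delim(file.path(dir, "samplesheet.tsv"), stringsAsFactors = FALSE)
  cp <- read.delim(file.path(dir, "cellprops.tsv"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  cell_props <- as.matrix(cp[, -1, drop = FALSE])
  rownames(cell_props) <- cp[[1]]
  ctrl <- read.delim(file.path(dir, "controlprobes.tsv"), check.names = FALSE,
                     stringsAsFactors = FALSE)
  control_probes <- as.matrix(ctrl[, -1, drop = FALSE])
  rownames(control_probes) <- ctrl[[1]]
  out <- list(signals = signals, annotation = ann, sheet = sheet,
              cell_props = cell_props, control_probes = control_probes)
  tfile <- file.path(dir, "truth", "samples.tsv")
  if (file.exists(tfile)) {
    ts <- read.delim(tfile, stringsAsFactors = FALSE)
    gp <- read.delim(file.path(dir, "truth", "geno_pcs.tsv"), check.names = FALSE,
                     stringsAsFactors = FALSE)
    geno_pcs <- as.matrix(gp[, -1, drop = FALSE])
    rownames(geno_pcs) <- gp[[1]]
    out$truth <- list(group = stats::setNames(ts$group, ts$sample_id),
                      group_code = stats::setNames(ts$group_code, ts$sample_id),
                      batch = stats::setNames(ts$batch, ts$sample_id),
                      geno_pcs = geno_pcs)
  }
  out
}
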