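#' Construct a SignalSet
#'
#' Bundles the per-probe, per-sample raw intensity data of a methylation
#' array cohort: methylated and unmethylated signals, bead counts, per-sample
#' negative-control intensities (one set per color channel), and each
#' probe's channel routing. Type I probes read both alleles in one channel
#' (`"grn"` or `"red"`); type II probes (`"both"`) read the methylated
#' allele in green and the unmethylated allele in red.
#'
#' @param meth,unmeth Numeric probes x samples matrices of non-negative
#'   intensities (arbitrary units) with probe ids as rownames and sample
#'   ids as colnames.
#' @param bead_counts Integer matrix of the same shape.
#' @param neg_controls Named list, one element per sample, each a list with
#'   numeric vectors `grn` and `red` of negative-control intensities.
#' @param probe_channel Character vector named by probe id with values
#'   `"grn"`, `"red"` or `"both"`.
#' @return A list of class `signal_set`.
#' @export
signal_set <- function(meth, unmeth, bead_counts, neg_controls, probe_channel) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  bead_counts <- as.matrix(bead_counts)
  if (is.null(rownames(meth)) || is.null(colnames(meth))) {
    stop_validation("meth must have probe rownames and sample colnames")
  }
  same_dimnames <- function(a, b) {
    identical(dim(a), dim(b)) && identical(dimnames(a), dimnames(b))
  }
  if (!same_dimnames(meth, unmeth) || !same_dimnames(meth, bead_counts)) {
    stop_validation("meth, unmeth and bead_counts must share dimnames")
  }
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop_validation("negative intensities")
  }
  samples <- colnames(meth)
  if (!all(samples %in% names(neg_controls))) {
    stop_validation("neg_controls missing for sample(s): ",
                    paste(setdiff(samples, names(neg_controls)), collapse = ", "))
  }
  probes <- rownames(meth)
  if (!all(probes %in% names(probe_channel))) {
    stop_validation("probe_channel missing for some probes")
  }
  probe_channel <- probe_channel[probes]
  if (!all(probe_channel %in% c("grn", "red", "both"))) {
    stop_validation("probe_channel values must be grn, red or both")
  }
  structure(list(meth = meth, unmeth = unmeth, bead_counts = bead_counts,
                 neg_controls = neg_controls[samples],
                 probe_channel = probe_channel),
            class = "signal_set")
}

#' @export
print.signal_set <- function(x, ...) {
  cat("signal_set:", nrow(x$meth), "probes x", ncol(x$meth), "samples\n")
  cat("  channels:", paste(names(table(x$probe_channel)),
                           table(x$probe_channel), sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Restrict a SignalSet to a set of probes
#'
#' @param signals A `signal_set`.
#' @param probe_ids Probe ids to keep (must all be present); output rows
#'   follow the order of `probe_ids`.
#' @return A `signal_set` restricted to those probes.
#' @export
subset_probes <- function(signals, probe_ids) {
  stopifnot(inherits(signals, "signal_set"))
  missing_ids <- setdiff(probe_ids, rownames(signals$meth))
  if (length(missing_ids)) {
    stop_validation("probes absent from signal set: ",
                    paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  signal_set(signals$meth[probe_ids, , drop = FALSE],
             signals$unmeth[probe_ids, , drop = FALSE],
             signals$bead_counts[probe_ids, , drop = FALSE],
             signals$neg_controls,
             signals$probe_channel[probe_ids])
}
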