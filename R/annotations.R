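#' Load a probe annotation table for one array platform
#'
#' Reads a delimited probe annotation table (TSV or CSV) and standardizes it
#' to the columns the probe-selection rules need: probe identity, probe kind
#' (CpG, genotyping rs, or control), distance to the nearest overlapping SNP,
#' and that SNP's minor allele frequency. Platform annotation sources name
#' these columns differently, so a per-platform column mapping can be
#' supplied; unknown columns are ignored.
#'
#' @param path Path to a delimited annotation table. Files ending in `.csv`
#'   are read as comma-separated, anything else as tab-separated. Must
#'   contain at least a probe identifier column.
#' @param array Platform the table describes: `"450K"`, `"EPICv1"` or
#'   `"EPICv2"`.
#' @param col_map Named list mapping the canonical field names
#'   (`probe_id`, `probe_kind`, `design_type`, `channel`, `snp_distance`,
#'   `maf`, `control_category`) to the column names used in the file.
#'   Fields absent from the mapping fall back to the canonical name; fields
#'   absent from the file are recorded as missing. May also be a path to a
#'   YAML or JSON file holding such a mapping.
#' @return A `data.frame` of class `probe_annotation` with columns
#'   `probe_id`, `probe_kind`, `array`, `design_type`, `channel`,
#'   `snp_distance`, `maf`, `control_category`. `probe_kind` is inferred
#'   from the probe id prefix (`cg`/`ch` = cpg, `rs` = rs, otherwise
#'   control) when no kind column is present.
#' @export
load_annotation <- function(path, array = c("450K", "EPICv1", "EPICv2"),
                            col_map = NULL) {
  array <- match.arg(array)
  if (!file.exists(path)) stop_validation("annotation file not found: ", path)
  col_map <- resolve_col_map(col_map)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)

  pick <- function(field) {
    nm <- col_map[[field]] %||% field
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }

  probe_id <- pick("probe_id")
  if (is.null(probe_id)) {
    stop_validation("annotation table has no probe_id column (looked for '",
                    col_map[["probe_id"]] %||% "probe_id", "')")
  }
  probe_id <- as.character(probe_id)
  if (anyDuplicated(probe_id)) {
    dup <- unique(probe_id[duplicated(probe_id)])
    stop_validation("duplicated probe_id in annotation: ",
                    paste(utils::head(dup, 5), collapse = ", "))
  }

  n <- length(probe_id)
  kind <- pick("probe_kind")
  if (is.null(kind)) {
    kind <- ifelse(grepl("^(cg|ch)", probe_id), "cpg",
                   ifelse(grepl("^rs", probe_id), "rs", "control"))
  } else {
    kind <- tolower(as.character(kind))
  }
  bad_kind <- setdiff(unique(kind), c("cpg", "rs", "control"))
  if (length(bad_kind)) {
    stop_validation("unknown probe_kind value(s): ", paste(bad_kind, collapse = ", "))
  }

  num_or_na <- function(x) if (is.null(x)) rep(NA_real_, n) else suppressWarnings(as.numeric(x))
  chr_or_na <- function(x) if (is.null(x)) rep(NA_character_, n) else as.character(x)

  maf <- num_or_na(pick("maf"))
  if (any(maf < 0 | maf > 1, na.rm = TRUE)) {
    stop_validation("maf values outside [0, 1]")
  }
  snp_distance <- num_or_na(pick("snp_distance"))
  if (any(snp_distance < 0, na.rm = TRUE)) {
    stop_validation("negative snp_distance values")
  }

  ann <- data.frame(
    probe_id = probe_id,
    probe_kind = kind,
    array = rep(array, n),
    design_type = chr_or_na(pick("design_type")),
    channel = chr_or_na(pick("channel")),
    snp_distance = snp_distance,
    maf = maf,
    control_category = chr_or_na(pick("control_category")),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

resolve_col_map <- function(col_map) {
  if (is.null(col_map)) return(list())
  if (is.character(col_map) && length(col_map) == 1L) {
    if (grepl("\\.ya?ml$", col_map, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop_validation("yaml package required to read a YAML column map")
      }
      return(yaml::read_yaml(col_map))
    }
    return(jsonlite::read_json(col_map, simplifyVector = TRUE))
  }
  as.list(col_map)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Merge annotation tables from multiple sources
#'
#' Used for EPICv1, where SNP-overlap annotations come from two
#' publications and a probe qualifies when it appears in either; duplicates
#' are dropped by probe id, keeping the first occurrence.
#'
#' @param ... `probe_annotation` tables for the same platform.
#' @return A single deduplicated `probe_annotation` table.
#' @export
merge_annotations <- function(...) {
  tabs <- list(...)
  if (!length(tabs)) stop_validation("no annotation tables supplied")
  arrays <- unique(vapply(tabs, function(t) t$array[1] %||% NA_character_, ""))
  arrays <- arrays[!is.na(arrays)]
  if (length(arrays) > 1) {
    stop_validation("annotation tables are for different platforms: ",
                    paste(arrays, collapse = ", "))
  }
  out <- do.call(rbind, tabs)
  out <- out[!duplicated(out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("probe_annotation", "data.frame")
  out
}

#' Select SNP-overlapping CpG probes ("SNP0bp")
#'
#' A CpG probe is ancestry-informative here when its interrogated site
#' overlaps a SNP exactly (distance 0) whose minor allele frequency is at
#' least `maf_min`; its beta value is then genotype-driven. Probes with an
#' unknown SNP distance or MAF are excluded.
#'
#' @param annotation A `probe_annotation` table.
#' @param maf_min Minimum minor allele frequency, inclusive. Default 0.05.
#' @return Character vector of probe ids, sorted lexicographically.
#' @export
select_snp0bp <- function(annotation, maf_min = 0.05) {
  stopifnot(inherits(annotation, "probe_annotation"))
  keep <- annotation$probe_kind == "cpg" &
    !is.na(annotation$snp_distance) & annotation$snp_distance == 0 &
    !is.na(annotation$maf) & annotation$maf >= maf_min
  sort(annotation$probe_id[keep])
}

#' Select genotyping rs probes
#'
#' Returns every probe of kind `rs` on the platform, sorted. If the table
#' contains none, the combined method degenerates to using residualized
#' betas alone, which is reported as a warning.
#'
#' @param annotation A `probe_annotation` table.
#' @return Character vector of probe ids, sorted lexicographically.
#' @export
select_rs_probes <- function(annotation) {
  stopifnot(inherits(annotation, "probe_annotation"))
  ids <- sort(annotation$probe_id[annotation$probe_kind == "rs"])
  if (!length(ids)) {
    warning("annotation contains no rs probes; genotype-augmented features ",
            "will be identical to the residualized features")
  }
  ids
}

#' Build a probe selection for one platform
#'
#' @param annotation A `probe_annotation` table.
#' @param maf_min Minimum minor allele frequency for SNP-overlapping CpGs.
#' @return A list of class `probe_selection` with `snp0bp_ids`, `rs_ids`
#'   and `array`.
#' @export
probe_selection <- function(annotation, maf_min = 0.05) {
  sel <- list(
    snp0bp_ids = select_snp0bp(annotation, maf_min = maf_min),
    rs_ids = select_rs_probes(annotation),
    array = annotation$array[1] %||% NA_character_
  )
  stopifnot(!anyDuplicated(c(sel$snp0bp_ids, sel$rs_ids)))
  class(sel) <- "probe_selection"
  sel
}

#' Write a probe selection to JSON
#'
#' @param selection A `probe_selection`.
#' @param path Output path.
#' @export
write_probe_selection <- function(selection, path) {
  stopifnot(inherits(selection, "probe_selection"))
  jsonlite::write_json(unclass(selection), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
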