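## On-disk formats: TSV matrices and tables, BED6 export, YAML run config.
## All tabular outputs are TSV with a fixed column order; floats are written
## with 6 significant digits and round-trip at that precision.

write_tsv <- function(df, path, digits = 6) {
  # fractional doubles get 6 significant digits; integral-valued columns
  # (e.g. genomic coordinates) are written exactly
  num <- vapply(df, function(v) {
    is.double(v) && any(v != round(v), na.rm = TRUE)
  }, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a feature-by-sample value matrix from TSV
#'
#' The file must have a header row of sample ids and a first column of
#' feature ids.  Values are validated for the declared kind: beta values in
#' \[0, 1\], TPM values >= 0.
#'
#' @param path TSV file path.
#' @param kind `"beta"` or `"tpm"`.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix <- function(path, kind = c("beta", "tpm")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (file.size(path) == 0) stopf("parse error: %s is empty", path)
  lines <- readLines(path)
  if (length(lines) < 2) stopf("parse error: %s has no data rows", path)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    stopf("parse error: ragged rows in %s (fields %s)", path,
          paste(unique(nfield), collapse = "/"))
  }
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stopf("duplicate feature ids in %s", path)
  if (anyDuplicated(names(df)[-1])) stopf("duplicate sample ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("parse error: non-numeric values in %s", path)
  rownames(m) <- ids
  bad <- if (kind == "beta") {
    which(m < 0 | m > 1, arr.ind = TRUE)
  } else {
    which(m < 0, arr.ind = TRUE)
  }
  if (nrow(bad)) {
    stopf("validation error: %s value %g out of range at feature %s, sample %s",
          kind, m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
          colnames(m)[bad[1, 2]])
  }
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m Numeric matrix with rownames (features) and colnames (samples).
#' @param path Output path.
#' @param feature_col Header name of the feature-id column.
#' @param digits Significant digits for values.
#' @export
write_matrix <- function(m, path, feature_col = "feature_id", digits = 6) {
  df <- data.frame(rownames(m), signif(m, digits), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(feature_col, colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

manifest_columns <- function() {
  c("probe_id", "chrom", "pos", "gene_symbol", "feature_class",
    "cgi_context", "sex_chrom", "multi_mapped", "snp_overlap",
    "detection_fail_fraction", "intensity_z")
}

#' Read and validate a probe manifest
#'
#' @param path Manifest TSV path.
#' @return Manifest data frame sorted by (chrom, pos), with unique probe ids.
#' @export
read_manifest <- function(path) {
  df <- read_tsv(path)
  validate_manifest(df)
}

validate_manifest <- function(df) {
  missing <- setdiff(manifest_columns(), names(df))
  if (length(missing)) {
    stopf("manifest is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$probe_id)) stopf("manifest probe_ids are not unique")
  if (any(df$pos < 1)) stopf("manifest positions must be >= 1")
  for (cl in c("sex_chrom", "multi_mapped", "snp_overlap")) {
    df[[cl]] <- as.logical(df[[cl]])
  }
  ord <- order(chrom_rank(df$chrom), df$pos)
  df <- df[ord, manifest_columns()]
  rownames(df) <- NULL
  df
}

chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  suppressWarnings(n <- as.numeric(x))
  n[x == "X"] <- 23; n[x == "Y"] <- 24; n[x == "M"] <- 25
  n[is.na(n)] <- 26
  n
}

#' Read and validate a twin-pair sample sheet
#'
#' Checks that every pair has exactly one depressed and one nondepressed
#' member and that pair-shared covariates (age, sex) agree within pair.
#'
#' @param path Sample sheet TSV path.
#' @return Validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path)
  validate_sample_sheet(df)
}

validate_sample_sheet <- function(df) {
  need <- c("sample_id", "pair_id", "role", "batch_id")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stopf("sample sheet is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (!all(df$role %in% c("depressed", "nondepressed"))) {
    stopf("sample sheet roles must be 'depressed' or 'nondepressed'")
  }
  tab <- table(df$pair_id, df$role)
  bad <- rownames(tab)[tab[, "depressed"] != 1 | tab[, "nondepressed"] != 1]
  if (length(bad)) {
    stopf("pairs without exactly one member per role: %s",
          paste(head(bad, 5), collapse = ", "))
  }
  for (cv in intersect(pair_shared_covariates(), names(df))) {
    agree <- tapply(df[[cv]], df$pair_id, function(v) length(unique(v)) == 1)
    if (!all(agree)) {
      stopf("pair-shared covariate '%s' differs within pair(s): %s", cv,
            paste(head(names(agree)[!agree], 5), collapse = ", "))
    }
  }
  df
}

#' Export called DMRs as a BED6 file
#'
#' Region coordinates are 1-based inclusive internally; BED output uses the
#' standard 0-based half-open convention (start-1, end).  The score column
#' is -10*log10(region q) capped at 1000.
#'
#' @param regions Region table (from [call_dmrs()] or [score_regions()])
#'   with columns `chrom`, `start`, `end`, `gene`, `region_q`.
#' @param path Output BED path.
#' @export
write_dmr_bed <- function(regions, path) {
  if (nrow(regions) && any(regions$end < regions$start)) {
    stopf("invalid region: end < start")
  }
  q <- regions$region_q
  score <- ifelse(q <= 0, 1000, pmin(round(-10 * log10(q)), 1000))
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start - 1,
    end = regions$end,
    name = regions$gene,
    score = score,
    strand = "."
  )
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

run_config_defaults <- function() {
  list(
    inputs = list(beta = NULL, tpm = NULL, manifest = NULL, genes = NULL,
                  samples = NULL),
    preprocess = list(detect_fail_max = 0.20, intensity_z_max = 3,
                      gene_floor = 1.0, gene_max_low_fraction = 0.05),
    dmr = list(max_gap_bp = 1000, min_probes = 5, peak_p = 0.01,
               min_corr = 0.30, q_max = 0.05, corr_method = "mean"),
    integration = list(cis_window = 5000, permutations = 100, alpha = 0.05,
                       tail = "two", bin_bp = 500),
    network = list(p_max = 0.001, min_module_size = 50, edge_cutoff = 0.1,
                   cut_height = 0.95, permutations = 200),
    seed = 1L
  )
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; missing keys are filled with documented
#' defaults and the effective thresholds are echoed to the log.
#'
#' @param path YAML config file.
#' @param require_inputs Character vector of input keys that must be set.
#' @param verbose Echo effective thresholds.
#' @return Nested configuration list.
#' @export
load_run_config <- function(path, require_inputs = character(0),
                            verbose = TRUE) {
  user <- yaml::read_yaml(path) %||% list()
  defaults <- run_config_defaults()
  unknown_sections <- setdiff(names(user), names(defaults))
  if (length(unknown_sections)) {
    stopf("config error: unknown key(s): %s",
          paste(unknown_sections, collapse = ", "))
  }
  cfg <- defaults
  for (sec in names(user)) {
    if (is.list(defaults[[sec]])) {
      unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
      if (length(unknown)) {
        stopf("config error: unknown key(s) in '%s': %s", sec,
              paste(unknown, collapse = ", "))
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    } else {
      cfg[[sec]] <- user[[sec]]
    }
  }
  missing <- require_inputs[vapply(cfg$inputs[require_inputs], is.null,
                                   logical(1))]
  if (length(missing)) {
    stopf("config error: missing required input path(s): %s",
          paste(missing, collapse = ", "))
  }
  log_msg("config: dmr min_probes=%d peak_p=%g min_corr=%g q_max=%g; cis_window=%d; seed=%d",
          cfg$dmr$min_probes, cfg$dmr$peak_p, cfg$dmr$min_corr,
          cfg$dmr$q_max, cfg$integration$cis_window, as.integer(cfg$seed),
          verbose = verbose)
  cfg
}
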