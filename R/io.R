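# Typed table IO: beta/expression matrices, sample sheets, probe manifests,
# GMT gene sets.  All writers are tab-delimited, header first, bit-stable
# (fixed column order, no quoting, no row names) so rerun digests reproduce.

#' Read a methylation beta matrix
#'
#' Reads a probes x samples TSV (first column probe ids, header row sample
#' ids) of methylation proportions.  The array beta statistic
#' M / (U + M + 100) is strictly below 1, so values must lie in `[0, 1)`;
#' missing cells, non-numeric cells and duplicated probe ids are rejected
#' rather than silently dropped.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with probe ids as rownames, sample ids as colnames.
#' @export
read_beta_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(tab) < 2L) stop("beta matrix needs a probe id column and >=1 sample")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicated probe id(s) in beta matrix: ", paste(unique(dup), collapse = ", "))
  m <- matrix(NA_real_, nrow(tab), ncol(tab) - 1L,
              dimnames = list(ids, colnames(tab)[-1L]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric or missing beta value at probe '%s', sample '%s'",
                   ids[bad[1L]], colnames(m)[j]))
    m[, j] <- v
  }
  validate_beta_matrix(m)
  m
}

#' @rdname read_beta_matrix
#' @param m numeric matrix to validate (values in `[0, 1)`, complete,
#'   dimnames present).
#' @export
validate_beta_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("beta matrix must carry probe and sample ids as dimnames")
  if (anyNA(m)) stop("beta matrix contains missing values")
  bad <- which(m < 0 | m >= 1, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value out of [0,1) at probe '%s', sample '%s': %g",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
                 m[bad[1L, 1L], bad[1L, 2L]]))
  invisible(m)
}

#' Write a probes x samples matrix as TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name for the leading id column.
#' @export
write_beta_matrix <- function(m, path, id_col = "probe_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(m))
  write_table(df, path)
}

#' Read a log2 expression matrix
#'
#' Same layout as [read_beta_matrix()]; values are log2-scale normalized
#' intensities, floored at 0 upstream (minimum raw expression set to 1
#' before the log transform).
#'
#' @inheritParams read_beta_matrix
#' @return numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated expression probe id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains non-numeric or missing values")
  if (any(m < 0)) stop("expression values must be >= 0 (log2 of floored intensities)")
  m
}

sample_sheet_required <- c(
  "sample_id", "subject_id", "tissue", "ga_weeks", "bw_sd_score", "sex", "batch"
)

#' Read and validate a sample sheet
#'
#' CSV with one row per sample.  Mandatory columns: sample_id, subject_id,
#' tissue (cord/postnatal), ga_weeks, bw_sd_score, sex (male/female), batch.
#' Optional: continuous and binary prenatal covariates,
#' postmenstrual_age_at_draw, interval_weeks (postnatal rows only).
#'
#' @param path path to a CSV file.
#' @return data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param df data.frame to validate in place.
#' @export
validate_sample_sheet <- function(df) {
  missing <- setdiff(sample_sheet_required, colnames(df))
  if (length(missing))
    stop("sample sheet missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!all(df$tissue %in% c("cord", "postnatal")))
    stop("tissue must be 'cord' or 'postnatal'; got: ",
         paste(unique(setdiff(df$tissue, c("cord", "postnatal"))), collapse = ", "))
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'; got: ",
         paste(unique(setdiff(df$sex, c("male", "female"))), collapse = ", "))
  if (any(df$ga_weeks < 22 | df$ga_weeks > 42))
    stop("ga_weeks outside [22, 42]")
  key <- paste(df$subject_id, df$tissue)
  if (anyDuplicated(key))
    stop("duplicate (subject_id, tissue) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id(s)")
  for (b in intersect(BINARY_COVARIATES, colnames(df))) {
    if (!all(df[[b]] %in% c(0L, 1L)))
      stop("binary covariate '", b, "' must be 0/1")
  }
  if ("interval_weeks" %in% colnames(df)) {
    if (any(!is.na(df$interval_weeks) & df$tissue == "cord"))
      stop("interval_weeks must be absent (NA) for cord rows")
    if (any(is.na(df$interval_weeks) & df$tissue == "postnatal"))
      stop("interval_weeks required for postnatal rows")
  } else if (any(df$tissue == "postnatal")) {
    stop("sample sheet with postnatal rows needs an interval_weeks column")
  }
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a CpG probe manifest
#'
#' TSV with columns probe_id, chrom, pos (1-based cytosine coordinate), gene
#' (symbol or empty), gene_region, island_relation, chromstate_T,
#' chromstate_B, and optionally is_cpg (0/1; synthetic manifests mark
#' non-CpG control probes explicitly instead of relying on vendor id
#' prefixes).
#'
#' @param path path to a TSV file.
#' @return data.frame of class `probe_manifest`.
#' @export
read_probe_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "gene", "gene_region",
            "island_relation", "chromstate_T", "chromstate_B")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("probe manifest missing column(s): ", paste(missing, collapse = ", "))
  df$gene[is.na(df$gene)] <- ""
  validate_probe_manifest(df)
}

#' @rdname read_probe_manifest
#' @param df data.frame to validate.
#' @export
validate_probe_manifest <- function(df) {
  if (any(df$pos <= 0)) stop("manifest positions must be positive")
  if (anyDuplicated(df$probe_id)) stop("duplicate probe_id in manifest")
  bad <- setdiff(unique(df$gene_region), GENE_REGIONS)
  if (length(bad))
    stop("unknown gene_region label(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$island_relation), ISLAND_RELATIONS)
  if (length(bad))
    stop("unknown island_relation label(s): ", paste(bad, collapse = ", "))
  for (col in c("chromstate_T", "chromstate_B")) {
    bad <- setdiff(unique(df[[col]]), CHROM_STATES_25)
    if (length(bad))
      stop("unknown chromatin state label(s) in ", col, ": ",
           paste(bad, collapse = ", "))
  }
  igr <- df$gene_region == "IGR"
  if (any(igr != (df$gene == "")))
    stop("gene_region must be IGR exactly when gene is empty")
  class(df) <- c("probe_manifest", "data.frame")
  df
}

#' Read an expression probe manifest
#'
#' TSV with columns expr_probe_id, chrom, pos (1-based representative
#' coordinate), gene.
#'
#' @param path path to a TSV file.
#' @return data.frame of class `expr_manifest`.
#' @export
read_expr_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("expr_probe_id", "chrom", "pos", "gene")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("expression manifest missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(df$pos <= 0)) stop("manifest positions must be positive")
  if (anyDuplicated(df$expr_probe_id)) stop("duplicate expr_probe_id")
  class(df) <- c("expr_manifest", "data.frame")
  df
}

#' Write a record table as bit-stable TSV
#'
#' Header-first, tab-delimited, unquoted, no row names; numeric columns are
#' serialized with full precision via format(..., digits = 15).
#'
#' @param records data.frame.
#' @param path output path.
#' @export
write_table <- function(records, path) {
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- vapply(out[[j]], function(x)
        if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE,
                                       trim = TRUE), "")
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a sample sheet as CSV
#' @param sheet sample sheet data.frame.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.csv(sheet, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes, one set per line.
#'
#' @param path path to a .gmt file.
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

#' Convert BED-style 0-based starts to 1-based point coordinates
#'
#' Manifests use the 1-based Illumina convention; BED input (0-based,
#' half-open) is shifted on load and the conversion is logged.
#'
#' @param start0 integer vector of 0-based start coordinates.
#' @return 1-based positions.
#' @export
bed_to_point <- function(start0) {
  .log("INFO", "converting ", length(start0),
       " BED 0-based starts to 1-based point coordinates")
  as.integer(start0) + 1L
}
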