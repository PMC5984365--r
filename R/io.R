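#' Read a taxon count table
#'
#' Reads a taxa-rows x sample-columns count table. The TSV dialect expects a
#' header of sample ids, a first column `taxon_id` and optional `genus` /
#' `species` columns; the BIOM dialect accepts a BIOM-JSON file (read via
#' the biomformat package). If `sample_ids` is supplied (e.g. from the
#' metadata table) and the table appears transposed (sample ids in the first
#' column rather than the header) it is auto-transposed with a warning.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"biom"`.
#' @param sample_ids optional character vector of expected sample ids, used
#'   only to detect a transposed table.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, dialect = c("tsv", "biom"), sample_ids = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required for dialect = 'biom'")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
    taxonomy <- NULL
    if (is.data.frame(om) && all(c("genus", "species") %in% names(om))) {
      taxonomy <- data.frame(taxon_id = rownames(m),
                             genus = as.character(om$genus),
                             species = as.character(om$species),
                             stringsAsFactors = FALSE)
    }
    return(count_matrix(m, taxonomy))
  }

  if (file.size(path) == 0 || length(readLines(path, n = 1L)) == 0)
    stop("empty count table: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("count table has a header but no rows: ", path)
  id_col <- names(df)[1]
  ids <- as.character(df[[1]])
  tax_cols <- intersect(c("genus", "species"), names(df))
  samp_cols <- setdiff(names(df)[-1], tax_cols)
  if (length(samp_cols) == 0) stop("count table has no sample columns")

  # transposed input: metadata sample ids found in the id column, not header
  if (!is.null(sample_ids) &&
      !any(sample_ids %in% samp_cols) && any(sample_ids %in% ids)) {
    warning("count table appears transposed (samples in rows); transposing")
    m <- t(as.matrix(df[, samp_cols, drop = FALSE]))
    colnames(m) <- ids
    return(count_matrix(m))
  }

  for (cn in samp_cols) {
    if (!is.numeric(df[[cn]])) {
      row <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))) | TRUE)[1]
      stop(sprintf("non-numeric count in column '%s' (e.g. row %d, taxon '%s')",
                   cn, row, ids[row]))
    }
  }
  m <- as.matrix(df[, samp_cols, drop = FALSE])
  rownames(m) <- ids
  taxonomy <- NULL
  if (length(tax_cols) > 0) {
    taxonomy <- data.frame(
      taxon_id = ids,
      genus = if ("genus" %in% tax_cols) as.character(df$genus) else ids,
      species = if ("species" %in% tax_cols) as.character(df$species) else "",
      stringsAsFactors = FALSE)
    taxonomy$species[is.na(taxonomy$species)] <- ""
  }
  cm <- count_matrix(m, taxonomy)
  message(sprintf("read %d taxa x %d samples from %s",
                  nrow(m), ncol(m), path))
  cm
}

#' Write a count table as TSV
#'
#' Inverse of [read_counts()] for the TSV dialect: columns `taxon_id`,
#' `genus`, `species`, then one column per sample.
#'
#' @param cm a [count_matrix()]
#' @param path output file path.
#' @export
write_counts <- function(cm, path) {
  df <- cbind(cm$taxonomy, as.data.frame(cm$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Required per-sample metadata columns (the analysis covariates + outcomes)
sample_frame_columns <- function() {
  c("sample_id", "group", "age", "sex", "race_white", "ethnicity_hispanic",
    "dental_visit_past_year", "antibiotic_past_3mo", "periodontitis",
    "caries", "total_reads")
}

#' Validate a per-sample metadata frame
#'
#' Checks the columns the pipeline requires: `sample_id`, `group` (PHIV or
#' PHEU), `age` (years), the 0/1 indicators `sex`, `race_white`,
#' `ethnicity_hispanic`, `dental_visit_past_year`, `antibiotic_past_3mo`,
#' the 0/1 outcomes `periodontitis` and `caries`, and `total_reads`
#' (positive integer). Unknown columns are preserved but ignored.
#'
#' @param sf data.frame of per-sample metadata.
#' @return the validated data.frame (invisibly identical content).
#' @export
validate_sample_frame <- function(sf) {
  miss <- setdiff(sample_frame_columns(), names(sf))
  if (length(miss) > 0)
    stop("metadata missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sf$sample_id))
    stop("duplicate sample ids in metadata")
  bad_grp <- setdiff(unique(as.character(sf$group)), c("PHIV", "PHEU"))
  if (length(bad_grp) > 0)
    stop("group values outside {PHIV, PHEU}: ", paste(bad_grp, collapse = ", "))
  if (anyNA(sf$group) || anyNA(sf$total_reads))
    stop("group and total_reads must be non-missing")
  if (any(sf$total_reads <= 0))
    stop("total_reads must be positive")
  for (cn in c("sex", "race_white", "ethnicity_hispanic",
               "dental_visit_past_year", "antibiotic_past_3mo",
               "periodontitis", "caries")) {
    v <- sf[[cn]]
    if (!all(v[!is.na(v)] %in% c(0, 1)))
      stop("column '", cn, "' must be coded 0/1")
  }
  sf$sample_id <- as.character(sf$sample_id)
  sf$group <- as.character(sf$group)
  sf
}

#' Read / write per-sample metadata
#'
#' TSV with one row per sample and the columns listed in
#' [validate_sample_frame()]; binary fields coded 0/1.
#'
#' @param path file path.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sf <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_frame(sf)
}

#' @rdname read_metadata
#' @param sf metadata data.frame.
#' @export
write_metadata <- function(sf, path) {
  utils::write.table(sf, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align a count matrix with a metadata frame
#'
#' Restricts and reorders the count matrix columns to the metadata's
#' `sample_id` order; errors if either side has samples the other lacks.
#' Optionally asserts that `total_reads` equals the column sums (true when
#' the metadata was derived from this matrix, before any taxon filtering).
#'
#' @param cm a [count_matrix()]
#' @param sf validated metadata frame.
#' @param check_total_reads assert `total_reads == sample_sums(cm)`.
#' @return list with elements `counts` and `metadata`, aligned.
#' @export
align_samples <- function(cm, sf, check_total_reads = FALSE) {
  sf <- validate_sample_frame(sf)
  only_cm <- setdiff(colnames(cm$counts), sf$sample_id)
  only_sf <- setdiff(sf$sample_id, colnames(cm$counts))
  if (length(only_cm) > 0 || length(only_sf) > 0)
    stop("sample mismatch between counts and metadata: ",
         paste(c(only_cm, only_sf), collapse = ", "))
  cm <- subset_samples(cm, colnames(cm$counts) %in% sf$sample_id)
  cm$counts <- cm$counts[, sf$sample_id, drop = FALSE]
  if (check_total_reads && !isTRUE(all.equal(unname(sample_sums(cm)),
                                             as.numeric(sf$total_reads))))
    stop("metadata total_reads does not equal count-matrix column sums")
  list(counts = cm, metadata = sf)
}

#' Relative abundance (simple proportions)
#'
#' Converts counts to per-sample proportions: each cell divided by its
#' sample's total. Every column of the result sums to 1.
#'
#' @param cm a [count_matrix()]
#' @return numeric matrix of proportions with the same dimnames.
#' @export
relative_abundance <- function(cm) {
  tot <- sample_sums(cm)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(names(tot)[tot == 0], collapse = ", "))
  sweep(cm$counts, 2, tot, "/")
}
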