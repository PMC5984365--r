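#' Taxon-by-sample count matrix
#'
#' Container for subgingival-plaque (or any amplicon) taxon counts: a
#' non-negative integer matrix with taxa as rows and samples as columns,
#' plus a taxonomy table carrying the genus and (optionally) species label
#' for each row. Species may be empty for reads classified only to genus
#' level ("genus-only" rows); phylotype labels such as "HOT 272" are allowed
#' in either field.
#'
#' @param counts numeric matrix, taxa x samples, with unique row and column
#'   names. All cells must be non-negative integers with no missing values.
#' @param taxonomy optional data.frame with columns `taxon_id`, `genus`,
#'   `species` (character; `species` may be `""`). Row order must match
#'   `rownames(counts)`. When omitted, `genus` defaults to the taxon id and
#'   `species` to `""`.
#' @return object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `taxonomy` (data.frame).
#' @examples
#' m <- matrix(c(1L, 3L, 2L, 4L), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' cm <- count_matrix(m)
#' sample_sums(cm)
#' @export
count_matrix <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have taxon row names and sample column names")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  if (anyNA(counts))
    stop("counts contain missing values")
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "double"  # integer-valued; double storage avoids overflow in sums

  if (is.null(taxonomy)) {
    taxonomy <- data.frame(taxon_id = rownames(counts),
                           genus = rownames(counts),
                           species = "",
                           stringsAsFactors = FALSE)
  } else {
    need <- c("taxon_id", "genus", "species")
    miss <- setdiff(need, names(taxonomy))
    if (length(miss) > 0)
      stop("taxonomy missing column(s): ", paste(miss, collapse = ", "))
    taxonomy <- as.data.frame(taxonomy[, need], stringsAsFactors = FALSE)
    taxonomy$species[is.na(taxonomy$species)] <- ""
    if (!identical(as.character(taxonomy$taxon_id), rownames(counts)))
      stop("taxonomy taxon_id must match count matrix row names (same order)")
  }
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d taxa x %d samples (total reads %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  n_sp <- sum(x$taxonomy$species != "")
  cat(sprintf("  %d species-level rows, %d genus-only rows, %d genera\n",
              n_sp, nrow(x$taxonomy) - n_sp, length(unique(x$taxonomy$genus))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
as.matrix.count_matrix <- function(x, ...) x$counts

#' Per-sample and per-taxon read totals
#' @param cm a [count_matrix()]
#' @return named numeric vector of column (sample) or row (taxon) sums.
#' @export
sample_sums <- function(cm) colSums(cm$counts)

#' @rdname sample_sums
#' @export
taxon_sums <- function(cm) rowSums(cm$counts)

#' Subset a count matrix by taxa or samples
#'
#' @param cm a [count_matrix()]
#' @param keep logical vector or character vector of ids to keep.
#' @return a [count_matrix()] restricted to the kept rows/columns.
#' @export
subset_taxa <- function(cm, keep) {
  if (is.character(keep)) keep <- rownames(cm$counts) %in% keep
  count_matrix(cm$counts[keep, , drop = FALSE],
               cm$taxonomy[keep, , drop = FALSE])
}

#' @rdname subset_taxa
#' @export
subset_samples <- function(cm, keep) {
  if (is.character(keep)) keep <- colnames(cm$counts) %in% keep
  count_matrix(cm$counts[, keep, drop = FALSE], cm$taxonomy)
}
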