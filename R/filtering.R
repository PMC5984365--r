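## Exclusion rules applied before analysis, in a fixed order:
## antibiotic use -> low-read samples -> rare taxa -> low-prevalence taxa.

filter_report <- function(stage, axis, kept, removed, extra = list()) {
  structure(c(list(stage = stage, axis = axis,
                   n_in = length(kept) + length(removed),
                   n_out = length(kept),
                   n_removed = length(removed),
                   removed_ids = removed), extra),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] %s: %d in, %d removed, %d retained\n",
              x$stage, x$axis, x$n_in, x$n_removed, x$n_out))
  invisible(x)
}

#' Exclude participants with recent antibiotic use
#'
#' Removes every sample whose `antibiotic_past_3mo` flag is 1 from both the
#' metadata and the count matrix (antibiotic use within the prior 3 months
#' perturbs the plaque community and would confound group comparisons).
#'
#' @param cm a [count_matrix()]
#' @param sf metadata frame aligned with `cm`.
#' @return list with `counts`, `metadata` and a `report` giving per-group
#'   removal counts.
#' @export
exclude_antibiotic_users <- function(cm, sf) {
  flagged <- sf$antibiotic_past_3mo == 1
  removed <- sf$sample_id[flagged]
  by_group <- table(factor(sf$group[flagged], levels = c("PHIV", "PHEU")))
  if (all(flagged))
    warning("all samples flagged for antibiotic use; nothing retained")
  report <- filter_report("antibiotic_use", "samples",
                          sf$sample_id[!flagged], removed,
                          list(removed_by_group = as.list(by_group)))
  list(counts = subset_samples(cm, !colnames(cm$counts) %in% removed),
       metadata = sf[!flagged, , drop = FALSE],
       report = report)
}

#' Drop samples with too few reads
#'
#' Removes samples whose total read count (column sum) is strictly below
#' `min_reads`.
#'
#' @param cm a [count_matrix()]
#' @param sf optional metadata frame, filtered in step.
#' @param min_reads minimum total reads to retain a sample (default 200).
#' @return list with `counts`, `metadata` (NULL when not supplied) and
#'   `report`.
#' @export
drop_low_read_samples <- function(cm, sf = NULL, min_reads = 200) {
  stopifnot(min_reads >= 1)
  tot <- sample_sums(cm)
  keep <- tot >= min_reads
  report <- filter_report("low_read_samples", "samples",
                          names(tot)[keep], names(tot)[!keep],
                          list(min_reads = min_reads))
  list(counts = subset_samples(cm, keep),
       metadata = if (!is.null(sf)) sf[sf$sample_id %in% names(tot)[keep], ,
                                       drop = FALSE],
       report = report)
}

#' Drop globally rare taxa
#'
#' Removes taxa whose pooled relative abundance — the taxon's total reads
#' divided by the grand total over all retained samples — is strictly below
#' `threshold`.
#'
#' @param cm a [count_matrix()]
#' @param threshold pooled relative-abundance cutoff (default 1e-5).
#' @return list with `counts` and `report`.
#' @export
drop_rare_taxa <- function(cm, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold < 1)
  rel <- taxon_sums(cm) / sum(cm$counts)
  keep <- rel >= threshold
  report <- filter_report("rare_taxa", "taxa",
                          rownames(cm$counts)[keep],
                          rownames(cm$counts)[!keep],
                          list(threshold = threshold))
  list(counts = subset_taxa(cm, keep), report = report)
}

#' Drop taxa detected in too few subjects
#'
#' Removes taxa with a non-zero count in strictly fewer than `min_subjects`
#' samples (both groups combined); one pooled plaque sample per subject, so
#' samples are subjects here.
#'
#' @param cm a [count_matrix()]
#' @param min_subjects minimum number of samples with a non-zero count
#'   (default 10).
#' @return list with `counts` and `report`.
#' @export
drop_low_prevalence_taxa <- function(cm, min_subjects = 10) {
  stopifnot(min_subjects >= 1)
  prev <- rowSums(cm$counts > 0)
  keep <- prev >= min_subjects
  report <- filter_report("low_prevalence_taxa", "taxa",
                          rownames(cm$counts)[keep],
                          rownames(cm$counts)[!keep],
                          list(min_subjects = min_subjects))
  list(counts = subset_taxa(cm, keep), report = report)
}

#' Apply the full exclusion cascade
#'
#' Runs, in order: removal of an optional `UNMATCHED` taxon row (reads the
#' upstream classifier could not assign), antibiotic-use exclusion,
#' low-read sample removal, rare-taxon removal (pooled relative abundance),
#' and low-prevalence taxon removal. Each rule is idempotent and the
#' reports satisfy in = out + removed on each axis.
#'
#' @param cm a [count_matrix()]
#' @param sf metadata frame covering the samples of `cm`.
#' @param min_reads,min_rel_abund,min_subjects rule thresholds.
#' @return list with `counts`, `metadata` and `reports` (list of
#'   `filter_report`s, named by stage).
#' @export
apply_filters <- function(cm, sf, min_reads = 200, min_rel_abund = 1e-5,
                          min_subjects = 10) {
  sf <- validate_sample_frame(sf)
  reports <- list()

  unmatched <- rownames(cm$counts) == "UNMATCHED"
  if (any(unmatched)) {
    message(sprintf("dropping UNMATCHED row (%s reads)",
                    format(sum(cm$counts[unmatched, ]), big.mark = ",")))
    reports$unmatched <- filter_report("unmatched_reads", "taxa",
                                       rownames(cm$counts)[!unmatched],
                                       rownames(cm$counts)[unmatched])
    cm <- subset_taxa(cm, !unmatched)
  }

  st <- exclude_antibiotic_users(cm, sf)
  reports$antibiotic_use <- st$report
  st2 <- drop_low_read_samples(st$counts, st$metadata, min_reads)
  reports$low_read_samples <- st2$report
  st3 <- drop_rare_taxa(st2$counts, min_rel_abund)
  reports$rare_taxa <- st3$report
  st4 <- drop_low_prevalence_taxa(st3$counts, min_subjects)
  reports$low_prevalence_taxa <- st4$report

  list(counts = st4$counts, metadata = st2$metadata, reports = reports)
}
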