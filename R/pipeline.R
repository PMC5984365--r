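format_or <- function(or, ci, degenerate) {
  if (isTRUE(degenerate) || is.na(or)) return("Undefined")
  sprintf("%.1f (%.1f, %.1f)", or, ci[1], ci[2])
}

## Table-shaped rendering of a disease screen: formatted OR (95% CI) per
## group, "Undefined" for degenerate rows.
render_disease_table <- function(res) {
  data.frame(
    taxon_id = res$taxon_id,
    pheu_or = vapply(seq_len(nrow(res)), function(i)
      format_or(res$or_group0[i], c(res$ci0_low[i], res$ci0_high[i]),
                res$degenerate[i]), ""),
    phiv_or = vapply(seq_len(nrow(res)), function(i)
      format_or(res$or_group1[i], c(res$ci1_low[i], res$ci1_high[i]),
                res$degenerate[i]), ""),
    interaction_p = ifelse(res$degenerate, "Undefined",
                           sprintf("%.2g", res$interaction_p)),
    stringsAsFactors = FALSE)
}

format_screen_table <- function(res) {
  data.frame(
    taxon_id = res$taxon_id,
    rate_ratio = sprintf("%.2f (%.2f, %.2f)", res$rate_ratio,
                         res$ci_low, res$ci_high),
    p_value = sprintf("%.2g", res$p_value),
    p_adjust = sprintf("%.2g", res$p_adjust),
    stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render result tables to TSV
#'
#' Writes differential-abundance (with noteworthiness columns) and
#' disease-association tables in the supplementary-table layout: raw
#' numeric columns for machine round-trips plus formatted columns;
#' degenerate odds ratios are rendered as the literal string "Undefined".
#'
#' @param results named list; elements of class `taxon_screen` or
#'   `disease_screen` (others are written as plain data.frames).
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
render_tables <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    if (inherits(x, "taxon_screen")) {
      write_tsv(x$results, path)
    } else if (inherits(x, "disease_screen")) {
      out <- cbind(x$results[setdiff(names(x$results),
                                     c("outcome", "interaction_p"))],
                   render_disease_table(x$results)[-1])
      write_tsv(out, path)
    } else {
      write_tsv(as.data.frame(x), path)
    }
    written <- c(written, path)
  }
  invisible(written)
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on a count table and metadata frame:
#' sample/taxon exclusions, alpha diversity with group t tests and
#' rarefaction curves, species- and genus-level negative binomial screens
#' with BH control and FPRP/BFDP noteworthiness, disease-association
#' interaction models (primary etiologic sets when present in the matrix,
#' otherwise an exploratory BH-adjusted all-taxa run, plus the combined-set
#' model), and the prevalence cross-tabulation. All tables are written to
#' `out_dir` together with a JSON run manifest recording configuration,
#' seed, package version and per-stage sample/taxon accounting
#' (in = out + removed at every stage).
#'
#' @param counts a [count_matrix()] or path to a count TSV.
#' @param metadata a metadata frame or path to a metadata TSV.
#' @param out_dir output directory.
#' @param min_reads,min_rel_abund,min_subjects filter thresholds.
#' @param q BH false discovery rate for the screens.
#' @param priors,rr1 noteworthiness parameters.
#' @param shannon_base Shannon log base.
#' @param rarefaction_min_total minimum reads for rarefaction inclusion.
#' @param sets etiologic taxon sets ([etiologic_sets()] by default).
#' @param covariates adjustment covariates.
#' @param total_reads_mode how total reads enters the NB models.
#' @param seed optional integer recorded in the manifest (the pipeline
#'   itself is deterministic given its inputs).
#' @return invisible list with all stage results and the manifest.
#' @export
run_pipeline <- function(counts, metadata, out_dir,
                         min_reads = 200, min_rel_abund = 1e-5,
                         min_subjects = 10, q = 0.05,
                         priors = c(0.001, 0.01, 0.05), rr1 = 1.5,
                         shannon_base = 2, rarefaction_min_total = 65000,
                         sets = etiologic_sets(),
                         covariates = default_covariates(),
                         total_reads_mode = "log-covariate",
                         seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("plaquescreen")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = seed,
                   config = list(min_reads = min_reads,
                                 min_rel_abund = min_rel_abund,
                                 min_subjects = min_subjects, q = q,
                                 priors = priors, rr1 = rr1,
                                 shannon_base = shannon_base,
                                 rarefaction_min_total = rarefaction_min_total,
                                 covariates = covariates,
                                 total_reads_mode = total_reads_mode),
                   stages = list())
  flush_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      flush_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  inputs <- stage("load", {
    cm <- if (inherits(counts, "count_matrix")) counts else read_counts(counts)
    sf <- if (is.data.frame(metadata)) validate_sample_frame(metadata)
          else read_metadata(metadata)
    align_samples(cm, sf, check_total_reads = TRUE)
  })
  cm <- inputs$counts; sf <- inputs$metadata
  manifest$stages$load <- list(n_taxa = nrow(cm$counts),
                               n_samples = ncol(cm$counts))

  filt <- stage("filtering", apply_filters(cm, sf, min_reads,
                                           min_rel_abund, min_subjects))
  manifest$stages$filtering <- lapply(filt$reports, function(r)
    list(axis = r$axis, n_in = r$n_in, n_removed = r$n_removed,
         n_out = r$n_out, removed_ids = r$removed_ids))
  cm <- filt$counts; sf <- filt$metadata
  write_tsv(sf, file.path(out_dir, "metadata_filtered.tsv"))

  div <- stage("diversity", {
    ad <- alpha_diversity(cm, base = shannon_base)
    tests <- list(
      shannon = diversity_ttest(ad$shannon, sf$group),
      simpson = diversity_ttest(ad$simpson, sf$group))
    curves <- tryCatch(rarefaction_curves(cm, sf,
                                          min_total = rarefaction_min_total),
                       error = function(e) NULL)
    list(alpha = ad, tests = tests, curves = curves)
  })
  write_tsv(div$alpha, file.path(out_dir, "diversity.tsv"))
  if (!is.null(div$curves))
    write_tsv(div$curves, file.path(out_dir, "rarefaction.tsv"))
  jsonlite::write_json(
    lapply(div$tests, function(t) t[c("statistic", "p_value")]),
    file.path(out_dir, "diversity_tests.json"),
    auto_unbox = TRUE, digits = NA)
  manifest$stages$diversity <- list(
    n_samples = nrow(div$alpha),
    n_rarefied = if (is.null(div$curves)) 0
                 else length(unique(div$curves$sample_id)))

  screens <- stage("differential_abundance", {
    lapply(c(species = "species", genus = "genus"), function(lv) {
      suppressMessages(add_noteworthiness(
        taxon_screen(cm, sf, level = lv, q = q, covariates = covariates,
                     total_reads_mode = total_reads_mode),
        priors = priors, rr1 = rr1))
    })
  })
  render_tables(list(diffabund_species = screens$species,
                     diffabund_genus = screens$genus), out_dir)
  manifest$stages$differential_abundance <- lapply(screens, function(s)
    list(n_taxa = s$n_taxa, bh_family = s$bh_family_size,
         n_significant = sum(s$results$significant),
         n_noteworthy = sum(s$results$noteworthy, na.rm = TRUE),
         n_nonconverged = sum(!s$results$converged)))

  disease <- stage("disease_association", {
    out <- list()
    for (oc in c("periodontitis", "caries")) {
      ids <- intersect(sets[[oc]], rownames(cm$counts))
      if (length(ids) > 0) {
        scr <- disease_screen(cm, sf, oc, taxa = ids, adjust = "none",
                              covariates = covariates)
        combined <- fit_disease_set(cm, sf, oc, ids, covariates)
      } else {
        scr <- suppressWarnings(
          disease_screen(cm, sf, oc, adjust = "BH",
                         covariates = covariates))
        combined <- fit_disease_set(cm, sf, oc, rownames(cm$counts),
                                    covariates)
      }
      out[[oc]] <- list(screen = scr, combined = combined,
                        primary = length(ids) > 0)
    }
    out
  })
  for (oc in names(disease)) {
    render_tables(stats::setNames(list(disease[[oc]]$screen),
                                  paste0("disease_", oc)), out_dir)
    manifest$stages$disease_association[[oc]] <- list(
      mode = if (disease[[oc]]$primary) "primary_sets" else "exploratory",
      n_taxa = nrow(disease[[oc]]$screen$results),
      n_degenerate = sum(disease[[oc]]$screen$results$degenerate),
      combined = list(
        or_group0 = disease[[oc]]$combined$or_group0,
        or_group1 = disease[[oc]]$combined$or_group1,
        interaction_p = disease[[oc]]$combined$interaction_p,
        degenerate = disease[[oc]]$combined$degenerate))
  }

  prev <- stage("prevalence", prevalence_table(sf))
  write_tsv(as.data.frame(prev), file.path(out_dir, "prevalence_table.tsv"))
  manifest$stages$prevalence <- list(n_samples = sum(prev$n))

  flush_manifest()
  invisible(list(counts = cm, metadata = sf, filters = filt$reports,
                 diversity = div, screens = screens, disease = disease,
                 prevalence = prev, manifest = manifest,
                 out_dir = out_dir))
}
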