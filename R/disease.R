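#' Half-minimum zero replacement and log10 transform
#'
#' Replaces zeros with half the vector's minimum non-zero value, then takes
#' log10. Strictly increasing on the original counts, so ranks are
#' preserved; the half-minimum is computed across all supplied samples
#' (both groups pooled).
#'
#' @param x non-negative count vector with at least one non-zero entry.
#' @return numeric vector, log10 scale.
#' @examples
#' log10_halfmin(c(0, 10, 1000))  # log10(5), 1, 3
#' @export
log10_halfmin <- function(x) {
  if (all(x == 0))
    stop("all-zero taxon: cannot transform (should have been filtered)")
  half_min <- min(x[x > 0]) / 2
  log10(ifelse(x == 0, half_min, x))
}

#' Logistic disease-association model with group interaction
#'
#' Fits a logistic regression of a binary oral-disease outcome
#' (periodontitis or caries) on group (PHIV vs PHEU reference), the
#' taxon's transformed level (see [log10_halfmin()]), their product, the
#' adjustment covariates, and the log10 of the sample's total reads. Taxon
#' levels are per-log10 unit, so exp(coefficient) is the odds ratio per
#' tenfold count increase: PHEU OR = exp(b_taxon), PHIV OR =
#' exp(b_taxon + b_interaction), each with a Wald 95% CI, plus the Wald
#' p-value of the multiplicative interaction term.
#'
#' Separation or an empty stratum (e.g. a taxon present only in non-cases
#' of one group) yields a degenerate fit: the result is flagged, the odds
#' ratios are NA and are rendered as "Undefined" in reports; no exception
#' is raised.
#'
#' @param counts taxon count vector (one value per sample).
#' @param sf metadata frame aligned with `counts`.
#' @param outcome `"periodontitis"` or `"caries"`.
#' @param covariates adjustment covariate names.
#' @return object of class `disease_fit`: `or_group0`/`ci_group0` (PHEU),
#'   `or_group1`/`ci_group1` (PHIV), `interaction_estimate` (log OR
#'   difference), `interaction_p`, `degenerate` flag and the glm `fit`.
#' @export
fit_disease_model <- function(counts, sf,
                              outcome = c("periodontitis", "caries"),
                              covariates = default_covariates()) {
  outcome <- match.arg(outcome)
  y <- sf[[outcome]]
  if (anyNA(y)) stop("missing values in outcome '", outcome, "'")
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present overall")
  des <- build_design(sf, covariates, "none")
  dat <- des$data
  dat$y <- y
  dat$z <- log10_halfmin(counts)
  dat$log10_total_reads <- log10(sf$total_reads)
  terms <- c(des$terms, "z", "group:z", "log10_total_reads")
  f <- stats::reformulate(terms, response = "y")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- stats::coef(fit)
  V <- stats::vcov(fit)
  iz <- "z"; ii <- "groupPHIV:z"
  bz <- b[[iz]]; bi <- b[[ii]]
  se0 <- sqrt(V[iz, iz])
  se1 <- sqrt(V[iz, iz] + V[ii, ii] + 2 * V[iz, ii])
  sei <- sqrt(V[ii, ii])
  degenerate <- !fit$converged || anyNA(c(bz, bi, se0, se1, sei)) ||
    max(abs(c(bz, bi))) > 10 || max(c(se0, se1, sei)) > 10 || sep_warn
  res <- list(outcome = outcome,
              or_group0 = exp(bz),
              ci_group0 = exp(bz + c(-1.96, 1.96) * se0),
              or_group1 = exp(bz + bi),
              ci_group1 = exp(bz + bi + c(-1.96, 1.96) * se1),
              interaction_estimate = bi,
              interaction_se = sei,
              interaction_p = 2 * stats::pnorm(-abs(bi / sei)),
              degenerate = degenerate,
              n = nrow(dat), fit = fit)
  if (degenerate) {
    res$or_group0 <- res$or_group1 <- NA_real_
    res$ci_group0 <- res$ci_group1 <- c(NA_real_, NA_real_)
    res$interaction_p <- NA_real_
  }
  structure(res, class = "disease_fit")
}

#' @export
print.disease_fit <- function(x, ...) {
  cat(sprintf("disease_fit (%s, n = %d)\n", x$outcome, x$n))
  cat("  PHEU OR per tenfold: ",
      format_or(x$or_group0, x$ci_group0, x$degenerate), "\n", sep = "")
  cat("  PHIV OR per tenfold: ",
      format_or(x$or_group1, x$ci_group1, x$degenerate), "\n", sep = "")
  cat("  interaction p: ",
      if (x$degenerate) "Undefined" else sprintf("%.3g", x$interaction_p),
      "\n", sep = "")
  invisible(x)
}

#' Disease-association screen over a set of taxa
#'
#' Runs [fit_disease_model()] for each requested taxon (rows of the count
#' matrix) and, optionally, BH-adjusts the interaction p-values — the
#' convention for exploratory all-taxa runs, while the small primary
#' etiologic families are compared to 0.05 unadjusted.
#'
#' @param cm a [count_matrix()]
#' @param sf aligned metadata.
#' @param outcome `"periodontitis"` or `"caries"`.
#' @param taxa character vector of taxon ids (default: all rows).
#' @param adjust `"none"` (primary families) or `"BH"` (exploratory).
#' @param covariates adjustment covariates.
#' @return object of class `disease_screen` with a `results` data.frame.
#' @export
disease_screen <- function(cm, sf, outcome = c("periodontitis", "caries"),
                           taxa = NULL, adjust = c("none", "BH"),
                           covariates = default_covariates()) {
  outcome <- match.arg(outcome)
  adjust <- match.arg(adjust)
  if (is.null(taxa)) taxa <- rownames(cm$counts)
  missing_taxa <- setdiff(taxa, rownames(cm$counts))
  if (length(missing_taxa) > 0)
    warning("taxa not in count matrix: ", paste(missing_taxa, collapse = ", "))
  taxa <- intersect(taxa, rownames(cm$counts))
  rows <- lapply(taxa, function(id) {
    ft <- fit_disease_model(cm$counts[id, ], sf, outcome, covariates)
    data.frame(taxon_id = id, outcome = outcome,
               or_group0 = ft$or_group0, ci0_low = ft$ci_group0[1],
               ci0_high = ft$ci_group0[2], or_group1 = ft$or_group1,
               ci1_low = ft$ci_group1[1], ci1_high = ft$ci_group1[2],
               interaction_p = ft$interaction_p,
               degenerate = ft$degenerate, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (adjust == "BH" && nrow(res) > 0)
    res$interaction_p_adjust <- suppressMessages(
      bh_adjust(res$interaction_p)$p_adjust)
  structure(list(results = res, outcome = outcome, adjust = adjust,
                 n_samples = nrow(sf), call = match.call()),
            class = "disease_screen")
}

#' @export
print.disease_screen <- function(x, ...) {
  cat(sprintf("disease_screen (%s): %d taxa, %d samples\n",
              x$outcome, nrow(x$results), x$n_samples))
  df <- render_disease_table(x$results)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.disease_screen <- function(x, ...) x$results

#' Combined etiologic-set disease model
#'
#' Sums the counts of the set's taxa per sample, applies the half-minimum
#' log10 transform to the summed counts, and fits the interaction model
#' ([fit_disease_model()]) — e.g. "all periodontitis-associated organisms
#' combined".
#'
#' @param cm a [count_matrix()]
#' @param sf aligned metadata.
#' @param outcome `"periodontitis"` or `"caries"`.
#' @param set_ids taxon ids composing the set.
#' @param covariates adjustment covariates.
#' @return a `disease_fit` (with the set size in `$set_size`).
#' @export
fit_disease_set <- function(cm, sf, outcome, set_ids,
                            covariates = default_covariates()) {
  present <- intersect(set_ids, rownames(cm$counts))
  if (length(present) == 0) stop("no set taxa present in the count matrix")
  if (length(present) < length(set_ids))
    warning("set taxa missing from the count matrix: ",
            paste(setdiff(set_ids, present), collapse = ", "))
  total <- colSums(cm$counts[present, , drop = FALSE])
  ft <- fit_disease_model(total, sf, outcome, covariates)
  ft$set_size <- length(present)
  ft
}

#' Putatively etiologic taxa for periodontitis and caries
#'
#' Default taxon sets for the primary disease-association analyses: the
#' species (and two genus-level groupings) conventionally implicated in
#' periodontitis and in caries. Both lists are configurable — they are
#' matched against the count matrix's taxon ids, and absent members are
#' reported.
#'
#' @return named list with character vectors `periodontitis` (10 entries)
#'   and `caries` (11 entries).
#' @export
etiologic_sets <- function() {
  list(
    periodontitis = c("Prevotella nigrescens", "Tannerella forsythia",
                      "Desulfobulbus", "Dialister invisus",
                      "Aggregatibacter actinomycetemcomitans",
                      "Filifactor alocis", "Treponema denticola",
                      "Porphyromonas gingivalis", "Streptococcus anginosus",
                      "Streptococcus sobrinus"),
    caries = c("Veillonella sp. HOT 780", "Veillonella parvula",
               "Veillonella", "Veillonella rogosae", "Lactobacillus",
               "Veillonella atypica", "Lactobacillus salivarius",
               "Streptococcus mutans", "Bifidobacterium dentium",
               "Scardovia wiggsiae", "Streptococcus sobrinus"))
}

#' Group-by-disease prevalence cross-tabulation
#'
#' Counts and within-group percentages of every group x periodontitis x
#' caries cell — the cohort-description table of the analysis.
#'
#' @param sf validated metadata frame.
#' @return data.frame of class `prevalence_table` with columns `group`,
#'   `periodontitis`, `caries`, `n`, `pct` (percent of the group's total).
#' @export
prevalence_table <- function(sf) {
  if (anyNA(sf$periodontitis) || anyNA(sf$caries))
    stop("outcome labels must be non-missing")
  tab <- as.data.frame(table(
    group = factor(sf$group, levels = c("PHEU", "PHIV")),
    periodontitis = factor(sf$periodontitis, c(0, 1), c("No", "Yes")),
    caries = factor(sf$caries, c(0, 1), c("None", "Any"))),
    responseName = "n")
  grp_tot <- tapply(tab$n, tab$group, sum)
  tab$pct <- 100 * tab$n / as.numeric(grp_tot[tab$group])
  class(tab) <- c("prevalence_table", "data.frame")
  tab
}

#' @export
print.prevalence_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$cell <- sprintf("%d (%.1f)", df$n, df$pct)
  cat("Prevalence (n, % within group):\n")
  for (g in levels(df$group)) {
    cat(sprintf("  %s (N = %d)\n", g, sum(df$n[df$group == g])))
    for (p in c("No", "Yes")) {
      row <- df[df$group == g & df$periodontitis == p, ]
      cat(sprintf("    periodontitis %-3s: no caries %s, any caries %s\n", p,
                  row$cell[row$caries == "None"],
                  row$cell[row$caries == "Any"]))
    }
  }
  invisible(x)
}
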