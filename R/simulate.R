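#' Disease-outcome model for the cohort simulator
#'
#' Logistic model on the log10-count scale: for sample j with group
#' indicator g (1 = PHIV) and centered transformed taxon levels z_ij,
#' logit P(y_j = 1) = intercept + group_beta * g + sum_i slope_i * z_ij +
#' sum_i delta_i * g * z_ij. Taxon levels are transformed exactly as the
#' analysis transforms them (zeros replaced by half the taxon's minimum
#' non-zero count, then log10) and centered at their cohort mean so the
#' intercept stays interpretable as the baseline-prevalence logit.
#'
#' @param intercept log-odds of disease at g = 0 and average taxon levels.
#' @param group_beta group (PHIV) main effect on the log-odds scale.
#' @param slopes named numeric vector of per-taxon slopes (log-odds per
#'   tenfold count increase); names are taxon indices into the simulated
#'   matrix, e.g. `c("3" = 0.3)`.
#' @param interaction named numeric vector of group-by-taxon interaction
#'   log-odds-ratios (delta), same naming convention.
#' @return list of class `disease_model_config`.
#' @export
disease_model_config <- function(intercept = stats::qlogis(0.3),
                                 group_beta = 0,
                                 slopes = numeric(0),
                                 interaction = numeric(0)) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(group_beta), length(group_beta) == 1)
  if (length(slopes) > 0 && is.null(names(slopes)))
    stop("slopes must be named by taxon index")
  if (length(interaction) > 0 && is.null(names(interaction)))
    stop("interaction must be named by taxon index")
  structure(list(intercept = intercept, group_beta = group_beta,
                 slopes = slopes, interaction = interaction),
            class = "disease_model_config")
}

#' Configuration for the synthetic PHIV/PHEU cohort
#'
#' Defaults reproduce the dimensions of the study design the package
#' analyses: 154 PHIV and 100 PHEU participants, several hundred taxa, and
#' per-sample sequencing depths drawn log-uniformly between 1,330 and
#' 230,039 reads (the heavy right skew typical of amplicon depth
#' distributions). Per-taxon baseline abundances are drawn once, inside
#' this constructor, from a normal on the log scale and softmax-normalised
#' at simulation time; per-taxon negative-binomial size parameters are
#' drawn log-uniformly on `dispersion_range`. All per-taxon vectors are
#' realized here (with `set.seed(seed)`), so the returned object is a
#' complete, reproducible description of the generating process.
#'
#' @param n_group1,n_group0 PHIV and PHEU sample sizes.
#' @param n_taxa number of taxa.
#' @param depth_range min/max sequencing depth (reads per sample).
#' @param baseline_log_mean per-taxon log relative-abundance scores
#'   (softmax-normalised); drawn `rnorm(n_taxa, 0, baseline_log_sd)` when NULL.
#' @param dispersion per-taxon NB size parameter k (> 0; variance
#'   mu + mu^2/k); drawn log-uniformly on `dispersion_range` when NULL.
#' @param group_log_rr per-taxon log rate ratio (PHIV vs PHEU); default 0.
#' @param covariate_coefs named coefficients multiplying the covariates
#'   (age, sex, race_white, ethnicity_hispanic, dental_visit_past_year) in
#'   the log mean of every taxon.
#' @param disease_models named list with elements `periodontitis` and
#'   `caries`, each a [disease_model_config()].
#' @param antibiotic_prob probability of the antibiotic-use flag, per group
#'   (`c(group1 =, group0 =)`).
#' @param antibiotic_n optional exact number of flagged samples per group
#'   (`c(group1 =, group0 =)`); overrides `antibiotic_prob`.
#' @param baseline_log_sd SD of the baseline log-abundance draw.
#' @param dispersion_range range for the log-uniform dispersion draw.
#' @param seed integer seed; drives both the constructor's draws and (via
#'   `seed + 1`) the sampling in [simulate_cohort()].
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_group1 = 154L, n_group0 = 100L, n_taxa = 600L,
                          depth_range = c(1330L, 230039L),
                          baseline_log_mean = NULL,
                          dispersion = NULL,
                          group_log_rr = NULL,
                          covariate_coefs = c(age = 0, sex = 0,
                                              race_white = 0,
                                              ethnicity_hispanic = 0,
                                              dental_visit_past_year = 0),
                          disease_models = list(
                            periodontitis = disease_model_config(
                              intercept = stats::qlogis(0.30)),
                            caries = disease_model_config(
                              intercept = stats::qlogis(0.45),
                              group_beta = stats::qlogis(0.62) - stats::qlogis(0.45))),
                          antibiotic_prob = c(group1 = 0, group0 = 0),
                          antibiotic_n = NULL,
                          baseline_log_sd = 2,
                          dispersion_range = c(0.1, 2),
                          seed = 1L) {
  stopifnot(n_group1 >= 1, n_group0 >= 1, n_taxa >= 1,
            length(depth_range) == 2, depth_range[1] >= 1,
            depth_range[2] >= depth_range[1],
            all(antibiotic_prob >= 0 & antibiotic_prob <= 1),
            dispersion_range[1] > 0)
  set.seed(as.integer(seed))
  if (is.null(baseline_log_mean))
    baseline_log_mean <- stats::rnorm(n_taxa, 0, baseline_log_sd)
  if (is.null(dispersion))
    dispersion <- exp(stats::runif(n_taxa, log(dispersion_range[1]),
                                   log(dispersion_range[2])))
  if (is.null(group_log_rr)) group_log_rr <- rep(0, n_taxa)
  stopifnot(length(baseline_log_mean) == n_taxa,
            length(dispersion) == n_taxa,
            length(group_log_rr) == n_taxa)
  if (any(dispersion <= 0)) stop("dispersion (NB size) must be > 0")
  if (all(!is.finite(baseline_log_mean)))
    stop("degenerate config: no taxon has finite baseline abundance")
  if (!is.null(antibiotic_n))
    stopifnot(length(antibiotic_n) == 2,
              antibiotic_n[1] <= n_group1, antibiotic_n[2] <= n_group0)
  structure(list(n_group1 = as.integer(n_group1),
                 n_group0 = as.integer(n_group0),
                 n_taxa = as.integer(n_taxa),
                 depth_range = as.numeric(depth_range),
                 baseline_log_mean = baseline_log_mean,
                 dispersion = dispersion,
                 group_log_rr = group_log_rr,
                 covariate_coefs = covariate_coefs,
                 disease_models = disease_models,
                 antibiotic_prob = antibiotic_prob,
                 antibiotic_n = antibiotic_n,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d PHIV + %d PHEU samples, %d taxa, depths %s-%s, seed %d\n",
              x$n_group1, x$n_group0, x$n_taxa,
              format(x$depth_range[1], big.mark = ","),
              format(x$depth_range[2], big.mark = ","), x$seed))
  n_eff <- sum(x$group_log_rr != 0)
  cat(sprintf("  %d taxa with non-null group rate ratio\n", n_eff))
  invisible(x)
}

#' Study-scale cohort configuration with depleted and caries-linked taxa
#'
#' A [cohort_config()] at the study's dimensions (154 PHIV, 100 PHEU,
#' 600 taxa, depths 1,330-230,039) with added structure: three abundant
#' taxa strongly depleted in PHIV (rate ratios 0.15, 0.20, 0.25 — the
#' Corynebacterium-like "health-associated" pattern) and four taxa whose
#' counts raise the odds of caries with a positive group-by-taxon
#' interaction (delta = log 1.5).
#'
#' @param seed integer seed.
#' @return a `cohort_config`.
#' @export
phiv_pheu_config <- function(seed = 1L) {
  cfg <- cohort_config(seed = seed)
  ord <- order(cfg$baseline_log_mean, decreasing = TRUE)
  depleted <- ord[c(5L, 10L, 15L)]
  cfg$group_log_rr[depleted] <- log(c(0.15, 0.20, 0.25))
  caries_taxa <- ord[c(3L, 7L, 12L, 20L)]
  slopes <- rep(0.3, 4); interaction <- rep(log(1.5), 4)
  names(slopes) <- names(interaction) <- as.character(caries_taxa)
  cfg$disease_models$caries$slopes <- slopes
  cfg$disease_models$caries$interaction <- interaction
  cfg$effect_taxa <- list(depleted = depleted, caries = caries_taxa)
  cfg
}

#' Simulate a PHIV/PHEU cohort with known ground truth
#'
#' Draws per-sample covariates, log-uniform sequencing depths, taxon counts
#' from negative binomials whose means are depth x softmax-normalised
#' baseline abundance x exp(group and covariate effects), and binary
#' disease outcomes from the configured logistic models. Reproducible:
#' the same configuration (hence seed) yields bitwise-identical output.
#'
#' @param cfg a [cohort_config()].
#' @return list with elements `counts` (a [count_matrix()]), `metadata`
#'   (validated sample frame with `total_reads` equal to the realized
#'   column sums) and `truth` (the realized configuration plus drawn
#'   depths — everything needed for parameter-recovery checks).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed + 1L)
  n1 <- cfg$n_group1; n0 <- cfg$n_group0; n <- n1 + n0
  p <- exp(cfg$baseline_log_mean - max(cfg$baseline_log_mean,
                                       na.rm = TRUE))
  p[!is.finite(p)] <- 0
  if (sum(p) == 0) stop("degenerate config: all-zero taxon abundances")
  p <- p / sum(p)

  sample_id <- sprintf("S%04d", seq_len(n))
  group <- c(rep("PHIV", n1), rep("PHEU", n0))
  g <- as.integer(group == "PHIV")
  age <- stats::runif(n, 10, 22)
  sex <- stats::rbinom(n, 1, 0.5)
  race_white <- stats::rbinom(n, 1, 0.5)
  ethnicity_hispanic <- stats::rbinom(n, 1, 0.5)
  dental_visit_past_year <- stats::rbinom(n, 1, 0.5)
  if (!is.null(cfg$antibiotic_n)) {
    antibiotic_past_3mo <- integer(n)
    antibiotic_past_3mo[sample(which(g == 1), cfg$antibiotic_n[1])] <- 1L
    antibiotic_past_3mo[sample(which(g == 0), cfg$antibiotic_n[2])] <- 1L
  } else {
    pr <- ifelse(g == 1, cfg$antibiotic_prob[1], cfg$antibiotic_prob[2])
    antibiotic_past_3mo <- stats::rbinom(n, 1, pr)
  }
  depth <- round(exp(stats::runif(n, log(cfg$depth_range[1]),
                                  log(cfg$depth_range[2]))))

  cov_mat <- cbind(age = age, sex = sex, race_white = race_white,
                   ethnicity_hispanic = ethnicity_hispanic,
                   dental_visit_past_year = dental_visit_past_year)
  cc <- cfg$covariate_coefs
  cov_lp <- as.numeric(cov_mat[, names(cc), drop = FALSE] %*% cc)

  counts <- matrix(0, cfg$n_taxa, n,
                   dimnames = list(sprintf("t%04d", seq_len(cfg$n_taxa)),
                                   sample_id))
  depth_eff <- depth * exp(cov_lp)
  for (i in seq_len(cfg$n_taxa)) {
    mu <- depth_eff * p[i] * exp(cfg$group_log_rr[i] * g)
    counts[i, ] <- stats::rnbinom(n, size = cfg$dispersion[i], mu = mu)
  }

  # taxonomy: genera of five taxa, first row of each genus "genus-only"
  genus <- sprintf("g%03d", (seq_len(cfg$n_taxa) - 1L) %/% 5L + 1L)
  within <- (seq_len(cfg$n_taxa) - 1L) %% 5L
  species <- ifelse(within == 0L, "", sprintf("%s_sp%d", genus, within))
  taxonomy <- data.frame(taxon_id = rownames(counts), genus = genus,
                         species = species, stringsAsFactors = FALSE)

  draw_outcome <- function(dm) {
    lp <- rep(dm$intercept, n) + dm$group_beta * g
    for (tx in union(names(dm$slopes), names(dm$interaction))) {
      i <- as.integer(tx)
      x <- counts[i, ]
      if (all(x == 0)) {
        warning("disease-model taxon ", i, " has all-zero counts; skipped")
        next
      }
      z <- log10_halfmin(x)
      z <- z - mean(z)
      s <- if (tx %in% names(dm$slopes)) dm$slopes[[tx]] else 0
      d <- if (tx %in% names(dm$interaction)) dm$interaction[[tx]] else 0
      lp <- lp + s * z + d * g * z
    }
    stats::rbinom(n, 1, stats::plogis(lp))
  }
  periodontitis <- draw_outcome(cfg$disease_models$periodontitis)
  caries <- draw_outcome(cfg$disease_models$caries)

  metadata <- data.frame(sample_id = sample_id, group = group, age = age,
                         sex = sex, race_white = race_white,
                         ethnicity_hispanic = ethnicity_hispanic,
                         dental_visit_past_year = dental_visit_past_year,
                         antibiotic_past_3mo = antibiotic_past_3mo,
                         periodontitis = periodontitis, caries = caries,
                         total_reads = colSums(counts),
                         stringsAsFactors = FALSE)
  rownames(metadata) <- NULL
  if (any(metadata$total_reads == 0))
    warning("some simulated samples have zero total reads")
  cm <- count_matrix(counts, taxonomy)
  truth <- list(config = cfg,
                group_log_rr = cfg$group_log_rr,
                dispersion = cfg$dispersion,
                baseline_log_mean = cfg$baseline_log_mean,
                rel_abundance = p,
                depth = stats::setNames(depth, sample_id),
                seed = cfg$seed)
  list(counts = cm, metadata = metadata, truth = truth)
}
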