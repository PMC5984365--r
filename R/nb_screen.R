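default_covariates <- function() {
  c("age", "sex", "dental_visit_past_year", "race_white",
    "ethnicity_hispanic")
}

check_complete <- function(sf, cols) {
  bad <- cols[vapply(cols, function(cn) anyNA(sf[[cn]]), TRUE)]
  if (length(bad) > 0)
    stop("missing values in covariate column(s): ",
         paste(bad, collapse = ", "),
         " (no imputation is performed; exclude or complete these samples)")
}

## Build the adjustment design shared by the NB and logistic models.
## Returns a data.frame plus the right-hand-side terms; constant columns
## are dropped (with a message) so degenerate toy designs stay fittable,
## and genuine collinearity is reported as an error naming the columns.
build_design <- function(sf, covariates, total_reads_mode) {
  covariates <- intersect(covariates, names(sf))
  check_complete(sf, c(covariates, "total_reads"))
  dat <- data.frame(group = factor(sf$group, levels = c("PHEU", "PHIV")))
  for (cn in covariates) dat[[cn]] <- sf[[cn]]
  terms <- c("group", covariates)
  offset <- NULL
  if (total_reads_mode == "log-covariate") {
    dat$log_total_reads <- log(sf$total_reads)
    terms <- c(terms, "log_total_reads")
  } else if (total_reads_mode == "offset") {
    offset <- log(sf$total_reads)
  }
  const <- terms[vapply(terms, function(tn) {
    v <- dat[[tn]]
    length(unique(v)) < 2
  }, TRUE)]
  const <- setdiff(const, "group")
  if (length(const) > 0) {
    message("dropping constant covariate(s): ", paste(const, collapse = ", "))
    terms <- setdiff(terms, const)
  }
  if (length(unique(dat$group)) < 2) stop("both groups must be present")
  X <- stats::model.matrix(stats::reformulate(terms), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    alias <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(alias, collapse = ", "))
  }
  list(data = dat, terms = terms, offset = offset)
}

#' Negative binomial group comparison for one taxon
#'
#' Fits a log-link negative binomial regression of one taxon's counts on
#' group (PHIV vs PHEU reference) plus the adjustment covariates, with the
#' per-taxon dispersion estimated by maximum likelihood jointly with the
#' coefficients (via [MASS::glm.nb()]). The exponentiated group coefficient
#' is the rate ratio — the fold change in expected counts in PHIV relative
#' to PHEU — with a Wald 95% CI `exp(est +/- 1.96 se)` and two-sided Wald
#' p-value. Total sequencing reads enters, by default, as a log-scale
#' covariate with a free coefficient; `total_reads_mode = "offset"` fixes
#' its coefficient at 1 for sensitivity analysis.
#'
#' Non-convergence is not an exception: the result is returned with NA
#' estimates and `converged = FALSE`.
#'
#' @param counts integer count vector for one taxon (one value per sample).
#' @param sf metadata frame aligned with `counts`.
#' @param covariates adjustment covariate names (default: age, sex, dental
#'   visit in the past year, race white, ethnicity Hispanic).
#' @param total_reads_mode `"log-covariate"` (default), `"offset"`, or
#'   `"none"`.
#' @return object of class `taxon_nb`: log rate ratio `estimate`, `se`,
#'   `rate_ratio`, `ci` (length 2), `p_value`, `theta` (NB size), a
#'   `converged` flag, and the underlying `fit` when converged.
#' @examples
#' sf <- data.frame(group = rep(c("PHIV", "PHEU"), each = 20),
#'                  total_reads = 10000)
#' y <- rnbinom(40, mu = rep(c(40, 20), each = 20), size = 1)
#' fit_taxon_nb(y, sf, covariates = character(0), total_reads_mode = "none")
#' @export
fit_taxon_nb <- function(counts, sf,
                         covariates = default_covariates(),
                         total_reads_mode = c("log-covariate", "offset",
                                              "none")) {
  total_reads_mode <- match.arg(total_reads_mode)
  if (total_reads_mode == "none" && !"total_reads" %in% names(sf))
    sf$total_reads <- 1
  des <- build_design(sf, covariates, total_reads_mode)
  dat <- des$data
  dat$y <- as.numeric(counts)
  f <- stats::reformulate(des$terms, response = "y")
  msgs <- character(0)
  fit <- withCallingHandlers(
    tryCatch({
      if (is.null(des$offset)) MASS::glm.nb(f, data = dat)
      else {
        dat$.off <- des$offset
        MASS::glm.nb(stats::update(f, . ~ . + offset(.off)), data = dat)
      }
    }, error = function(e) e),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  bad <- inherits(fit, "error") || !isTRUE(fit$converged)
  if (bad) {
    return(structure(list(estimate = NA_real_, se = NA_real_,
                          rate_ratio = NA_real_, ci = c(NA_real_, NA_real_),
                          p_value = NA_real_, theta = NA_real_,
                          converged = FALSE,
                          message = if (inherits(fit, "error"))
                            conditionMessage(fit) else "IRLS did not converge",
                          fit = NULL),
                     class = "taxon_nb"))
  }
  co <- summary(fit)$coefficients
  est <- co["groupPHIV", "Estimate"]
  se <- co["groupPHIV", "Std. Error"]
  structure(list(estimate = est, se = se, rate_ratio = exp(est),
                 ci = exp(est + c(-1.96, 1.96) * se),
                 p_value = 2 * stats::pnorm(-abs(est / se)),
                 theta = fit$theta, converged = TRUE,
                 message = if (length(msgs)) paste(unique(msgs),
                                                   collapse = "; ") else NA_character_,
                 fit = fit),
            class = "taxon_nb")
}

#' @export
print.taxon_nb <- function(x, ...) {
  if (!x$converged) {
    cat("taxon_nb fit: did not converge (", x$message, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("taxon_nb fit: RR = %.3f (95%% CI %.3f, %.3f), p = %.3g, theta = %.3g\n",
              x$rate_ratio, x$ci[1], x$ci[2], x$p_value, x$theta))
  invisible(x)
}

#' Aggregate a count matrix to species or genus level
#'
#' `level = "species"` keeps the species-resolved rows as they are.
#' `level = "genus"` aggregates per genus: mode `"genus_only"` uses the
#' reads classified to the genus but not to any species (the rows with an
#' empty species field, i.e. subtracting out sequences also identified at
#' species level); mode `"total"` sums every row of the genus.
#'
#' @param cm a [count_matrix()]
#' @param level `"species"` or `"genus"`.
#' @param genus_mode `"genus_only"` (default) or `"total"`.
#' @return numeric matrix (units x samples) with descriptive row names.
#' @export
aggregate_counts <- function(cm, level = c("species", "genus"),
                             genus_mode = c("genus_only", "total")) {
  level <- match.arg(level)
  genus_mode <- match.arg(genus_mode)
  tax <- cm$taxonomy
  if (level == "species") {
    keep <- tax$species != ""
    m <- cm$counts[keep, , drop = FALSE]
    rownames(m) <- tax$taxon_id[keep]
    return(m)
  }
  rows <- if (genus_mode == "genus_only") which(tax$species == "")
          else seq_len(nrow(tax))
  if (length(rows) == 0) stop("no genus-level rows to aggregate")
  grp <- tax$genus[rows]
  m <- rowsum(cm$counts[rows, , drop = FALSE], grp, reorder = TRUE)
  m
}

#' Benjamini-Hochberg step-up decisions
#'
#' Rejects the k* smallest p-values where k* = max(k : p_(k) <= k q / m),
#' computed through [stats::p.adjust()] on the non-missing family (NA
#' p-values are excluded from m, counted in a message, and returned as NA
#' decisions).
#'
#' @param p p-values in (0, 1]; NA allowed.
#' @param q target false discovery rate (default 0.05).
#' @return list with `reject` (logical, NA where p was NA), `p_adjust`
#'   (BH-adjusted p-values) and `m` (family size used).
#' @export
bh_adjust <- function(p, q = 0.05) {
  stopifnot(q > 0, q < 1)
  ok <- !is.na(p)
  if (any(!ok))
    message(sum(!ok), " NA p-value(s) excluded from the BH family")
  adj <- rep(NA_real_, length(p))
  adj[ok] <- stats::p.adjust(p[ok], method = "BH")
  reject <- rep(NA, length(p))
  reject[ok] <- adj[ok] <= q
  list(reject = reject, p_adjust = adj, m = sum(ok))
}

#' Screen all taxa for group differences in average counts
#'
#' The central fitting function: one negative binomial regression per
#' taxon (see [fit_taxon_nb()]) at the species or genus level, followed by
#' Benjamini-Hochberg control at level `q` within the analysis level
#' (species- and genus-level runs are separate BH families). Non-converged
#' taxa are reported, flagged and excluded from the BH family.
#'
#' @param cm a filtered [count_matrix()]
#' @param sf metadata frame aligned with `cm` (samples in matching order).
#' @param level `"species"` or `"genus"`.
#' @param genus_mode see [aggregate_counts()].
#' @param q BH false discovery rate.
#' @param covariates,total_reads_mode passed to [fit_taxon_nb()].
#' @return object of class `taxon_screen` with a `results` data.frame
#'   (taxon_id, estimate = log RR, se, rate_ratio, ci_low, ci_high,
#'   p_value, theta, converged, p_adjust, significant) and metadata about
#'   the run. Methods: `print`, `summary`, `coef` (named log rate ratios),
#'   `plot` (rate-ratio interval plot), `as.data.frame`.
#' @export
taxon_screen <- function(cm, sf, level = c("species", "genus"),
                         genus_mode = c("genus_only", "total"), q = 0.05,
                         covariates = default_covariates(),
                         total_reads_mode = c("log-covariate", "offset",
                                              "none")) {
  level <- match.arg(level)
  genus_mode <- match.arg(genus_mode)
  total_reads_mode <- match.arg(total_reads_mode)
  stopifnot(ncol(cm$counts) == nrow(sf))
  m <- aggregate_counts(cm, level, genus_mode)
  ids <- rownames(m)
  rows <- lapply(ids, function(id) {
    ft <- fit_taxon_nb(m[id, ], sf, covariates, total_reads_mode)
    data.frame(taxon_id = id, estimate = ft$estimate, se = ft$se,
               rate_ratio = ft$rate_ratio, ci_low = ft$ci[1],
               ci_high = ft$ci[2], p_value = ft$p_value, theta = ft$theta,
               converged = ft$converged, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_for_bh <- ifelse(res$converged, res$p_value, NA_real_)
  bh <- suppressMessages(bh_adjust(p_for_bh, q))
  res$p_adjust <- bh$p_adjust
  res$significant <- ifelse(is.na(bh$reject), FALSE, bh$reject)
  n_nc <- sum(!res$converged)
  if (n_nc > 0)
    message(n_nc, " taxa did not converge and were excluded from the BH family")
  structure(list(results = res, level = level, genus_mode = genus_mode,
                 q = q, n_samples = ncol(cm$counts),
                 n_taxa = nrow(res), bh_family_size = bh$m,
                 covariates = covariates,
                 total_reads_mode = total_reads_mode,
                 call = match.call()),
            class = "taxon_screen")
}

#' @export
print.taxon_screen <- function(x, ...) {
  cat(sprintf("taxon_screen (%s level): %d taxa, %d samples\n",
              x$level, x$n_taxa, x$n_samples))
  cat(sprintf("  BH family m = %d (q = %g): %d significant; %d non-converged\n",
              x$bh_family_size, x$q, sum(x$results$significant),
              sum(!x$results$converged)))
  if ("noteworthy" %in% names(x$results))
    cat(sprintf("  %d noteworthy (FPRP/BFDP rule at prior %g)\n",
                sum(x$results$noteworthy, na.rm = TRUE),
                x$noteworthiness$flag_prior))
  invisible(x)
}

#' @export
summary.taxon_screen <- function(object, ...) {
  res <- object$results[order(object$results$p_value), ]
  structure(list(screen = object, ordered = res), class = "summary.taxon_screen")
}

#' @export
print.summary.taxon_screen <- function(x, ...) {
  print(x$screen)
  sig <- x$ordered[x$ordered$significant %in% TRUE, ]
  if (nrow(sig) > 0) {
    cat("\nSignificant taxa (BH):\n")
    print(format_screen_table(sig), row.names = FALSE)
  } else cat("\nNo significant taxa.\n")
  invisible(x)
}

#' @export
coef.taxon_screen <- function(object, ...) {
  stats::setNames(object$results$estimate, object$results$taxon_id)
}

#' @export
as.data.frame.taxon_screen <- function(x, ...) x$results

#' @export
plot.taxon_screen <- function(x, n_top = 20, ...) {
  res <- x$results[x$results$converged, ]
  res <- res[order(res$p_value), ]
  res <- utils::head(res, n_top)
  res <- res[nrow(res):1, ]
  rng <- range(c(res$ci_low, res$ci_high, 1), finite = TRUE)
  graphics::plot(res$rate_ratio, seq_len(nrow(res)), log = "x",
                 xlim = rng, yaxt = "n", ylab = "",
                 xlab = "rate ratio (PHIV vs PHEU)",
                 pch = ifelse(res$significant, 19, 1), ...)
  graphics::segments(res$ci_low, seq_len(nrow(res)),
                     res$ci_high, seq_len(nrow(res)))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(nrow(res)), labels = res$taxon_id,
                 las = 1, cex.axis = 0.6)
  invisible(x)
}
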