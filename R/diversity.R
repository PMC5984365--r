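#' Shannon diversity index
#'
#' H = -sum p_i log_base(p_i) over taxa with positive counts. Base defaults
#' to 2 (the QIIME convention), so H is in bits; the base used is attached
#' as an attribute.
#'
#' @param x non-negative count (or proportion) vector.
#' @param base logarithm base.
#' @return Shannon index (numeric scalar, attribute `base`).
#' @export
shannon_index <- function(x, base = 2) {
  if (all(x == 0)) stop("all-zero count vector")
  h <- vegan::diversity(x, index = "shannon", base = base)
  structure(as.numeric(h), base = base)
}

#' Simpson diversity index (1 - D)
#'
#' 1 - sum p_i^2: the probability that two reads drawn at random belong to
#' different taxa. Ranges over [0, 1) and is invariant to rescaling the
#' counts.
#'
#' @param x non-negative count vector.
#' @return numeric scalar in [0, 1).
#' @export
simpson_index <- function(x) {
  if (all(x == 0)) stop("all-zero count vector")
  as.numeric(vegan::diversity(x, index = "simpson"))
}

#' Analytic rarefaction curve for one sample
#'
#' Expected richness in a random subsample of n reads drawn without
#' replacement: E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n)),
#' the hypergeometric expectation. At n = N this equals the observed
#' richness. An optional Monte-Carlo mode subsamples explicitly.
#'
#' @param x non-negative count vector for one sample.
#' @param depths integer subsample sizes (all <= sum(x)).
#' @param mc number of Monte-Carlo subsampling replicates; 0 (default)
#'   uses the exact hypergeometric expectation.
#' @return data.frame with columns `depth` and `richness`.
#' @export
rarefaction_curve <- function(x, depths, mc = 0) {
  if (all(x == 0)) stop("all-zero count vector")
  N <- sum(x)
  if (any(depths > N))
    stop("subsample depth exceeds sample total (", N, ")")
  if (any(depths < 1)) stop("depths must be >= 1")
  if (mc > 0) {
    pool <- rep.int(seq_along(x), x)
    rich <- vapply(depths, function(n) {
      mean(vapply(seq_len(mc),
                  function(r) length(unique(sample(pool, n))), 0))
    }, 0)
  } else {
    # vegan::rarefy warns when no count equals 1; purely diagnostic here
    rich <- withCallingHandlers(
      as.numeric(vegan::rarefy(x, sample = depths)),
      warning = function(w) {
        if (grepl("counts 1", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  data.frame(depth = depths, richness = rich)
}

#' Per-sample alpha diversity table
#'
#' Observed richness, Shannon (configurable log base) and Simpson 1 - D for
#' every sample, computed on unrarefied counts.
#'
#' @param cm a [count_matrix()]
#' @param base Shannon log base.
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `simpson` (attribute `shannon_base` records the base).
#' @export
alpha_diversity <- function(cm, base = 2) {
  m <- cm$counts
  out <- data.frame(
    sample_id = colnames(m),
    richness = colSums(m > 0),
    shannon = apply(m, 2, function(x) as.numeric(shannon_index(x, base))),
    simpson = apply(m, 2, simpson_index),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "shannon_base") <- base
  out
}

#' Rarefaction curves for deeply sequenced samples
#'
#' Computes analytic rarefaction curves for every sample whose total reads
#' meet `min_total` (shallower samples are excluded from this analysis);
#' the default depth grid runs from 1,000 reads up to `min_total`.
#'
#' @param cm a [count_matrix()]
#' @param depths integer depth grid; defaults to ten points spanning
#'   1,000..`min_total`.
#' @param min_total minimum sample total for inclusion (default 65,000).
#' @return data.frame (class `rarefaction_curves`) in long format:
#'   `sample_id`, `group` (if supplied), `depth`, `richness`.
#' @param sf optional metadata for group labels.
#' @export
rarefaction_curves <- function(cm, sf = NULL, depths = NULL,
                               min_total = 65000) {
  tot <- sample_sums(cm)
  keep <- names(tot)[tot >= min_total]
  if (length(keep) == 0) stop("no sample reaches min_total = ", min_total)
  if (is.null(depths))
    depths <- unique(round(seq(min(1000, min_total), min_total,
                               length.out = 10)))
  out <- do.call(rbind, lapply(keep, function(s) {
    cbind(sample_id = s, rarefaction_curve(cm$counts[, s], depths))
  }))
  if (!is.null(sf))
    out$group <- sf$group[match(out$sample_id, sf$sample_id)]
  class(out) <- c("rarefaction_curves", "data.frame")
  out
}

#' @export
plot.rarefaction_curves <- function(x, ...) {
  has_grp <- "group" %in% names(x)
  cols <- if (has_grp) ifelse(x$group == "PHIV", "firebrick", "steelblue") else "grey30"
  graphics::plot(x$depth, x$richness, type = "n",
                 xlab = "reads subsampled", ylab = "expected richness", ...)
  for (s in unique(x$sample_id)) {
    i <- x$sample_id == s
    graphics::lines(x$depth[i], x$richness[i], col = cols[i][1])
  }
  if (has_grp)
    graphics::legend("bottomright", legend = c("PHIV", "PHEU"),
                     col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Two-sample comparison of a diversity measure
#'
#' t test of a per-sample diversity value between the PHIV and PHEU groups.
#' Welch's unequal-variance test is the default (diversity distributions
#' are typically skewed with unequal spread); set `var_equal = TRUE` for
#' Student's test.
#'
#' @param values numeric per-sample values.
#' @param groups group labels (two levels).
#' @param var_equal use the pooled-variance Student test.
#' @return list with `statistic` (t), `p_value`, `group_means`, `method`.
#' @export
diversity_ttest <- function(values, groups, var_equal = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("need >= 2 samples per group")
  tt <- stats::t.test(values ~ groups, var.equal = var_equal)
  list(statistic = unname(tt$statistic),
       p_value = tt$p.value,
       group_means = tapply(values, groups, mean),
       method = tt$method)
}
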