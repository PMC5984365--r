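# Independent oracles and fixture builders used across the suite.

# Brute-force BH step-up: reject hypotheses 1..k* in sorted order where
# k* = max{k : p_(k) <= k q / m}; independent of stats::p.adjust.
bh_brute <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  reject <- rep(FALSE, m)
  if (length(ok) > 0) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# Exact rarefaction by exhaustive enumeration of all subsets of n reads
# (feasible only for tiny totals).
rarefy_enum <- function(x, n) {
  reads <- rep.int(seq_along(x), x)
  subsets <- utils::combn(length(reads), n)
  mean(apply(subsets, 2, function(i) length(unique(reads[i]))))
}

# Direct-formula Shannon (base b) and Simpson 1-D, written independently
# of the package implementation.
shannon_direct <- function(x, base = 2) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p, base = base))
}
simpson_direct <- function(x) {
  p <- x / sum(x)
  1 - sum(p^2)
}

# Valid per-sample metadata frame with randomized covariates.
make_sf <- function(n1 = 30, n0 = 20, seed = 1, total_reads = NULL) {
  set.seed(seed)
  n <- n1 + n0
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    group = rep(c("PHIV", "PHEU"), c(n1, n0)),
    age = runif(n, 10, 22),
    sex = rbinom(n, 1, 0.5),
    race_white = rbinom(n, 1, 0.5),
    ethnicity_hispanic = rbinom(n, 1, 0.5),
    dental_visit_past_year = rbinom(n, 1, 0.5),
    antibiotic_past_3mo = 0L,
    periodontitis = rbinom(n, 1, 0.3),
    caries = rbinom(n, 1, 0.5),
    total_reads = if (is.null(total_reads)) round(runif(n, 2000, 80000))
                  else total_reads,
    stringsAsFactors = FALSE)
}

# Random small count matrix with matching metadata.
make_cm <- function(n_taxa = 10, n_samples = 8, seed = 1, lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)),
                              sprintf("s%03d", seq_len(n_samples))))
  count_matrix(m)
}
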