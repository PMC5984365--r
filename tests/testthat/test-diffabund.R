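test_that("saturated two-group NB fit recovers the ratio of group means", {
  sf <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("PHIV", "PHEU"), each = 3),
    total_reads = 1000)
  y <- c(10, 20, 30, 5, 10, 15)
  ft <- suppressMessages(
    fit_taxon_nb(y, sf, covariates = character(0),
                 total_reads_mode = "none"))
  expect_true(ft$converged)
  expect_equal(ft$rate_ratio, 2.0, tolerance = 1e-6)
  expect_equal(ft$ci, exp(ft$estimate + c(-1.96, 1.96) * ft$se),
               tolerance = 1e-12)
  # constant total-reads covariate must be dropped, not crash the fit
  ft2 <- suppressMessages(
    fit_taxon_nb(y, sf, covariates = character(0),
                 total_reads_mode = "log-covariate"))
  expect_equal(ft2$rate_ratio, 2.0, tolerance = 1e-6)
})

test_that("rate ratio inverts under reference-group relabeling", {
  set.seed(14)
  sf <- make_sf(25, 25, seed = 14)
  y <- rnbinom(50, mu = ifelse(sf$group == "PHIV", 40, 20), size = 1)
  ft <- fit_taxon_nb(y, sf)
  sf_sw <- sf
  sf_sw$group <- ifelse(sf$group == "PHIV", "PHEU", "PHIV")
  ft_sw <- fit_taxon_nb(y, sf_sw)
  expect_equal(ft_sw$estimate, -ft$estimate, tolerance = 1e-6)
  expect_equal(ft_sw$se, ft$se, tolerance = 1e-6)
})

test_that("rank-deficient designs error naming the collinear column", {
  sf <- make_sf(10, 10, seed = 3)
  sf$age_copy <- sf$age
  y <- rpois(20, 20)
  expect_error(
    fit_taxon_nb(y, sf, covariates = c("age", "age_copy")),
    "collinear.*age_copy")
})

test_that("non-convergence yields a flagged NA result, not an exception", {
  sf <- make_sf(5, 5, seed = 4)
  y <- rep(0, 10)
  ft <- suppressMessages(fit_taxon_nb(y, sf))
  expect_false(ft$converged)
  expect_true(is.na(ft$estimate))
  expect_true(is.na(ft$p_value))
})

test_that("genus aggregation separates genus-only from total reads", {
  m <- matrix(c(10, 20, 5, 7,
                10, 20, 5, 7), 4, 2,
              dimnames = list(c("sp1", "sp2", "gonly", "other"),
                              c("s1", "s2")))
  tax <- data.frame(taxon_id = rownames(m),
                    genus = c("GenusA", "GenusA", "GenusA", "GenusB"),
                    species = c("A sp1", "A sp2", "", "B sp"),
                    stringsAsFactors = FALSE)
  cm <- count_matrix(m, tax)
  only <- aggregate_counts(cm, "genus", "genus_only")
  expect_equal(unname(only["GenusA", ]), c(5, 5))
  expect_false("GenusB" %in% rownames(only))  # no genus-only reads
  total <- aggregate_counts(cm, "genus", "total")
  expect_equal(unname(total["GenusA", ]), c(35, 35))
  expect_equal(unname(total["GenusB", ]), c(7, 7))
  sp <- aggregate_counts(cm, "species")
  expect_equal(rownames(sp), c("sp1", "sp2", "other"))
})

test_that("BH step-up matches the spec examples and brute force", {
  bh <- bh_adjust(c(0.01, 0.012, 0.03, 0.2), q = 0.05)
  expect_equal(sum(bh$reject), 3)
  expect_equal(bh_adjust(rep(1, 6))$reject, rep(FALSE, 6))
  expect_equal(bh_adjust(rep(1e-9, 6))$reject, rep(TRUE, 6))

  set.seed(17)
  for (r in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    p[p == 0] <- 1e-4
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_adjust(p, q)$reject, bh_brute(p, q))
  }
})

test_that("NA p-values are excluded from the BH family", {
  p <- c(0.01, NA, 0.04, NA, 0.5)
  expect_message(bh <- bh_adjust(p, 0.05), "2 NA")
  expect_identical(is.na(bh$reject), is.na(p))
  expect_equal(bh$m, 3)
  expect_identical(bh$reject[!is.na(p)], bh_brute(p[!is.na(p)], 0.05))
})

test_that("screening a cohort returns one row per unit and flags BH hits", {
  rr <- rep(0, 60); rr[1] <- log(0.15)
  cfg <- cohort_config(n_group1 = 60, n_group0 = 40, n_taxa = 60,
                       baseline_log_mean = rep(0, 60),
                       dispersion = rep(0.8, 60), group_log_rr = rr,
                       seed = 77)
  sim <- simulate_cohort(cfg)
  scr <- suppressMessages(taxon_screen(sim$counts, sim$metadata,
                                       level = "species"))
  expect_s3_class(scr, "taxon_screen")
  expect_equal(nrow(scr$results), sum(sim$counts$taxonomy$species != ""))
  # the strongly depleted taxon is species "t0002" (t0001 is genus-only)
  expect_true(all(c("p_adjust", "significant") %in% names(scr$results)))
  expect_equal(length(coef(scr)), nrow(scr$results))
  gscr <- suppressMessages(taxon_screen(sim$counts, sim$metadata,
                                        level = "genus"))
  expect_equal(nrow(gscr$results), length(unique(sim$counts$taxonomy$genus)))
})

test_that("log rate ratio estimates center on the truth at RR 0.2", {
  est <- c()
  for (r in 1:25) {
    rr <- rep(0, 120); rr[1] <- log(0.2)
    cfg <- cohort_config(n_taxa = 120, baseline_log_mean = rep(0, 120),
                         dispersion = rep(0.5, 120), group_log_rr = rr,
                         seed = 5000 + r)
    sim <- simulate_cohort(cfg)
    ft <- fit_taxon_nb(sim$counts$counts[1, ], sim$metadata)
    if (ft$converged) est <- c(est, ft$estimate)
  }
  expect_gt(length(est), 20)
  expect_lt(abs(mean(est) - log(0.2)), 0.15)
})
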