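# Sample roster shaped like the study: 173 + 106 samples with 19 + 6
# antibiotic flags; the exclusion must leave 154/100.
test_that("antibiotic exclusion reproduces the study's accounting", {
  cfg <- cohort_config(n_group1 = 173, n_group0 = 106, n_taxa = 15,
                       antibiotic_n = c(19, 6), seed = 8)
  sim <- simulate_cohort(cfg)
  st <- exclude_antibiotic_users(sim$counts, sim$metadata)
  expect_equal(st$report$n_in, 279)
  expect_equal(st$report$n_removed, 25)
  expect_equal(st$report$n_out, 254)
  expect_equal(unname(table(st$metadata$group)[c("PHIV", "PHEU")]),
               c(154L, 100L), ignore_attr = TRUE)
  expect_equal(st$report$removed_by_group$PHIV, 19)
  expect_equal(ncol(st$counts$counts), 254)
})

test_that("antibiotic exclusion handles no-flag and all-flag extremes", {
  cm <- make_cm(5, 6, seed = 2)
  sf <- make_sf(3, 3, seed = 2)
  st <- exclude_antibiotic_users(cm, sf)
  expect_identical(st$counts$counts, cm$counts)
  expect_equal(st$report$n_removed, 0)

  sf$antibiotic_past_3mo <- 1L
  expect_warning(st2 <- exclude_antibiotic_users(cm, sf), "all samples")
  expect_equal(ncol(st2$counts$counts), 0)
})

test_that("low-read sample drop uses a strict < threshold", {
  m <- matrix(c(199, 200, 201), 1, 3,
              dimnames = list("t1", c("a", "b", "c")))
  st <- drop_low_read_samples(count_matrix(m), min_reads = 200)
  expect_equal(colnames(st$counts$counts), c("b", "c"))
  expect_equal(st$report$removed_ids, "a")

  all_ok <- drop_low_read_samples(count_matrix(m + 10), min_reads = 200)
  expect_equal(all_ok$report$n_removed, 0)
})

test_that("rare-taxon drop uses pooled relative abundance, strict <", {
  m <- matrix(0, 3, 2, dimnames = list(c("rare", "exact", "common"),
                                       c("s1", "s2")))
  m["rare", 1] <- 1          # 1 / 1e5 = 1e-5? grand total set below
  m["exact", ] <- c(1, 0)
  m["common", ] <- c(49999, 49999)
  # grand total 1e5: rare and exact both at exactly 1e-5 -> retained;
  # use threshold just above to remove
  cm <- count_matrix(m)
  st <- drop_rare_taxa(cm, threshold = 1e-5)
  expect_equal(sort(rownames(st$counts$counts)),
               c("common", "exact", "rare"))  # exactly at threshold kept
  st2 <- drop_rare_taxa(cm, threshold = 1.01e-5)
  expect_false("rare" %in% rownames(st2$counts$counts))
})

test_that("prevalence drop uses a strict < min_subjects rule", {
  set.seed(4)
  m <- matrix(0, 3, 12, dimnames = list(c("in9", "in10", "zero"),
                                        sprintf("s%02d", 1:12)))
  m["in9", 1:9] <- 1
  m["in10", 1:10] <- 1
  st <- drop_low_prevalence_taxa(count_matrix(m), min_subjects = 10)
  expect_equal(rownames(st$counts$counts), "in10")
  expect_equal(sort(st$report$removed_ids), c("in9", "zero"))
})

test_that("filters agree with brute-force scans on random matrices", {
  for (seed in 1:5) {
    cm <- make_cm(30, 15, seed = seed, lambda = 2)
    tot <- colSums(cm$counts)
    st <- drop_low_read_samples(cm, min_reads = 30)
    expect_equal(sort(st$report$removed_ids), sort(names(tot)[tot < 30]))

    rel <- rowSums(cm$counts) / sum(cm$counts)
    st2 <- drop_rare_taxa(cm, threshold = 0.02)
    expect_equal(sort(st2$report$removed_ids),
                 sort(rownames(cm$counts)[rel < 0.02]))

    prev <- rowSums(cm$counts > 0)
    st3 <- drop_low_prevalence_taxa(cm, min_subjects = 14)
    expect_equal(sort(st3$report$removed_ids),
                 sort(rownames(cm$counts)[prev < 14]))
  }
})

test_that("each filter is idempotent and conserves counts", {
  cm <- make_cm(40, 20, seed = 6, lambda = 1)
  sf <- make_sf(12, 8, seed = 6)
  sf$antibiotic_past_3mo[c(1, 5)] <- 1L

  st <- exclude_antibiotic_users(cm, sf)
  st_again <- exclude_antibiotic_users(st$counts, st$metadata)
  expect_identical(st_again$counts$counts, st$counts$counts)

  for (f in list(function(x) drop_low_read_samples(x, min_reads = 10),
                 function(x) drop_rare_taxa(x, threshold = 5e-3),
                 function(x) drop_low_prevalence_taxa(x, min_subjects = 5))) {
    once <- f(cm)
    twice <- f(once$counts)
    expect_identical(twice$counts$counts, once$counts$counts)
    expect_equal(once$report$n_in, once$report$n_out + once$report$n_removed)
    expect_equal(twice$report$n_removed, 0)
  }
})

test_that("the cascade drops UNMATCHED rows and keeps accounting consistent", {
  cm <- make_cm(20, 16, seed = 9, lambda = 5)
  rownames(cm$counts)[20] <- "UNMATCHED"
  cm$taxonomy$taxon_id[20] <- "UNMATCHED"
  sf <- make_sf(9, 7, seed = 9)
  sf$antibiotic_past_3mo[1] <- 1L
  res <- suppressMessages(apply_filters(cm, sf, min_reads = 10,
                                        min_rel_abund = 1e-4,
                                        min_subjects = 2))
  expect_false("UNMATCHED" %in% rownames(res$counts$counts))
  expect_equal(res$reports$unmatched$n_removed, 1)
  for (r in res$reports)
    expect_equal(r$n_in, r$n_out + r$n_removed)
  expect_equal(res$reports$antibiotic_use$n_removed, 1)
  expect_equal(ncol(res$counts$counts), nrow(res$metadata))
})
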