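test_that("half-minimum log10 transform follows its definition", {
  expect_equal(log10_halfmin(c(0, 10, 1000)),
               c(log10(5), 1, 3), tolerance = 1e-12)
  x <- c(3, 7, 21)
  expect_equal(log10_halfmin(x), log10(x))
  expect_error(log10_halfmin(c(0, 0)), "all-zero")
  set.seed(8)
  for (r in 1:10) {
    x <- rpois(30, 3)
    if (all(x == 0)) next
    z <- log10_halfmin(x)
    expect_equal(order(z), order(x))          # rank-preserving
    expect_true(all(diff(sort(z)[!duplicated(sort(x))]) > 0))
  }
})

test_that("interaction model reports per-group ORs per tenfold increase", {
  set.seed(19)
  sf <- make_sf(80, 80, seed = 19)
  g <- as.integer(sf$group == "PHIV")
  z <- rnorm(160, 2, 0.8)
  lp <- qlogis(0.35) + 0.8 * (z - 2) + log(2) * g * (z - 2)
  sf$periodontitis <- rbinom(160, 1, plogis(lp))
  counts <- round(10^z)
  ft <- fit_disease_model(counts, sf, "periodontitis")
  expect_s3_class(ft, "disease_fit")
  expect_false(ft$degenerate)
  # PHIV OR should exceed PHEU OR (positive interaction built in)
  expect_gt(ft$or_group1, ft$or_group0)
  expect_true(ft$ci_group0[1] < ft$or_group0 &
              ft$or_group0 < ft$ci_group0[2])
})

test_that("per-group ORs are invariant to reference relabeling", {
  set.seed(23)
  sf <- make_sf(50, 50, seed = 23)
  counts <- rnbinom(100, mu = 30, size = 1) + 1
  ft <- fit_disease_model(counts, sf, "caries")
  sf_sw <- sf
  sf_sw$group <- ifelse(sf$group == "PHIV", "PHEU", "PHIV")
  ft_sw <- fit_disease_model(counts, sf_sw, "caries")
  expect_equal(ft_sw$or_group0, ft$or_group1, tolerance = 1e-6)
  expect_equal(ft_sw$or_group1, ft$or_group0, tolerance = 1e-6)
  expect_equal(ft_sw$interaction_p, ft$interaction_p, tolerance = 1e-6)
})

test_that("separation is flagged degenerate, not raised", {
  set.seed(29)
  sf <- make_sf(40, 40, seed = 29)
  y <- rpois(80, 5) + 1
  y[sf$group == "PHEU" & sf$periodontitis == 1] <- 0
  ft <- fit_disease_model(y, sf, "periodontitis")
  expect_true(ft$degenerate)
  expect_true(is.na(ft$or_group0))
  expect_match(format_or(ft$or_group0, ft$ci_group0, ft$degenerate),
               "Undefined")
})

test_that("Wald and LRT interaction tests agree on well-conditioned fits", {
  set.seed(31)
  diffs <- vapply(1:15, function(r) {
    sf <- make_sf(60, 60, seed = 300 + r)
    g <- as.integer(sf$group == "PHIV")
    z <- rnorm(120, 2, 0.7)
    sf$caries <- rbinom(120, 1, plogis(-0.3 + 0.4 * (z - 2) +
                                         0.5 * g * (z - 2)))
    ft <- fit_disease_model(round(10^z), sf, "caries")
    f1 <- ft$fit
    f0 <- stats::glm(stats::update(formula(f1), . ~ . - group:z),
                     family = binomial(), data = f1$model)
    lrt_p <- pchisq(2 * (logLik(f1) - logLik(f0))[1], 1, lower.tail = FALSE)
    abs(-log10(ft$interaction_p) + log10(lrt_p))
  }, 0)
  expect_lt(mean(diffs), 0.3)
})

test_that("combined-set models reduce correctly", {
  cm <- make_cm(6, 60, seed = 37, lambda = 15)
  sf <- make_sf(35, 25, seed = 37)
  single <- fit_disease_set(cm, sf, "caries", "t01")
  direct <- fit_disease_model(cm$counts["t01", ], sf, "caries")
  expect_equal(single$or_group0, direct$or_group0, tolerance = 1e-10)
  expect_equal(single$interaction_p, direct$interaction_p,
               tolerance = 1e-10)

  pair <- fit_disease_set(cm, sf, "caries", c("t01", "t02"))
  summed <- fit_disease_model(colSums(cm$counts[c("t01", "t02"), ]),
                              sf, "caries")
  expect_equal(pair$or_group0, summed$or_group0, tolerance = 1e-10)
  expect_warning(fit_disease_set(cm, sf, "caries", c("t01", "nope")),
                 "nope")
  expect_error(fit_disease_set(cm, sf, "caries", "nope"), "no set taxa")
})

test_that("disease screen renders Undefined for degenerate rows", {
  set.seed(41)
  cm <- make_cm(3, 80, seed = 41, lambda = 8)
  sf <- make_sf(40, 40, seed = 41)
  cm$counts["t02", sf$group == "PHEU" & sf$periodontitis == 1] <- 0
  scr <- disease_screen(cm, sf, "periodontitis")
  expect_equal(nrow(scr$results), 3)
  expect_true(scr$results$degenerate[scr$results$taxon_id == "t02"])
  printed <- capture.output(print(scr))
  expect_true(any(grepl("Undefined", printed)))
})

test_that("prevalence table reproduces the cohort cross-tabulation", {
  # cross-tab shaped like the study: PHEU 38/32/17/13, PHIV 34/68/24/28
  cells <- rbind(
    expand.grid(group = "PHEU", periodontitis = c(0, 1), caries = c(0, 1)),
    expand.grid(group = "PHIV", periodontitis = c(0, 1), caries = c(0, 1)))
  cells$n <- c(38, 17, 32, 13, 34, 24, 68, 28)
  sf <- cells[rep(seq_len(nrow(cells)), cells$n), 1:3]
  sf$sample_id <- sprintf("s%03d", seq_len(nrow(sf)))
  pt <- prevalence_table(sf)
  phiv_pyes_cno <- pt[pt$group == "PHIV" & pt$periodontitis == "Yes" &
                        pt$caries == "None", ]
  expect_equal(phiv_pyes_cno$n, 24)
  expect_equal(round(phiv_pyes_cno$pct, 1), 15.6)

  one <- data.frame(group = rep("PHIV", 5), periodontitis = 1, caries = 1,
                    sample_id = letters[1:5])
  pt1 <- prevalence_table(one)
  expect_equal(pt1$pct[pt1$n == 5], 100)

  set.seed(43)
  rnd <- make_sf(20, 20, seed = 43)
  ptr <- prevalence_table(rnd)
  brute <- as.data.frame(table(rnd$group, rnd$periodontitis, rnd$caries))
  expect_equal(sum(ptr$n), 40)
  for (i in seq_len(nrow(ptr))) {
    g <- as.character(ptr$group[i])
    p <- as.integer(ptr$periodontitis[i] == "Yes")
    cc <- as.integer(ptr$caries[i] == "Any")
    expect_equal(ptr$n[i],
                 sum(rnd$group == g & rnd$periodontitis == p &
                       rnd$caries == cc))
  }
})

test_that("etiologic sets have the expected sizes", {
  sets <- etiologic_sets()
  expect_length(sets$periodontitis, 10)
  expect_length(sets$caries, 11)
  expect_true("Streptococcus sobrinus" %in% sets$periodontitis)
  expect_true("Streptococcus mutans" %in% sets$caries)
})
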