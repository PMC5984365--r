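---
title: "Statistical methods behind plaquescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind plaquescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquescreen)
```

plaquescreen analyses taxon-by-sample count tables from subgingival
plaque 16S rDNA surveys of perinatally HIV-infected (PHIV) and
perinatally HIV-exposed, uninfected (PHEU) youth. This vignette is the
package's account of the statistics it implements: the models, the
tunable parameters and their defaults, what the synthetic cohort
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## Data model and exclusion rules

The unit of observation is one pooled subgingival plaque sample per
participant. Counts live in a `count_matrix` (taxa x samples,
non-negative integers, with genus and optional species labels; an empty
species field marks reads classified only to genus level). Covariates
and outcomes live in a per-sample metadata frame: group (PHIV/PHEU),
age in years, sex, race (white or other), ethnicity (Hispanic or not),
a dental visit in the previous year, antibiotic use in the prior three
months, periodontitis (present/absent, consumed as a given binary
label), caries (any/none), and the sample's total sequencing reads.
Missing covariates in included samples are an error: no imputation is
performed, because none is defensible without a model of the
missingness mechanism, and the fitting functions would otherwise drop
rows silently.

Exclusions run in a fixed order (`apply_filters()`): an optional
`UNMATCHED` row of unassignable reads is dropped first, then samples
flagged for recent antibiotic use, then samples with fewer than 200
total reads (strict `<`), then taxa whose *pooled* relative abundance —
taxon total over grand total — is below 1e-5 (strict `<`), then taxa
detected in fewer than 10 subjects in both groups combined. Two
interpretations deserve a note. The rare-taxon rule could be read
per-sample or pooled; the pooled reading is used because it is the one
that removes globally negligible phylotypes rather than taxa that are
merely rare somewhere. "Present in" a subject means a non-zero count,
with no minimum-count refinement, since none is stated anywhere
authoritative. Every filter is idempotent, reports in = out + removed,
and the prevalence filter is applied after the sample exclusions (the
ordering used by `run_pipeline()`).

## Alpha diversity and rarefaction

Shannon diversity is `-sum p_i log_base p_i`; the log base defaults to
2 (QIIME's convention) and is recorded in the output, since the choice
is a units convention, not a scientific claim. Simpson diversity is
reported as 1 - D = `1 - sum p_i^2`, the probability that two random
reads come from different taxa; it is invariant to count rescaling.
Both are computed on unrarefied counts — rarefaction is applied only to
the richness curves, where sequencing depth mechanically drives the
statistic.

Rarefaction curves use the exact hypergeometric expectation
`E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))` (via `vegan::rarefy`)
rather than Monte-Carlo subsampling; a Monte-Carlo mode exists mainly
so tests can verify that the two converge. Curves are restricted to
samples with at least 65,000 reads, and the default depth grid spans
1,000 to that minimum, so every sample is evaluated on the same grid.
At full depth the expectation equals observed richness exactly, which
the tests assert to numerical precision.

Group contrasts of the diversity measures use a two-sample t test.
Welch's unequal-variance form is the default — diversity distributions
are typically skewed with group-dependent spread — with Student's
pooled form available (`var_equal = TRUE`) for strict replication of
analyses that used it.

## Per-taxon negative binomial screening

For each taxon, counts are modelled by a log-link negative binomial
regression on group plus age, sex, dental visit, race, ethnicity, and
the log of total sequencing reads, with variance `mu + mu^2 / k` and the
size `k` estimated per taxon by maximum likelihood jointly with the
coefficients (`MASS::glm.nb`). The exponentiated group coefficient is
the rate ratio (RR): the fold change in expected counts in PHIV
relative to PHEU. Inference on the group coefficient is Wald —
`exp(est +/- 1.96 se)` intervals and a two-sided normal p-value —
because the screen's deliverable is an RR with a CI, which is
Wald-natural; a likelihood-ratio check is exercised in the test suite
as an agreement property rather than offered as a second user-facing
path.

Total reads enters as a log-scale covariate with a *free* coefficient,
not as an offset, mirroring its listing among adjustment covariates;
`total_reads_mode = "offset"` pins the coefficient at 1 for sensitivity
analysis, and `"none"` drops it for degenerate toy designs. Constant
covariates are dropped with a message (a constant column and the
intercept are indistinguishable); genuinely collinear designs error,
naming the aliased columns. Non-convergence is data, not an exception:
the taxon is reported with NA estimates, flagged, excluded from the BH
family, and counted in a message.

Screens run at the species level (species-resolved rows) and the genus
level. Genus aggregation defaults to *genus-only* reads — sequences
assigned to the genus but not to any species, i.e. subtracting out
species-level assignments — with a `"total"` mode that sums the whole
genus instead. Benjamini-Hochberg step-up control at q = 0.05 is
applied separately within each level (separate families for separate
sets of comparisons), through `stats::p.adjust` on the non-missing
p-values; the test suite checks the decisions against a brute-force
implementation of the step-up definition.

## FPRP, BFDP and noteworthiness

A significance threshold alone does not say how likely a "significant"
taxon is to be a false positive. Two complementary posterior summaries
are attached to every converged taxon:

* **FPRP** (false positive report probability):
  `alpha (1 - pi) / (alpha (1 - pi) + (1 - beta) pi)`, where `alpha` is
  the observed p-value (the "observed FPRP" convention), `pi` the prior
  probability of a true association, and `1 - beta` the power of the
  two-sided level-`alpha` z-test at a stated alternative. The
  alternative is an expected rate ratio of 1.5, applied by magnitude so
  depleted and enriched taxa are treated symmetrically.
* **BFDP** (Bayesian false discovery probability): with `V = se^2`,
  `z = est / se`, the approximate Bayes factor
  `ABF = sqrt((V + W)/V) exp(-z^2 W / (2(V + W)))` compares the point
  null to a normal alternative `N(0, W)` on the log-RR scale, and
  `BFDP = ABF PO / (1 + ABF PO)` with prior odds `PO = (1 - pi)/pi`.

The prior variance W is elicited from the same single effect-size
anchor: the 97.5th percentile of the prior RR distribution is set at
1.5, giving `W = (log 1.5 / 1.96)^2 ~= 0.0428`. This is configurable;
published tables computed with a different elicitation will differ
numerically, which is why no external FPRP/BFDP value is treated as a
fixed target. Both quantities are computed at priors 0.001, 0.01 and
0.05; the composite *noteworthy* flag uses the 0.01 prior and marks a
BH-significant taxon when both FPRP and BFDP are below 0.5, or either
is below 0.2. The closed-form BFDP is verified against numerical
integration of the two marginal likelihoods to 1e-6, and the power term
against a 10^6-draw Monte-Carlo z-test.

## Disease-association interaction models

Whether a taxon relates differently to periodontitis (or caries) in
PHIV versus PHEU youth is tested by logistic regression of the outcome
on group, the taxon's level, their product, the adjustment covariates,
and the sample's total counts. Taxon counts are log10-transformed after
replacing zeros with half the taxon's minimum non-zero count — computed
across all included samples, both groups pooled, since the rule is a
property of the taxon, not of a stratum. Coefficients are therefore
log-odds per tenfold count increase: the PHEU odds ratio is
`exp(b_taxon)`, the PHIV odds ratio `exp(b_taxon + b_interaction)`
(with the delta-method CI using the full covariance), and the
interaction Wald p-value tests the group difference in slopes. The
sample's total counts enters as log10 of total reads, paralleling the
taxon transform for scale comparability.

Separation — a taxon present, say, only in non-cases of one group —
makes the MLE diverge. Such fits are flagged *degenerate* by combining
the IRLS separation warning with coefficient/standard-error magnitude
checks, reported with no numeric OR, and rendered as the literal string
`Undefined` in output tables; they never raise exceptions, because a
screen over hundreds of taxa must survive individual pathologies.

Primary analyses target configurable etiologic sets (defaults: ten
periodontitis-associated and eleven caries-associated taxa, including
two genus-level groupings); their interaction p-values are compared to
0.05 unadjusted, while exploratory all-taxa screens are BH-adjusted.
The combined-set model sums the member taxa's counts per sample before
the same transform and model.

## The synthetic cohort generator

`cohort_config()` defaults are the study conditions the package is
designed around: 154 PHIV and 100 PHEU samples, 600 taxa, per-sample
depths drawn log-uniformly on 1,330-230,039 reads (matching the heavy
right skew of real amplicon depth distributions). Baseline taxon
abundances are drawn once per configuration from a normal on the log
scale (sd 2) and softmax-normalised, giving the realistic many-rare,
few-dominant profile; per-taxon NB sizes are drawn log-uniformly on
0.1-2, the overdispersion range typical of amplicon counts. Counts are
`NB(mu = depth x p_i x exp(rr_i g + covariate effects), size = k_i)` —
the same mean/size parameterisation the downstream GLM fits, so
parameter-recovery experiments are internally consistent. Covariates
default to age ~ uniform(10, 22) and Bernoulli(0.5) binaries; these are
configuration, not estimates of any real cohort. Disease outcomes come
from the logistic models of the previous section, applied to centered
log10 half-minimum-transformed counts, again exactly the analysis
transform. `phiv_pheu_config()` adds three abundant taxa depleted in
PHIV at RR 0.15-0.25 (the Corynebacterium-like pattern) and four taxa
with positive caries interactions (delta = log 1.5).

Reproducibility contract: per-taxon parameters are realized inside the
constructor under `set.seed(seed)`, and `simulate_cohort()` consumes a
decoupled stream (`seed + 1`); the same configuration always
regenerates bitwise-identical output. Recorded `total_reads` are the
realized column sums, which asserts cleanly against the count matrix
but means realized totals scatter around the drawn depth parameter.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: taxon-taxon correlation beyond shared
sequencing depth, zero inflation beyond what the negative binomial
produces, compositional closure effects, taxonomy misassignment, batch
or site effects, and confounding between group and covariates (the
simulated covariates are independent of group unless configured
otherwise). Validation on these cohorts demonstrates that the
estimators are correct under the stated model, not that the model is
true of plaque communities.

## Validation experiment sizes

The packaged validation suite runs at the study's sample size
(n = 254) with problem sizes chosen to make the Monte-Carlo error small
relative to the bands being checked: null type-I error of the NB screen
over 12 independent cohorts of 120 equal-abundance taxa (~1,150 Wald
tests; per-cohort rejection rates are correlated through the shared
design, so averaging over cohorts, not taxa, is what matters); CI
coverage at a true RR of 0.2 over 200 replicate cohorts; interaction
null level over 500 replicates and delta = log 2 recovery over 200.
Dispersion is fixed at k = 0.5 in these experiments — mid-range
overdispersion — and the target taxon sits at ~0.8% relative abundance,
deep enough for stable fits without being dominant. One caution
learned in building them: with only a handful of simulated taxa the
realized total-read covariate becomes a noisy proxy for depth dominated
by a few dispersed taxa, and Wald coverage degrades for reasons that
have nothing to do with the estimator; validity experiments should use
cohorts with realistically many taxa.

## Known limitations

* Wald inference is mildly anticonservative for weakly-identified taxa
  (low counts, small size parameter); the BH family inherits this.
* FPRP/BFDP values depend on the W elicitation and the expected-RR
  anchor; they are decision aids, not posterior probabilities under a
  fitted prior.
* The compositional structure of relative-abundance data is not
  modelled; rate ratios are statements about counts at fixed total
  reads, not about absolute microbial load.
* Beta diversity, zero-inflated and log-ratio models are deliberately
  out of scope.

## A minimal run

```{r example, eval = FALSE}
cfg <- phiv_pheu_config(seed = 1)
sim <- simulate_cohort(cfg)
res <- run_pipeline(sim$counts, sim$metadata, out_dir = "results",
                    seed = 1)
summary(res$screens$species)
```
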