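#' Two-sided power of a Wald z-test at a stated alternative
#'
#' Normal-approximation power of the two-sided level-`alpha` z-test of a
#' log rate ratio, at alternative `theta1` given standard error `se`:
#' with c = qnorm(1 - alpha/2) and t = theta1 / se, power =
#' 1 - pnorm(c - t) + pnorm(-c - t). Symmetric in the sign of `theta1`.
#'
#' @param alpha two-sided test level in (0, 1) — for the FPRP this is the
#'   observed p-value.
#' @param se standard error of the log effect estimate (> 0).
#' @param theta1 alternative log effect (e.g. log of the expected rate
#'   ratio).
#' @return power (1 - beta) in (0, 1). Vectorised over all arguments.
#' @export
power_at_alternative <- function(alpha, se, theta1) {
  stopifnot(all(alpha > 0), all(alpha < 1), all(se > 0))
  cc <- stats::qnorm(1 - alpha / 2)
  t1 <- theta1 / se
  1 - stats::pnorm(cc - t1) + stats::pnorm(-cc - t1)
}

#' False positive report probability (FPRP)
#'
#' Posterior probability that a significant association is a false
#' positive, given the observed p-value `alpha`, the power of the
#' level-`alpha` test at the expected effect size, and the prior
#' probability `prior` that the association is real:
#' FPRP = alpha (1 - prior) / (alpha (1 - prior) + power * prior).
#' The expected effect is specified as a rate ratio `rr1` (default 1.5);
#' its log magnitude is applied symmetrically, so depleted and enriched
#' taxa are treated alike.
#'
#' @param alpha observed two-sided p-value(s) in (0, 1).
#' @param se standard error(s) of the log rate ratio.
#' @param prior prior probability of a true association, in (0, 1].
#' @param rr1 expected rate ratio under the alternative.
#' @return FPRP in [0, 1]. Vectorised.
#' @export
fprp <- function(alpha, se, prior, rr1 = 1.5) {
  stopifnot(all(prior > 0), all(prior <= 1))
  pw <- power_at_alternative(alpha, se, abs(log(rr1)))
  num <- alpha * (1 - prior)
  num / (num + pw * prior)
}

#' Bayesian false discovery probability (BFDP)
#'
#' Posterior probability of the point null against a normal prior
#' N(0, W) on the log rate ratio, from the approximate Bayes factor based
#' on the estimator's normal sampling distribution: with V = se^2 and
#' z = theta_hat / se,
#' ABF = sqrt((V + W) / V) * exp(-z^2 W / (2 (V + W))) and
#' BFDP = ABF * PO / (1 + ABF * PO), PO = (1 - prior) / prior.
#' The default prior variance W places the 97.5th percentile of the prior
#' rate-ratio distribution at 1.5: W = (log 1.5 / 1.96)^2.
#'
#' @param theta_hat estimated log rate ratio(s).
#' @param se standard error(s) (> 0).
#' @param prior prior probability of a true association, in (0, 1).
#' @param w prior variance of the log rate ratio under the alternative
#'   (>= 0).
#' @return list with `abf` (approximate Bayes factor, null vs alternative)
#'   and `bfdp`, both vectorised.
#' @export
bfdp <- function(theta_hat, se, prior,
                 w = (log(1.5) / stats::qnorm(0.975))^2) {
  stopifnot(all(se > 0), all(prior > 0), all(prior < 1), all(w >= 0))
  V <- se^2
  z <- theta_hat / se
  abf <- sqrt((V + w) / V) * exp(-z^2 * w / (2 * (V + w)))
  po <- (1 - prior) / prior
  list(abf = abf, bfdp = abf * po / (1 + abf * po))
}

#' Composite noteworthiness rule
#'
#' A significant taxon is noteworthy when (1) both the FPRP and the BFDP
#' are below 0.5, or (2) the FPRP is below 0.2, or (3) the BFDP is below
#' 0.2. Non-significant taxa are never noteworthy.
#'
#' @param significant logical BH decision.
#' @param fprp_value,bfdp_value FPRP and BFDP at the flagging prior.
#' @return logical; NA when significant but an input is NA.
#' @export
flag_noteworthy <- function(significant, fprp_value, bfdp_value) {
  rule <- (fprp_value < 0.5 & bfdp_value < 0.5) | fprp_value < 0.2 |
    bfdp_value < 0.2
  out <- significant & rule
  out[!significant %in% TRUE] <- FALSE
  out
}

#' Append FPRP/BFDP noteworthiness columns to a screen
#'
#' Computes, for every converged taxon in a [taxon_screen()] result, the
#' FPRP and BFDP at each prior probability (defaults 0.001, 0.01, 0.05)
#' and the composite noteworthy flag evaluated at `flag_prior` (default
#' 0.01) with expected rate ratio `rr1` (default 1.5) and prior variance
#' `w` (default anchored so the prior 97.5th rate-ratio percentile is
#' `rr1`).
#'
#' @param screen a `taxon_screen` object.
#' @param priors prior probabilities of true association.
#' @param rr1 expected rate ratio for the FPRP power term.
#' @param w BFDP prior variance; NULL uses `(log(rr1)/1.96)^2`.
#' @param flag_prior the prior at which the noteworthy flag is evaluated.
#' @return the screen with columns `fprp_<prior>`, `bfdp_<prior>` and
#'   `noteworthy` added to `$results`, and the parameters recorded in
#'   `$noteworthiness`.
#' @export
add_noteworthiness <- function(screen, priors = c(0.001, 0.01, 0.05),
                               rr1 = 1.5, w = NULL, flag_prior = 0.01) {
  stopifnot(inherits(screen, "taxon_screen"), flag_prior %in% priors)
  if (is.null(w)) w <- (log(rr1) / stats::qnorm(0.975))^2
  res <- screen$results
  ok <- res$converged & !is.na(res$p_value) & res$p_value < 1
  for (pi0 in priors) {
    fcol <- sprintf("fprp_%g", pi0)
    bcol <- sprintf("bfdp_%g", pi0)
    res[[fcol]] <- NA_real_
    res[[bcol]] <- NA_real_
    res[[fcol]][ok] <- fprp(res$p_value[ok], res$se[ok], pi0, rr1)
    res[[bcol]][ok] <- bfdp(res$estimate[ok], res$se[ok], pi0, w)$bfdp
  }
  res$noteworthy <- flag_noteworthy(
    res$significant,
    res[[sprintf("fprp_%g", flag_prior)]],
    res[[sprintf("bfdp_%g", flag_prior)]])
  screen$results <- res
  screen$noteworthiness <- list(priors = priors, rr1 = rr1, w = w,
                                flag_prior = flag_prior)
  screen
}
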