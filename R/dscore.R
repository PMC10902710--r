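#' Overall call rate at a site
#'
#' The proportion of non-missing samples in which a call is made (genotype
#' heterozygous or homozygous alternate).
#'
#' @param g integer genotype vector (see [is_called()]).
#' @return The call rate f in \[0, 1\].
#' @export
overall_call_rate <- function(g) {
  ok <- !is.na(g)
  if (!any(ok)) stop("all genotypes missing: call rate undefined")
  sum(g[ok] >= 1L) / sum(ok)
}

## maximum of f(q) = 2q(1-q) b_het + q^2 b_hom on [0,1], and its location
call_rate_peak <- function(beta_het, beta_hom) {
  q_star <- if (beta_hom < 2 * beta_het) {
    min(1, beta_het / (2 * beta_het - beta_hom))
  } else 1
  f_of_q <- function(q) 2 * q * (1 - q) * beta_het + q^2 * beta_hom
  list(q = q_star, f = f_of_q(q_star), f_of_q = f_of_q)
}

#' Infer the alternate-allele frequency behind an observed call rate
#'
#' Under the detection model, a site with allele frequency q is called in a
#' random sample with probability
#' `f(q) = 2 q (1 - q) beta_het + q^2 beta_hom`
#' (Hardy-Weinberg genotypes, genotype-specific detection). This inverts the
#' map on the rare-variant branch \[0, q*\], where q* is the location of the
#' maximum attainable call rate, by bisection to `|f(q) - f| <= 1e-12`.
#'
#' @param f observed overall call rate in \[0, 1\].
#' @param beta_het,beta_hom detection probabilities for heterozygous and
#'   homozygous carriers, in \[0, 1\], not both 0 when `f > 0`.
#' @return The allele frequency q in \[0, 1\].
#' @examples
#' infer_allele_frequency(0.19, 1, 1)  # 0.1 (closed form 1 - sqrt(1 - f))
#' @export
infer_allele_frequency <- function(f, beta_het, beta_hom) {
  stopifnot(f >= 0, f <= 1, beta_het >= 0, beta_het <= 1,
            beta_hom >= 0, beta_hom <= 1)
  if (f == 0) return(0)
  if (beta_het == 0 && beta_hom == 0) {
    stop("f > 0 is unattainable with beta_het = beta_hom = 0")
  }
  pk <- call_rate_peak(beta_het, beta_hom)
  if (f > pk$f + 1e-12) {
    stop(sprintf("call rate f = %.6g exceeds the maximum %.6g attainable under beta_het = %.3g, beta_hom = %.3g",
                 f, pk$f, beta_het, beta_hom))
  }
  lo <- 0; hi <- pk$q
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- pk$f_of_q(mid)
    if (abs(fm - f) <= 1e-12) return(mid)
    if (fm < f) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sibling sharing probability under the true-variant model
#'
#' The probability that a full sibling of a called sample is itself called,
#' for a true variant at allele frequency q, computed by exact enumeration:
#' two parents are drawn independently from Hardy-Weinberg genotype
#' frequencies, two children by Mendelian transmission, and a carrier is
#' called with probability 0 / `beta_het` / `beta_hom` according to its
#' genotype. In the rare-variant limit this tends to `beta_het / 2` (a single
#' heterozygous parent transmits to the second sibling with probability 1/2).
#'
#' @param q alternate-allele frequency in \[0, 1\].
#' @param beta_het,beta_hom detection probabilities, not both 0 (and `q > 0`
#'   is required, otherwise no sibling is ever called and the conditional is
#'   undefined).
#' @return f_sib = P(call in sib2 | call in sib1), in \[0, 1\].
#' @export
sib_sharing_prob <- function(q, beta_het, beta_hom) {
  stopifnot(q >= 0, q <= 1, beta_het >= 0, beta_het <= 1,
            beta_hom >= 0, beta_hom <= 1)
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)   # genotype 0/1/2
  det <- c(0, beta_het, beta_hom)
  transmit <- c(0, 0.5, 1)                   # P(alt allele | parent genotype)
  num <- 0; den <- 0
  for (g1 in 0:2) for (g2 in 0:2) {
    p_par <- hw[g1 + 1] * hw[g2 + 1]
    if (p_par == 0) next
    p1 <- transmit[g1 + 1]; p2 <- transmit[g2 + 1]
    ## child genotype distribution given parents
    child <- c((1 - p1) * (1 - p2), p1 * (1 - p2) + (1 - p1) * p2, p1 * p2)
    s <- sum(child * det)                    # P(child called | parents)
    num <- num + p_par * s^2
    den <- den + p_par * s
  }
  if (den <= 0) {
    stop("P(call) is 0 (q = 0 or both betas 0): conditional sharing undefined")
  }
  num / den
}

#' Observed sibling sharing at a site
#'
#' Counts over all ordered full-sibling pairs (i, j): `n` increments when i
#' is called, `k` when both are called; ordered pairs with a missing genotype
#' in either member are dropped.
#'
#' @param g integer genotype vector named by sample id.
#' @param ped a [pedigree()] covering the samples.
#' @return list with `k`, `n` and `f_sib_observed = k/n` (`NaN` when n = 0).
#' @export
observe_sib_sharing <- function(g, ped) {
  if (is.null(names(g))) stop("genotype vector must be named by sample id")
  pairs <- full_sib_pairs(ped)
  k <- 0L; n <- 0L
  if (nrow(pairs)) {
    g1 <- g[pairs$id1]; g2 <- g[pairs$id2]
    ok <- !is.na(g1) & !is.na(g2)
    c1 <- g1[ok] >= 1L; c2 <- g2[ok] >= 1L
    n <- sum(c1) + sum(c2)            # ordered pairs with first member called
    k <- 2L * sum(c1 & c2)            # ordered pairs with both called
  }
  list(k = as.integer(k), n = as.integer(n),
       f_sib_observed = if (n > 0) k / n else NaN)
}

#' D-score: sibling-sharing log-likelihood ratio for one site
#'
#' Contrasts the observed sibling sharing k out of n ordered sib pairs
#' against two binomial models: under the true-variant hypothesis the shared
#' count is Binomial(n, f_sib); under the reproducible-false-call hypothesis
#' it is Binomial(n, f), f being the overall call rate. The score is the
#' natural log of `P(X1 < k) / P(X0 > k)` (strict inequalities on the count
#' scale; `strict = FALSE` uses `P(X1 <= k) / P(X0 >= k)` instead). Both
#' probabilities are floored at 1e-300 before the log; a floored score is
#' finite but flagged `capped`, keeping scores sortable for prioritisation.
#'
#' @param k,n observed shared / total ordered sib-pair counts, `0 <= k <= n`.
#' @param f overall call rate.
#' @param f_sib model sibling sharing probability (see [sib_sharing_prob()]).
#' @param n_called number of called samples at the site across the cohort;
#'   sites with fewer than `min_calls` are not scored.
#' @param min_calls minimum called samples needed for a score (default 2).
#' @param strict use strict tail inequalities (default) or non-strict.
#' @return list with `D` (`NA` when unscored), `k`, `n`, `f`, `f_sib` and
#'   `status` in `"scored"`, `"capped"`, `"too_few_calls"`, `"no_sib_pairs"`.
#' @examples
#' d_score(k = 1, n = 2, f = 0.05, f_sib = 0.5, n_called = 2)$D  # log(100)
#' @export
d_score <- function(k, n, f, f_sib, n_called = NULL, min_calls = 2,
                    strict = TRUE) {
  if (k > n) stop("k must not exceed n")
  if (k < 0 || n < 0) stop("k and n must be nonnegative")
  res <- list(D = NA_real_, k = as.integer(k), n = as.integer(n),
              f = f, f_sib = f_sib, status = "scored")
  if (!is.null(n_called) && n_called < min_calls) {
    res$status <- "too_few_calls"
    return(res)
  }
  if (n == 0) {
    res$status <- "no_sib_pairs"
    return(res)
  }
  if (strict) {
    num <- stats::pbinom(k - 1, n, f_sib)                      # P(X1 < k)
    den <- stats::pbinom(k, n, f, lower.tail = FALSE)          # P(X0 > k)
  } else {
    num <- stats::pbinom(k, n, f_sib)                          # P(X1 <= k)
    den <- stats::pbinom(k - 1, n, f, lower.tail = FALSE)      # P(X0 >= k)
  }
  floor_p <- 1e-300
  capped <- num < floor_p || den < floor_p
  res$D <- log(max(num, floor_p)) - log(max(den, floor_p))
  res$status <- if (capped) "capped" else "scored"
  res
}
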