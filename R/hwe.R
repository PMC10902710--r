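#' One-sided exact test for heterozygote excess
#'
#' Exact Hardy-Weinberg test against the alternative of *excess*
#' heterozygosity, the signature of reproducible mapping-artifact calls.
#' Conditional on the sample size n and the alternate-allele count, the
#' heterozygote count follows the Levene-Haldane distribution
#' `P(n_het) proportional to 2^n_het * n! / (n_hom_ref! n_het! n_hom_alt!)`,
#' and the p-value is the upper tail `P(N_het >= n_het_observed)`. Deficits
#' of heterozygotes are never flagged (p close to 1 there).
#'
#' @param n_hom_ref,n_het,n_hom_alt nonnegative genotype counts, total > 0.
#' @return The one-sided p-value in (0, 1\].
#' @examples
#' hwe_excess_het_pvalue(0, 2, 0)   # 2/3 on the two-sample margin
#' hwe_excess_het_pvalue(10, 0, 0)  # 1: no excess possible
#' @export
hwe_excess_het_pvalue <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("counts must be nonnegative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("total genotype count must be positive")
  n_alt <- n_het + 2 * n_hom_alt
  ## support: k = n_alt (mod 2), 0 <= k <= min(n_alt, 2n - n_alt)
  k <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  lw <- k * log(2) + lfactorial(n) -
    lfactorial((n_alt - k) / 2) - lfactorial(k) - lfactorial(n - (n_alt + k) / 2)
  w <- exp(lw - max(lw))
  sum(w[k >= n_het]) / sum(w)
}
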