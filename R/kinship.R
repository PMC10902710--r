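#' KING-robust kinship coefficient for one sample pair
#'
#' The within-pair, allele-frequency-free estimator
#' `phi = (N_het,het - 2 N_opp,hom) / (N_het(i) + N_het(j))`,
#' where `N_het,het` counts sites at which both samples are heterozygous,
#' `N_opp,hom` sites at which they are opposite homozygotes, and `N_het(x)`
#' the heterozygous sites of sample x. Sites with a missing genotype in
#' either sample are dropped. Expected values: 0.5 for duplicates, 0.25 for
#' full siblings and parent-offspring, ~0 for unrelated pairs.
#'
#' @param gi,gj equal-length integer genotype vectors.
#' @return list with `phi` (`NA` when neither sample has a heterozygous
#'   site), `n_het_i`, `n_het_j`, `n_het_het`, `n_opp_hom`, `n_sites`
#'   (non-missing sites used).
#' @examples
#' king_robust_kinship(rep(1L, 10), rep(1L, 10))$phi  # 0.5
#' @export
king_robust_kinship <- function(gi, gj) {
  if (length(gi) != length(gj)) stop("genotype vectors must have equal length")
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n_het_i <- sum(gi == 1L)
  n_het_j <- sum(gj == 1L)
  n_het_het <- sum(gi == 1L & gj == 1L)
  n_opp_hom <- sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
  den <- n_het_i + n_het_j
  list(phi = if (den > 0) (n_het_het - 2 * n_opp_hom) / den else NA_real_,
       n_het_i = n_het_i, n_het_j = n_het_j, n_het_het = n_het_het,
       n_opp_hom = n_opp_hom, n_sites = length(gi))
}

#' Kinship report for all full-sibling pairs
#'
#' @param calls a [call_matrix()].
#' @param ped a [pedigree()].
#' @param autosomes_only drop sites flagged as X/Y before estimating
#'   (default `TRUE`; no-op when the site table has no `sex_chrom` column).
#' @return data.frame with one row per full-sib pair: `id1`, `id2`, `fid`,
#'   `phi` and the KING counts.
#' @export
sib_pair_kinship <- function(calls, ped, autosomes_only = TRUE) {
  stopifnot(inherits(calls, "call_matrix"))
  if (autosomes_only && !is.null(calls$sites$sex_chrom)) {
    keep <- !calls$sites$sex_chrom
    if (!all(keep)) calls <- calls[keep, ]
  }
  pairs <- full_sib_pairs(ped)
  pairs <- pairs[pairs$id1 %in% calls$samples & pairs$id2 %in% calls$samples, ,
                 drop = FALSE]
  if (!nrow(pairs)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      fid = character(0), phi = numeric(0),
                      n_het_i = integer(0), n_het_j = integer(0),
                      n_het_het = integer(0), n_opp_hom = integer(0),
                      n_sites = integer(0), stringsAsFactors = FALSE))
  }
  est <- lapply(seq_len(nrow(pairs)), function(r) {
    king_robust_kinship(calls$genotypes[, pairs$id1[r]],
                        calls$genotypes[, pairs$id2[r]])
  })
  cbind(pairs, do.call(rbind, lapply(est, as.data.frame)))
}

#' Mean sibling kinship per deletion size bin
#'
#' Recomputes the KING-robust coefficient for every full-sib pair on the
#' subset of sites falling in each bin. A clean call set should sit near the
#' sibling expectation of 0.25 in every bin; systematic departures localise
#' calling artifacts to a size range.
#'
#' @inheritParams sib_pair_kinship
#' @param bins a [size_bin_scheme()].
#' @return data.frame with columns `bin`, `n_sites`, `n_pairs` (pairs with a
#'   defined estimate), `mean_phi` (`NA` when no pair is estimable).
#' @export
kinship_by_size_bin <- function(calls, ped, bins, autosomes_only = TRUE) {
  stopifnot(inherits(bins, "size_bin_scheme"))
  bin <- assign_size_bin(calls$sites$size, bins)
  out <- lapply(bins$label, function(b) {
    idx <- which(!is.na(bin) & bin == b)
    if (!length(idx)) {
      return(data.frame(bin = b, n_sites = 0L, n_pairs = 0L,
                        mean_phi = NA_real_, stringsAsFactors = FALSE))
    }
    kk <- sib_pair_kinship(calls[idx, ], ped, autosomes_only = autosomes_only)
    ok <- !is.na(kk$phi)
    data.frame(bin = b, n_sites = length(idx), n_pairs = sum(ok),
               mean_phi = if (any(ok)) mean(kk$phi[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
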