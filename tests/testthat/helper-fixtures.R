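## Shared fixture builders and independent oracles.

## A nuclear-family pedigree: n_fam families, each 2 founders + sibs children.
toy_ped <- function(n_fam = 1, sibs = 2, affection = "unknown") {
  rows <- lapply(seq_len(n_fam), function(i) {
    f <- paste0("F", i)
    kids <- paste0(f, "_s", seq_len(sibs))
    data.frame(fid = f,
               iid = c(paste0(f, "_p1"), paste0(f, "_p2"), kids),
               pat = c(NA, NA, rep(paste0(f, "_p1"), sibs)),
               mat = c(NA, NA, rep(paste0(f, "_p2"), sibs)),
               sex = c(1L, 2L, rep(0L, sibs)),
               affection = affection, stringsAsFactors = FALSE)
  })
  pedigree(do.call(rbind, rows))
}

## Call matrix from a genotype matrix; sites are consecutive 100-bp deletions.
make_cm <- function(geno, samples = colnames(geno), size = 100) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  call_matrix(geno,
              sites = data.frame(chrom = "chr1",
                                 start = seq_len(n) * 1000,
                                 end = seq_len(n) * 1000 + size,
                                 site_id = paste0("s", seq_len(n))),
              samples = samples)
}

## The engineered 100-site QC fixture: 80 clean sites plus disjoint
## violations (10 all-HET excess-het, 5 monomorphic, 3 low call rate, 2 low
## allele count) on a founder-only cohort of 60 samples.
qc_fixture <- function() {
  n_samp <- 60
  ped <- pedigree(data.frame(fid = paste0("F", seq_len(n_samp)),
                             iid = paste0("u", seq_len(n_samp)),
                             pat = NA, mat = NA, sex = 0L,
                             affection = "unknown"))
  set.seed(404)
  clean_site <- function() {
    ## ~HWE genotypes at q = 0.25: comfortably past every filter
    g <- stats::rbinom(n_samp, 2, 0.25)
    ## guard against an accidental monomorphic or low-AC draw
    if (sum(g) < 5) g[1:3] <- c(1L, 1L, 1L)
    as.integer(g)
  }
  rows <- c(
    replicate(10, rep(1L, n_samp), simplify = FALSE),                  # excess het
    replicate(5, rep(0L, n_samp), simplify = FALSE),                   # monomorphic
    replicate(3, c(rep(NA_integer_, 10), rep(1L, 10),
                   stats::rbinom(n_samp - 20, 2, 0.25)), simplify = FALSE), # call rate 5/6
    replicate(2, c(1L, 1L, rep(0L, n_samp - 2)), simplify = FALSE),    # AC = 2
    replicate(80, clean_site(), simplify = FALSE)
  )
  g <- do.call(rbind, rows)
  list(cm = make_cm(g, samples = ped$iid), ped = ped)
}

## Brute-force reciprocal-overlap matcher: all-pairs fractions, threshold,
## then greedy one-to-one in decreasing min-fraction order with the same
## deterministic tie-break. No interval-tree machinery.
bf_match <- function(truth, calls, frac = 0.5) {
  cand <- NULL
  for (i in seq_len(nrow(truth))) for (j in seq_len(nrow(calls))) {
    if (truth$chrom[i] != calls$chrom[j]) next
    ov <- min(truth$end[i], calls$end[j]) - max(truth$start[i], calls$start[j])
    if (ov <= 0) next
    fa <- ov / (truth$end[i] - truth$start[i])
    fb <- ov / (calls$end[j] - calls$start[j])
    if (min(fa, fb) < frac) next
    cand <- rbind(cand, data.frame(truth_id = truth$event_id[i],
                                   call_id = calls$site_id[j],
                                   frac_truth = fa, frac_call = fb,
                                   min_frac = min(fa, fb),
                                   t_start = truth$start[i],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(cand)) {
    return(data.frame(truth_id = character(0), call_id = character(0)))
  }
  cand <- cand[order(-cand$min_frac, cand$t_start, cand$truth_id,
                     cand$call_id), ]
  used_t <- used_c <- character(0)
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (cand$truth_id[r] %in% used_t || cand$call_id[r] %in% used_c) next
    keep[r] <- TRUE
    used_t <- c(used_t, cand$truth_id[r])
    used_c <- c(used_c, cand$call_id[r])
  }
  out <- cand[keep, c("truth_id", "call_id"), drop = FALSE]
  out[order(out$truth_id), , drop = FALSE]
}

## Excess-heterozygosity oracle: condition the unconditional Hardy-Weinberg
## multinomial (any allele frequency; the conditional is frequency-free) on
## the alternate-allele count, via dmultinom.
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt, p = 0.37) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- n_het + 2 * n_hom_alt
  support <- seq(n_alt %% 2, min(n_alt, 2 * n - n_alt), by = 2)
  w <- vapply(support, function(b) {
    c_ <- (n_alt - b) / 2
    a <- n - b - c_
    stats::dmultinom(c(a, b, c_), prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, numeric(1))
  sum(w[support >= n_het]) / sum(w)
}

## Monte-Carlo check of the sibling-sharing model: simulate n_fam parent
## pairs, two children each, Rao-Blackwellise the call indicators by using
## the per-genotype detection probabilities, and measure the discrepancy
## statistic w = d1*d2 - f_sib*d1, which has mean exactly 0 when f_sib is
## the true conditional sharing probability (no ratio-estimator bias).
mc_sharing_discrepancy <- function(q, beta_het, beta_hom, f_sib,
                                   n_fam = 1e6) {
  g_pa <- stats::rbinom(n_fam, 2, q)
  g_ma <- stats::rbinom(n_fam, 2, q)
  child <- function() stats::rbinom(n_fam, 1, g_pa / 2) +
    stats::rbinom(n_fam, 1, g_ma / 2)
  det <- c(0, beta_het, beta_hom)
  d1 <- det[child() + 1]
  d2 <- det[child() + 1]
  w <- d1 * d2 - f_sib * d1
  list(delta = mean(w), se = stats::sd(w) / sqrt(n_fam))
}

## Rank-based AUC of scores x (positives) vs y (negatives).
auc_rank <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
    (length(x) * length(y))
}
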