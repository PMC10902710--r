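#' QC configuration for the filter cascade
#'
#' @param hwe_p_threshold sites with a one-sided excess-heterozygosity exact
#'   p-value below this are removed (default 5e-8).
#' @param min_call_rate minimum fraction of non-missing genotypes (default
#'   0.90).
#' @param min_alt_allele_count minimum alternate allele count,
#'   `n_het + 2 n_hom_alt` (default 5).
#' @param hwe_cohort compute the excess-het test on `"founders"` (default;
#'   avoids pseudo-replication from Mendelian transmission) or `"all"`
#'   samples.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(hwe_p_threshold = 5e-8, min_call_rate = 0.90,
                      min_alt_allele_count = 5,
                      hwe_cohort = c("founders", "all")) {
  stopifnot(hwe_p_threshold > 0, hwe_p_threshold <= 1,
            min_call_rate >= 0, min_call_rate <= 1,
            min_alt_allele_count >= 0)
  structure(list(hwe_p_threshold = hwe_p_threshold,
                 min_call_rate = min_call_rate,
                 min_alt_allele_count = min_alt_allele_count,
                 hwe_cohort = match.arg(hwe_cohort)),
            class = "qc_config")
}

#' Per-site QC record table
#'
#' Genotype counts, call rate, alternate allele count and the one-sided
#' excess-heterozygosity exact p-value (computed on the configured cohort)
#' for every site, together with the first failing cascade stage.
#'
#' @param calls a [call_matrix()].
#' @param ped a [pedigree()]; needed when `cfg$hwe_cohort == "founders"`.
#' @param cfg a [qc_config()].
#' @param n_genome_hits optional named integer vector (site_id -> number of
#'   genomic placements from an external multi-mapping annotation); sites
#'   with more than 100 hits fail a final `multi_mapped` stage.
#' @return data.frame with one row per site: counts, `call_rate`,
#'   `alt_allele_count`, `hwe_excess_het_p`, `filter_status` in `pass`,
#'   `excess_het`, `hom_ref_only`, `low_call_rate`, `low_ac`,
#'   `multi_mapped`.
#' @export
site_qc_table <- function(calls, ped = NULL, cfg = qc_config(),
                          n_genome_hits = NULL) {
  stopifnot(inherits(calls, "call_matrix"), inherits(cfg, "qc_config"))
  counts <- site_counts(calls)
  n_total <- length(calls$samples)
  counts$call_rate <- 1 - counts$n_missing / n_total
  counts$alt_allele_count <- counts$n_het + 2L * counts$n_hom_alt

  hwe_samples <- calls$samples
  if (cfg$hwe_cohort == "founders") {
    if (is.null(ped)) stop("a pedigree is required for hwe_cohort = 'founders'")
    hwe_samples <- intersect(founders(ped), calls$samples)
    if (!length(hwe_samples)) {
      warning("no founders among the samples: excess-het test uses all samples")
      hwe_samples <- calls$samples
    }
  }
  gh <- calls$genotypes[, hwe_samples, drop = FALSE]
  counts$hwe_excess_het_p <- vapply(seq_len(nrow(gh)), function(i) {
    g <- gh[i, ]
    a <- sum(g == 0L, na.rm = TRUE); b <- sum(g == 1L, na.rm = TRUE)
    c_ <- sum(g == 2L, na.rm = TRUE)
    if (a + b + c_ == 0) return(1)
    hwe_excess_het_pvalue(a, b, c_)
  }, numeric(1))

  status <- rep("pass", nrow(counts))
  fail1 <- counts$hwe_excess_het_p < cfg$hwe_p_threshold
  fail2 <- counts$n_het + counts$n_hom_alt == 0L
  fail3 <- counts$call_rate < cfg$min_call_rate
  fail4 <- counts$alt_allele_count < cfg$min_alt_allele_count
  status[fail4] <- "low_ac"
  status[fail3] <- "low_call_rate"
  status[fail2] <- "hom_ref_only"
  status[fail1] <- "excess_het"   # first-failing stage wins, applied last
  if (!is.null(n_genome_hits)) {
    hits <- n_genome_hits[counts$site_id]
    fail5 <- !is.na(hits) & hits > 100
    status[fail5 & status == "pass"] <- "multi_mapped"
  }
  counts$filter_status <- status
  counts
}

#' QC filter cascade
#'
#' Applies the site filters in fixed order: (1) excess heterozygosity
#' (exact p below threshold), (2) no called carriers (homozygous-reference /
#' monomorphic sites), (3) call rate below the minimum, (4) alternate allele
#' count below the minimum, and optionally (5) external multi-mapping
#' annotation (> 100 genomic hits). Each site is attributed to the first
#' stage it fails, so the per-stage removal counts plus survivors add up to
#' the input site count. The cascade is idempotent.
#'
#' @inheritParams site_qc_table
#' @return list with `calls` (the filtered [call_matrix()]), `removed`
#'   (named integer vector of per-stage removals), `n_input`, `n_surviving`
#'   and `qc` (the [site_qc_table()]).
#' @export
qc_cascade <- function(calls, ped = NULL, cfg = qc_config(),
                       n_genome_hits = NULL) {
  qc <- site_qc_table(calls, ped = ped, cfg = cfg,
                      n_genome_hits = n_genome_hits)
  stages <- c("excess_het", "hom_ref_only", "low_call_rate", "low_ac",
              "multi_mapped")
  removed <- vapply(stages, function(s) sum(qc$filter_status == s), integer(1))
  if (is.null(n_genome_hits)) removed <- removed[stages != "multi_mapped"]
  keep <- qc$filter_status == "pass"
  list(calls = calls[keep, ], removed = removed,
       n_input = nrow(qc), n_surviving = sum(keep), qc = qc)
}

#' Family segregation check (75% rule)
#'
#' A site segregates in a family when at least 75% of the affected,
#' genotyped family members carry the call. Families without any affected
#' genotyped member are reported separately.
#'
#' @param g integer genotype vector named by sample id.
#' @param ped a [pedigree()].
#' @param min_fraction carrier fraction required among affected genotyped
#'   members (default 0.75; the boundary is inclusive).
#' @return data.frame with one row per family: `fid`, `n_affected_genotyped`,
#'   `n_carriers`, `status` in `segregating`, `not_segregating`,
#'   `no_affected_data`.
#' @export
segregation_check <- function(g, ped, min_fraction = 0.75) {
  if (is.null(names(g))) stop("genotype vector must be named by sample id")
  out <- lapply(split(seq_len(nrow(ped)), ped$fid), function(rows) {
    ids <- ped$iid[rows][ped$affection[rows] == "affected"]
    gg <- g[intersect(ids, names(g))]
    gg <- gg[!is.na(gg)]
    n_aff <- length(gg)
    n_car <- sum(gg >= 1L)
    data.frame(fid = ped$fid[rows[1]], n_affected_genotyped = n_aff,
               n_carriers = n_car,
               status = if (n_aff == 0) "no_affected_data"
                        else if (n_car / n_aff >= min_fraction) "segregating"
                        else "not_segregating",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$fid), , drop = FALSE]
}
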