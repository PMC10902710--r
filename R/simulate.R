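#' Simulation configuration for family cohorts
#'
#' Defines a multi-family cohort with Hardy-Weinberg founders, Mendelian
#' transmission to full siblings, and a caller error model: carriers are
#' detected with genotype-specific probabilities, non-carriers can receive
#' random false calls, and a fraction of sites are locus-reproducible
#' artifacts whose calls hit samples i.i.d. at a fixed rate regardless of
#' relatedness (so the expected sibling sharing at those sites equals the
#' population call rate).
#'
#' @param n_families number of nuclear families.
#' @param sibs_per_family full siblings per family (>= 1).
#' @param include_parents genotype the two founder parents too (default
#'   `TRUE`). When `FALSE`, parents are simulated as latent transmitters and
#'   appear in the pedigree but not in the call matrices.
#' @param n_sites number of deletion sites.
#' @param q_range allele-frequency range for true-variant sites; each site's
#'   q is drawn uniformly from `[q_range[1], q_range[2]]` (use equal
#'   endpoints for a point mass).
#' @param size_range deletion sizes (bp) are drawn log-uniformly from this
#'   range (default 2-5000), mimicking the strong skew toward small events.
#' @param beta_het,beta_hom caller detection probabilities for heterozygous
#'   and homozygous carriers.
#' @param fp_random_rate per sample-site probability of a spurious call on a
#'   non-carrier.
#' @param fp_locus_fraction fraction of sites that are reproducible false
#'   calls (no true variant).
#' @param fp_locus_call_rate per-sample call probability at reproducible
#'   false-call sites; set near 0.5 to emulate heterozygote-inflating
#'   mapping artifacts.
#' @param clean_fraction fraction of sites with no variant and no locus
#'   artifact (callable only through random false positives).
#' @param missing_rate per sample-site probability of a missing genotype in
#'   the observed matrix.
#' @param contig,contig_length toy reference contig name and length (bp);
#'   sites are placed without overlap.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 200, sibs_per_family = 2,
                       include_parents = TRUE, n_sites = 1000,
                       q_range = c(0.05, 0.3), size_range = c(2, 5000),
                       beta_het = 1, beta_hom = 1,
                       fp_random_rate = 0, fp_locus_fraction = 0,
                       fp_locus_call_rate = 0.05, clean_fraction = 0,
                       missing_rate = 0, contig = "chr1",
                       contig_length = 1e7) {
  probs <- c(beta_het, beta_hom, fp_random_rate, fp_locus_fraction,
             fp_locus_call_rate, clean_fraction, missing_rate)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (fp_locus_fraction + clean_fraction > 1) {
    stop("fp_locus_fraction + clean_fraction must not exceed 1")
  }
  stopifnot(n_families >= 1, sibs_per_family >= 1, n_sites >= 1,
            length(q_range) == 2, all(q_range > 0), all(q_range < 1),
            q_range[1] <= q_range[2],
            length(size_range) == 2, size_range[1] >= 1,
            size_range[1] <= size_range[2])
  structure(list(n_families = n_families, sibs_per_family = sibs_per_family,
                 include_parents = include_parents, n_sites = n_sites,
                 q_range = q_range, size_range = size_range,
                 beta_het = beta_het, beta_hom = beta_hom,
                 fp_random_rate = fp_random_rate,
                 fp_locus_fraction = fp_locus_fraction,
                 fp_locus_call_rate = fp_locus_call_rate,
                 clean_fraction = clean_fraction,
                 missing_rate = missing_rate,
                 contig = contig, contig_length = contig_length),
            class = "sim_config")
}

## place n non-overlapping intervals of the given sizes on [0, L)
place_nonoverlapping <- function(sizes, L, chrom) {
  n <- length(sizes)
  total <- sum(sizes)
  if (total > L) {
    stop("contig of length ", L, " too small for ", n,
         " events totalling ", total, " bp")
  }
  slack <- L - total
  gaps_at <- sort(stats::runif(n, 0, slack))
  sizes <- sizes[sample.int(n)]          # random order along the contig
  start <- floor(gaps_at + cumsum(c(0, sizes[-n]))) + 1  # keep an anchor base
  data.frame(chrom = chrom, start = start, end = start + sizes,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-family deletion call set
#'
#' Draws founder genotypes from Hardy-Weinberg proportions at each
#' true-variant site, transmits alleles to the siblings by Mendelian
#' segregation, then pushes the true genotypes through the caller error
#' model of [sim_config()] to produce the observed call matrix. Detected
#' heterozygous carriers appear as HET, detected homozygous carriers as
#' HOM_ALT; missed carriers and uncalled samples appear as HOM_REF; false
#' calls appear as HET. All randomness is governed by `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return list of class `sim_cohort` with elements `ped` (a [pedigree()];
#'   affection is assigned `affected`/`unaffected` at random 1:1 so the
#'   segregation rule can be exercised), `truth` (true-genotype
#'   [call_matrix()]), `observed` (caller-output [call_matrix()]), `labels`
#'   (per-site `true_variant` / `reproducible_false` / `clean`), `q`
#'   (per-site allele frequency, `NA` for non-variant sites) and `cfg`.
#' @export
simulate_cohort <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))

  ## pedigree ----------------------------------------------------------------
  fid <- sprintf("F%04d", seq_len(cfg$n_families))
  ped_rows <- lapply(seq_len(cfg$n_families), function(i) {
    pa <- paste0(fid[i], "_p1"); ma <- paste0(fid[i], "_p2")
    kids <- paste0(fid[i], "_s", seq_len(cfg$sibs_per_family))
    data.frame(fid = fid[i],
               iid = c(pa, ma, kids),
               pat = c(NA, NA, rep(pa, length(kids))),
               mat = c(NA, NA, rep(ma, length(kids))),
               sex = c(1L, 2L, rep(0L, length(kids))),
               affection = "unknown", stringsAsFactors = FALSE)
  })
  ped_df <- do.call(rbind, ped_rows)
  ped_df$affection <- sample(c("affected", "unaffected"), nrow(ped_df),
                             replace = TRUE)
  ped <- pedigree(ped_df)

  is_parent <- is.na(ped$pat)
  parent_ids <- ped$iid[is_parent]
  child_ids <- ped$iid[!is_parent]
  out_samples <- if (cfg$include_parents) ped$iid else child_ids

  ## site table --------------------------------------------------------------
  m <- cfg$n_sites
  sizes <- round(exp(stats::runif(m, log(cfg$size_range[1]),
                                  log(cfg$size_range[2]))))
  sizes <- pmin(pmax(sizes, cfg$size_range[1]), cfg$size_range[2])
  loc <- place_nonoverlapping(sizes, cfg$contig_length, cfg$contig)
  loc <- loc[order(loc$start), , drop = FALSE]
  loc$site_id <- sprintf("site%05d", seq_len(m))

  n_fp <- round(cfg$fp_locus_fraction * m)
  n_clean <- round(cfg$clean_fraction * m)
  labels <- rep("true_variant", m)
  special <- sample.int(m, n_fp + n_clean)
  labels[special[seq_len(n_fp)]] <- "reproducible_false"
  if (n_clean > 0) labels[special[n_fp + seq_len(n_clean)]] <- "clean"
  q <- ifelse(labels == "true_variant",
              stats::runif(m, cfg$q_range[1], cfg$q_range[2]), NA_real_)

  ## true genotypes ----------------------------------------------------------
  n_par <- length(parent_ids); n_kid <- length(child_ids)
  g_true <- matrix(0L, m, nrow(ped), dimnames = list(loc$site_id, ped$iid))
  tv <- which(labels == "true_variant")
  if (length(tv)) {
    ## founder genotypes: binomial(2, q) per parent per site
    gp <- matrix(stats::rbinom(length(tv) * n_par, 2, rep(q[tv], n_par)),
                 nrow = length(tv))
    g_true[tv, parent_ids] <- gp
    ## children: one allele from each parent
    kid_fam <- match(ped$fid[match(child_ids, ped$iid)], fid)
    pa_col <- match(paste0(fid[kid_fam], "_p1"), parent_ids)
    ma_col <- match(paste0(fid[kid_fam], "_p2"), parent_ids)
    for (j in seq_len(n_kid)) {
      gpa <- gp[, pa_col[j]]; gma <- gp[, ma_col[j]]
      a1 <- stats::rbinom(length(tv), 1, gpa / 2)
      a2 <- stats::rbinom(length(tv), 1, gma / 2)
      g_true[tv, child_ids[j]] <- a1 + a2
    }
  }
  g_true <- g_true[, out_samples, drop = FALSE]

  ## observed calls ----------------------------------------------------------
  ns <- length(out_samples)
  g_obs <- matrix(0L, m, ns, dimnames = list(loc$site_id, out_samples))
  u_det <- matrix(stats::runif(m * ns), m, ns)
  det_p <- matrix(0, m, ns)
  det_p[g_true == 1L] <- cfg$beta_het
  det_p[g_true == 2L] <- cfg$beta_hom
  detected <- u_det < det_p
  g_obs[detected & g_true == 1L] <- 1L
  g_obs[detected & g_true == 2L] <- 2L
  if (cfg$fp_random_rate > 0) {
    fp <- matrix(stats::runif(m * ns), m, ns) < cfg$fp_random_rate
    g_obs[fp & g_true == 0L & labels != "reproducible_false"] <- 1L
  }
  if (n_fp > 0) {
    rf <- which(labels == "reproducible_false")
    hit <- matrix(stats::runif(length(rf) * ns), length(rf), ns) <
      cfg$fp_locus_call_rate
    sub <- g_obs[rf, , drop = FALSE]
    sub[hit] <- 1L
    g_obs[rf, ] <- sub
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(m * ns), m, ns) < cfg$missing_rate
    g_obs[miss] <- NA_integer_
  }

  sites <- loc[, c("chrom", "start", "end", "site_id")]
  structure(list(ped = ped,
                 truth = call_matrix(g_true, sites = sites,
                                     samples = out_samples),
                 observed = call_matrix(g_obs, sites = sites,
                                        samples = out_samples),
                 labels = stats::setNames(labels, loc$site_id),
                 q = stats::setNames(q, loc$site_id),
                 cfg = cfg, seed = as.integer(seed)),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort: ", x$cfg$n_families, " families x ",
      x$cfg$sibs_per_family, " sibs",
      if (x$cfg$include_parents) " (+ parents)", ", ",
      x$cfg$n_sites, " sites\n", sep = "")
  lab <- table(x$labels)
  cat("  site labels: ", paste(names(lab), lab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Generate a spike-in truth list
#'
#' Produces a list of synthetic events (deletions, insertions, inversions,
#' tandem duplications) with sizes drawn uniformly from the given range,
#' half of each type heterozygous and half homozygous (odd counts give the
#' extra event to HET), placed without overlap on a toy multi-contig genome.
#' A configurable fraction of events is flagged `excluded`, modelling
#' spike-ins that failed to insert and must be dropped from sensitivity
#' denominators.
#'
#' @param n_del,n_ins,n_inv,n_dup per-type event counts. The defaults
#'   reproduce the composition 4,040 + 4,040 + 1,560 + 1,560 = 11,200.
#' @param size_range event sizes in bp (uniform integer draw; default
#'   2-5000).
#' @param fail_rate probability an event is flagged excluded (default
#'   0.0292).
#' @param contigs named numeric vector of contig lengths (default 22
#'   autosome-like contigs of 15 Mb).
#' @param seed integer seed.
#' @return A truth data.frame (see [read_truth_tsv()]) with an `excluded`
#'   column. Insertions are recorded as 1-bp anchor intervals carrying an
#'   `ins_size` column.
#' @export
generate_spikein_truth <- function(n_del = 4040, n_ins = 4040, n_inv = 1560,
                                   n_dup = 1560, size_range = c(2, 5000),
                                   fail_rate = 0.0292,
                                   contigs = stats::setNames(rep(1.5e7, 22),
                                                             paste0("chr", 1:22)),
                                   seed = 1) {
  stopifnot(n_del >= 0, n_ins >= 0, n_inv >= 0, n_dup >= 0,
            fail_rate >= 0, fail_rate <= 1, !is.null(names(contigs)))
  set.seed(as.integer(seed))
  counts <- c(DEL = n_del, INS = n_ins, INV = n_inv, DUP = n_dup)
  type <- rep(names(counts), counts)
  n <- length(type)
  if (n == 0) stop("no events requested")
  size <- sample(seq(size_range[1], size_range[2]), n, replace = TRUE)
  ## half HET / half HOM within each type; odd counts give HET the extra
  zyg <- unlist(lapply(counts, function(ct) {
    if (ct == 0) return(character(0))
    sample(rep(c("HET", "HOM"), c(ceiling(ct / 2), floor(ct / 2))))
  }), use.names = FALSE)
  ## genomic extent occupied: INS occupies a 1-bp anchor
  extent <- ifelse(type == "INS", 1L, size)
  contig_of <- sample(names(contigs), n, replace = TRUE,
                      prob = contigs / sum(contigs))
  out <- data.frame(chrom = character(n), start = numeric(n), end = numeric(n),
                    stringsAsFactors = FALSE)
  for (cn in names(contigs)) {
    idx <- which(contig_of == cn)
    if (!length(idx)) next
    total <- sum(extent[idx])
    if (total > contigs[[cn]]) {
      stop("contig ", cn, " (", contigs[[cn]], " bp) too small for ",
           length(idx), " events totalling ", total, " bp")
    }
    ord <- idx[sample.int(length(idx))]  # order along the contig
    gaps_at <- sort(stats::runif(length(idx), 0, contigs[[cn]] - total))
    start <- floor(gaps_at + cumsum(c(0, extent[ord][-length(ord)]))) + 1
    out$chrom[ord] <- cn
    out$start[ord] <- start
    out$end[ord] <- start + extent[ord]
  }
  truth <- data.frame(chrom = out$chrom, start = out$start, end = out$end,
                      type = type, zygosity = zyg,
                      event_id = sprintf("ev%05d", seq_len(n)),
                      excluded = stats::runif(n) < fail_rate,
                      ins_size = ifelse(type == "INS", size, NA_integer_),
                      stringsAsFactors = FALSE)
  validate_truth(truth)
}

#' Degrade a truth list into a simulated deletion call set
#'
#' Each non-excluded truth deletion is emitted as a call with probability
#' `beta_het` or `beta_hom` according to its zygosity, with both breakpoints
#' jittered by an integer drawn uniformly from `[-jitter_bp, jitter_bp]`
#' (shrunk per event so that a detected call always retains at least 50%
#' reciprocal overlap with its truth event). Undetected events produce no
#' call.
#'
#' @param truth a truth data.frame.
#' @param beta_het,beta_hom emission probabilities by zygosity.
#' @param jitter_bp maximum absolute breakpoint jitter in bp (default 10).
#' @param seed integer seed.
#' @return A site data.frame (`chrom`, `start`, `end`, `site_id`) usable as
#'   the `calls` argument of [match_calls()].
#' @export
degrade_truth_to_calls <- function(truth, beta_het, beta_hom, jitter_bp = 10,
                                   seed = 1) {
  stopifnot(beta_het >= 0, beta_het <= 1, beta_hom >= 0, beta_hom <= 1,
            jitter_bp >= 0)
  set.seed(as.integer(seed))
  truth <- eligible_truth(validate_truth(truth))
  if (!nrow(truth)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), site_id = character(0),
                      stringsAsFactors = FALSE))
  }
  beta <- ifelse(truth$zygosity == "HET", beta_het, beta_hom)
  emit <- stats::runif(nrow(truth)) < beta
  truth <- truth[emit, , drop = FALSE]
  if (!nrow(truth)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), site_id = character(0),
                      stringsAsFactors = FALSE))
  }
  size <- truth$end - truth$start
  ## cap jitter so min reciprocal overlap stays >= 0.5 even in the worst case
  j <- pmin(jitter_bp, pmax(0, floor((size - 1) / 4)))
  d1 <- floor(stats::runif(nrow(truth), -j, j + 1))
  d2 <- floor(stats::runif(nrow(truth), -j, j + 1))
  data.frame(chrom = truth$chrom, start = truth$start + d1,
             end = truth$end + d2,
             site_id = paste0("call_", truth$event_id),
             stringsAsFactors = FALSE)
}
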