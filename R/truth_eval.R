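#' Reciprocal overlap between two interval sets
#'
#' For paired half-open intervals a = `[start1, end1)` and b = `[start2,
#' end2)` returns the overlap length as a fraction of each interval. Two
#' intervals on different chromosomes overlap by zero.
#'
#' @param start1,end1,start2,end2 numeric vectors (recycled), half-open
#'   0-based coordinates, `end > start`.
#' @param chrom1,chrom2 optional chromosome names; if omitted all intervals
#'   are assumed comparable.
#' @return A two-column matrix `frac_a`, `frac_b`, both in \[0, 1\].
#' @examples
#' reciprocal_overlap(100, 200, 150, 250)  # 0.5, 0.5
#' @export
reciprocal_overlap <- function(start1, end1, start2, end2,
                               chrom1 = NULL, chrom2 = NULL) {
  if (any(end1 <= start1) || any(end2 <= start2)) {
    stop("intervals must have positive length")
  }
  ov <- pmax(0, pmin(end1, end2) - pmax(start1, start2))
  if (!is.null(chrom1) || !is.null(chrom2)) {
    if (is.null(chrom1) || is.null(chrom2)) stop("supply both chrom1 and chrom2 or neither")
    ov[chrom1 != chrom2] <- 0
  }
  cbind(frac_a = ov / (end1 - start1), frac_b = ov / (end2 - start2))
}

#' Read / write truth event lists
#'
#' Truth lists are BED-like TSV tables with header columns `chrom`, `start`,
#' `end` (0-based half-open), `type` (`DEL`, `INS`, `INV`, `DUP`),
#' `zygosity` (`HET` or `HOM`), `event_id` and optionally `excluded`
#' (insertion-failure flag).
#'
#' @param path file path.
#' @return `read_truth_tsv()` returns the validated data.frame.
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_truth(df)
}

#' @rdname read_truth_tsv
#' @param truth a truth data.frame as above.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(validate_truth(truth), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_truth <- function(truth) {
  truth <- as.data.frame(truth, stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "type", "zygosity", "event_id")
  missing_cols <- setdiff(needed, names(truth))
  if (length(missing_cols)) stop("truth list lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  if (!all(truth$type %in% c("DEL", "INS", "INV", "DUP"))) {
    stop("event types must be DEL, INS, INV or DUP")
  }
  if (!all(truth$zygosity %in% c("HET", "HOM"))) {
    stop("zygosity must be HET or HOM")
  }
  span <- truth$type %in% c("DEL", "INV", "DUP")
  if (any(truth$end[span] <= truth$start[span])) {
    stop("DEL/INV/DUP events must satisfy end > start")
  }
  if (anyDuplicated(truth$event_id)) stop("duplicate event ids")
  if (is.null(truth$excluded)) truth$excluded <- FALSE
  truth
}

## truth rows eligible for deletion-call matching/sensitivity
eligible_truth <- function(truth) {
  truth[truth$type == "DEL" & !truth$excluded, , drop = FALSE]
}

#' Match deletion calls to truth events by reciprocal overlap
#'
#' A truth event is detected when some call on the same chromosome overlaps
#' it with `min(frac_truth, frac_call) >= reciprocal_fraction`. Under
#' one-to-one assignment, qualifying pairs are accepted greedily in
#' decreasing order of the minimum fraction, ties broken by smaller truth
#' start then lexicographic ids, and each truth event and each call
#' participate in at most one accepted pair. Only `DEL` truth events not
#' flagged `excluded` participate.
#'
#' @param truth truth data.frame (see [read_truth_tsv()]).
#' @param calls a [call_matrix()] or a site data.frame with `chrom`, `start`,
#'   `end`, `site_id`.
#' @param reciprocal_fraction required reciprocal overlap, in (0, 1\];
#'   default 0.5.
#' @param one_to_one if `TRUE` (default) apply the greedy one-to-one
#'   assignment; otherwise return every qualifying pair.
#' @return data.frame with columns `truth_id`, `call_id`, `frac_truth`,
#'   `frac_call`.
#' @export
match_calls <- function(truth, calls, reciprocal_fraction = 0.5,
                        one_to_one = TRUE) {
  if (!(reciprocal_fraction > 0 && reciprocal_fraction <= 1)) {
    stop("reciprocal_fraction must be in (0, 1]")
  }
  truth <- eligible_truth(validate_truth(truth))
  sites <- if (inherits(calls, "call_matrix")) calls$sites else as.data.frame(calls)
  empty <- data.frame(truth_id = character(0), call_id = character(0),
                      frac_truth = numeric(0), frac_call = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(truth) || !nrow(sites)) return(empty)

  gr_t <- GenomicRanges::GRanges(truth$chrom,
                                 IRanges::IRanges(truth$start + 1, truth$end))
  gr_c <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$start + 1, sites$end))
  hits <- GenomicRanges::findOverlaps(gr_t, gr_c)
  if (!length(hits)) return(empty)
  ti <- S4Vectors::queryHits(hits); ci <- S4Vectors::subjectHits(hits)
  fr <- reciprocal_overlap(truth$start[ti], truth$end[ti],
                           sites$start[ci], sites$end[ci])
  keep <- pmin(fr[, 1], fr[, 2]) >= reciprocal_fraction
  if (!any(keep)) return(empty)
  cand <- data.frame(truth_id = truth$event_id[ti][keep],
                     call_id = sites$site_id[ci][keep],
                     frac_truth = fr[keep, 1], frac_call = fr[keep, 2],
                     min_frac = pmin(fr[, 1], fr[, 2])[keep],
                     t_start = truth$start[ti][keep],
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$min_frac, cand$t_start, cand$truth_id, cand$call_id), ]
  if (one_to_one) {
    used_t <- character(0); used_c <- character(0); take <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (cand$truth_id[i] %in% used_t || cand$call_id[i] %in% used_c) next
      take[i] <- TRUE
      used_t <- c(used_t, cand$truth_id[i]); used_c <- c(used_c, cand$call_id[i])
    }
    cand <- cand[take, , drop = FALSE]
  }
  rownames(cand) <- NULL
  cand[, c("truth_id", "call_id", "frac_truth", "frac_call")]
}

#' Spike-in sensitivity per size bin and zygosity
#'
#' Sensitivity is the number of detected events over the number of true
#' events; cells with no true events are reported as `NA`, not 0. Only `DEL`
#' truth events not flagged `excluded` enter the denominator.
#'
#' @param truth truth data.frame.
#' @param matches output of [match_calls()] (rows referencing unknown truth
#'   ids raise an error).
#' @param bins optional [size_bin_scheme()]; when supplied, rows are
#'   stratified by bin (plus a pooled row labelled `"all"`).
#' @param stratify_zygosity also stratify rows by HET/HOM (plus pooled).
#' @return data.frame with columns `bin`, `zygosity`, `n_true`, `n_detected`,
#'   `sensitivity`.
#' @export
sensitivity_table <- function(truth, matches, bins = NULL,
                              stratify_zygosity = FALSE) {
  truth <- eligible_truth(validate_truth(truth))
  unknown <- setdiff(matches$truth_id, truth$event_id)
  if (length(unknown)) stop("match references unknown truth id(s): ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  detected <- truth$event_id %in% matches$truth_id
  size <- truth$end - truth$start
  bin <- if (is.null(bins)) rep("all", nrow(truth)) else assign_size_bin(size, bins)
  bin_levels <- if (is.null(bins)) "all" else c(bins$label, "all")
  zyg_levels <- if (stratify_zygosity) c("HET", "HOM", "pooled") else "pooled"
  rows <- list()
  for (b in bin_levels) {
    in_b <- if (b == "all") rep(TRUE, nrow(truth)) else (!is.na(bin) & bin == b)
    for (z in zyg_levels) {
      in_z <- if (z == "pooled") rep(TRUE, nrow(truth)) else truth$zygosity == z
      sel <- in_b & in_z
      n_true <- sum(sel); n_det <- sum(sel & detected)
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, zygosity = z, n_true = n_true, n_detected = n_det,
        sensitivity = if (n_true > 0) n_det / n_true else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate genotype-specific caller sensitivities from spike-ins
#'
#' `beta_het` is the fraction of heterozygous truth deletions detected,
#' `beta_hom` the fraction of homozygous ones, per size bin and pooled.
#'
#' @inheritParams sensitivity_table
#' @return data.frame with columns `bin`, `beta_het`, `beta_hom`,
#'   `n_het_true`, `n_het_detected`, `n_hom_true`, `n_hom_detected`. The
#'   pooled row has `bin == "all"`. Undefined cells (no truth events of that
#'   zygosity in the bin) are `NA` with a count of 0.
#' @export
estimate_beta <- function(truth, matches, bins = NULL) {
  tab <- sensitivity_table(truth, matches, bins = bins,
                           stratify_zygosity = TRUE)
  het <- tab[tab$zygosity == "HET", ]
  hom <- tab[tab$zygosity == "HOM", ]
  out <- data.frame(bin = het$bin,
                    beta_het = het$sensitivity,
                    beta_hom = hom$sensitivity,
                    n_het_true = het$n_true, n_het_detected = het$n_detected,
                    n_hom_true = hom$n_true, n_hom_detected = hom$n_detected,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
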