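#' Score every site of a call set with the D-score
#'
#' For each deletion site: the overall call rate f, the implied allele
#' frequency q (given the caller sensitivities), the model sibling sharing
#' probability f_sib, the observed sharing (k, n) over ordered full-sib
#' pairs, and the D-score. Sites with fewer than `min_calls` called samples,
#' or no informative sib pairs, are reported with the corresponding status
#' and no score.
#'
#' @param calls a [call_matrix()].
#' @param ped a [pedigree()] covering (at least) the matrix samples.
#' @param betas either a numeric vector `c(beta_het, beta_hom)` applied to
#'   every site, or a per-bin table from [estimate_beta()] (matched on the
#'   site's size bin, falling back to the pooled `"all"` row with a warning
#'   when a bin has no estimate).
#' @param bins optional [size_bin_scheme()] used to annotate sites and to
#'   look up per-bin betas and per-bin median summaries.
#' @param min_calls minimum called samples for a score (default 2).
#' @param strict strict tail inequalities in the score (default `TRUE`).
#' @param f_cohort compute f over `"all"` samples (default) or `"founders"`
#'   only.
#' @return An object of class `dscore_result`: list with `table` (one row
#'   per site: site_id, chrom, start, end, size, bin, f, q, f_sib, k, n, D,
#'   status), `by_bin` (per-bin median D over scored sites), and the call
#'   parameters. Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @export
score_callset <- function(calls, ped, betas, bins = NULL, min_calls = 2,
                          strict = TRUE, f_cohort = c("all", "founders")) {
  stopifnot(inherits(calls, "call_matrix"))
  f_cohort <- match.arg(f_cohort)
  sites <- calls$sites
  bin <- if (is.null(bins)) rep(NA_character_, nrow(sites)) else
    assign_size_bin(sites$size, bins)

  beta_tab <- NULL
  if (is.data.frame(betas)) {
    beta_tab <- betas
    if (!all(c("bin", "beta_het", "beta_hom") %in% names(beta_tab))) {
      stop("beta table must have columns bin, beta_het, beta_hom")
    }
    pooled <- beta_tab[beta_tab$bin == "all", , drop = FALSE]
    if (!nrow(pooled) || is.na(pooled$beta_het[1]) || is.na(pooled$beta_hom[1])) {
      stop("beta table needs a defined pooled row (bin == 'all')")
    }
  } else {
    if (length(betas) != 2 || any(is.na(betas))) {
      stop("betas must be c(beta_het, beta_hom) or an estimate_beta() table")
    }
  }
  site_betas <- function(b) {
    if (is.null(beta_tab)) return(as.numeric(betas))
    row <- if (!is.na(b)) beta_tab[beta_tab$bin == b, , drop = FALSE] else
      beta_tab[0, , drop = FALSE]
    if (!nrow(row) || is.na(row$beta_het[1]) || is.na(row$beta_hom[1])) {
      warning("no beta estimate for bin '", b, "': using pooled betas",
              call. = FALSE)
      row <- beta_tab[beta_tab$bin == "all", , drop = FALSE]
    }
    c(row$beta_het[1], row$beta_hom[1])
  }

  f_samples <- if (f_cohort == "all") calls$samples else
    intersect(founders(ped), calls$samples)
  if (!length(f_samples)) stop("no samples available for the call-rate cohort")

  ## sib pairs are the same for every site; enumerate once
  pairs <- full_sib_pairs(ped)
  pairs <- pairs[pairs$id1 %in% calls$samples & pairs$id2 %in% calls$samples, ,
                 drop = FALSE]
  i1 <- match(pairs$id1, calls$samples)
  i2 <- match(pairs$id2, calls$samples)

  n <- nrow(sites)
  out <- data.frame(site_id = sites$site_id, chrom = sites$chrom,
                    start = sites$start, end = sites$end, size = sites$size,
                    bin = bin, f = NA_real_, q = NA_real_, f_sib = NA_real_,
                    k = NA_integer_, n = NA_integer_, D = NA_real_,
                    status = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    g <- calls$genotypes[i, ]
    gf <- g[f_samples]
    n_called <- sum(g >= 1L, na.rm = TRUE)
    if (all(is.na(gf)) || n_called < min_calls) {
      out$status[i] <- "too_few_calls"
      next
    }
    f <- overall_call_rate(gf)
    bb <- site_betas(bin[i])
    pk <- call_rate_peak(bb[1], bb[2])
    ## call rates beyond the attainable ceiling (artifact-like sites) are
    ## saturated at the peak frequency rather than rejected
    q <- if (f > pk$f) pk$q else infer_allele_frequency(f, bb[1], bb[2])
    f_sib <- sib_sharing_prob(q, bb[1], bb[2])
    g1 <- g[i1]; g2 <- g[i2]
    ok <- !is.na(g1) & !is.na(g2)
    c1 <- g1[ok] >= 1L; c2 <- g2[ok] >= 1L
    obs <- list(k = 2L * sum(c1 & c2), n = sum(c1) + sum(c2))
    sc <- d_score(obs$k, obs$n, f, f_sib, n_called = n_called,
                  min_calls = min_calls, strict = strict)
    out$f[i] <- f; out$q[i] <- q; out$f_sib[i] <- f_sib
    out$k[i] <- sc$k; out$n[i] <- sc$n; out$D[i] <- sc$D
    out$status[i] <- sc$status
  }

  by_bin <- NULL
  scored <- !is.na(out$D)
  bins_present <- if (is.null(bins)) "all" else c(bins$label, "all")
  by_bin <- do.call(rbind, lapply(bins_present, function(b) {
    sel <- scored & (b == "all" | (!is.na(out$bin) & out$bin == b))
    data.frame(bin = b, n_scored = sum(sel),
               median_D = if (any(sel)) stats::median(out$D[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  structure(list(table = out, by_bin = by_bin, min_calls = min_calls,
                 strict = strict, f_cohort = f_cohort,
                 betas = if (is.null(beta_tab)) as.numeric(betas) else beta_tab),
            class = "dscore_result")
}

#' @export
print.dscore_result <- function(x, ...) {
  tab <- x$table
  cat("D-score scan: ", nrow(tab), " site(s)\n", sep = "")
  st <- table(tab$status)
  cat("  status: ", paste(names(st), st, sep = "=", collapse = ", "), "\n", sep = "")
  d <- tab$D[!is.na(tab$D)]
  if (length(d)) {
    cat(sprintf("  D: median %.3f  IQR [%.3f, %.3f]\n",
                stats::median(d), stats::quantile(d, 0.25),
                stats::quantile(d, 0.75)))
  }
  invisible(x)
}

#' @export
summary.dscore_result <- function(object, ...) {
  cat("D-score scan summary\n")
  cat("  min_calls = ", object$min_calls, ", ",
      if (object$strict) "strict" else "non-strict", " tails, f over ",
      object$f_cohort, " samples\n", sep = "")
  print(object$by_bin, row.names = FALSE)
  invisible(object$by_bin)
}

#' @export
as.data.frame.dscore_result <- function(x, ...) x$table

#' Boxplot of D-scores by size bin
#'
#' @param x a `dscore_result`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.dscore_result <- function(x, ...) {
  tab <- x$table[!is.na(x$table$D), , drop = FALSE]
  if (!nrow(tab)) stop("no scored sites to plot")
  grp <- if (all(is.na(tab$bin))) rep("all", nrow(tab)) else tab$bin
  graphics::boxplot(tab$D ~ factor(grp, levels = unique(x$by_bin$bin)),
                    xlab = "size bin (bp)", ylab = "D-score", ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(x)
}

#' Write a D-score table as TSV
#'
#' @param x a `dscore_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dscore_tsv <- function(x, path) {
  stopifnot(inherits(x, "dscore_result"))
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
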