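#' Genotype codes
#'
#' Genotypes are stored as integers: `0` = homozygous reference, `1` =
#' heterozygous, `2` = homozygous alternate, `NA` = missing. A sample is
#' "called" at a site when its genotype is heterozygous or homozygous
#' alternate.
#'
#' @param g integer vector of genotype codes.
#' @return `is_called()` returns a logical vector (`NA` where the genotype is
#'   missing).
#' @examples
#' is_called(c(0L, 1L, 2L, NA))
#' @export
is_called <- function(g) {
  ifelse(is.na(g), NA, g >= 1L)
}

#' Deletion call matrix
#'
#' Container for a biallelic-deletion call set: a site table (half-open
#' 0-based coordinates) and a sites x samples integer genotype matrix (see
#' [is_called()] for the coding).
#'
#' @param genotypes integer matrix, sites in rows, samples in columns. Values
#'   must be 0/1/2/NA.
#' @param sites data.frame with columns `chrom`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `site_id`. A `size` column is derived as
#'   `end - start` (and checked if present).
#' @param samples character vector of unique sample ids; defaults to the
#'   column names of `genotypes`.
#' @return An object of class `call_matrix`: a list with elements `sites`
#'   (data.frame, including `size`), `samples` and `genotypes` (dimnamed by
#'   `site_id` x sample).
#' @examples
#' cm <- call_matrix(
#'   rbind(c(1L, 0L, NA)),
#'   sites = data.frame(chrom = "chr1", start = 100, end = 144, site_id = "d1"),
#'   samples = c("s1", "s2", "s3")
#' )
#' cm$sites$size
#' @export
call_matrix <- function(genotypes, sites, samples = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) stop("sample ids are required (none supplied and no column names)")
  samples <- as.character(samples)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  needed <- c("chrom", "start", "end", "site_id")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(sites) != nrow(genotypes)) {
    stop("genotype matrix has ", nrow(genotypes), " rows but site table has ",
         nrow(sites), " sites")
  }
  if (length(samples) != ncol(genotypes)) {
    stop("genotype matrix has ", ncol(genotypes), " columns but ",
         length(samples), " sample ids were given")
  }
  if (anyDuplicated(samples)) stop("duplicate sample ids: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids: ",
                                         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) stop("genotype codes must be 0, 1, 2 or NA")
  if (any(sites$end <= sites$start)) stop("all sites must satisfy end > start")
  size <- as.integer(sites$end - sites$start)
  if (!is.null(sites$size) && !all(sites$size == size)) {
    stop("site table 'size' column disagrees with end - start")
  }
  sites$size <- size
  sites$chrom <- as.character(sites$chrom)
  sites$site_id <- as.character(sites$site_id)
  rownames(sites) <- NULL
  dimnames(genotypes) <- list(sites$site_id, samples)
  structure(list(sites = sites, samples = samples, genotypes = genotypes),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat("call_matrix: ", nrow(x$sites), " deletion site(s) x ",
      length(x$samples), " sample(s)\n", sep = "")
  cat("  size range: ", min(x$sites$size), "-", max(x$sites$size), " bp\n", sep = "")
  g <- x$genotypes
  cat("  genotypes: ", sum(g == 0, na.rm = TRUE), " hom-ref, ",
      sum(g == 1, na.rm = TRUE), " het, ", sum(g == 2, na.rm = TRUE),
      " hom-alt, ", sum(is.na(g)), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.call_matrix <- function(x) dim(x$genotypes)

#' Subset a call matrix
#'
#' @param x a [call_matrix()].
#' @param i site index (integer, logical or site ids).
#' @param j sample index (integer, logical or sample ids).
#' @param ... unused.
#' @return A `call_matrix` restricted to the selected sites and samples.
#' @export
`[.call_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(i)) i <- match(i, x$sites$site_id)
  if (is.character(j)) j <- match(j, x$samples)
  call_matrix(x$genotypes[i, j, drop = FALSE],
              sites = x$sites[i, , drop = FALSE],
              samples = x$samples[j])
}

## per-site genotype counts used by several modules
site_counts <- function(cm) {
  g <- cm$genotypes
  data.frame(
    site_id = cm$sites$site_id,
    n_hom_ref = rowSums(g == 0, na.rm = TRUE),
    n_het = rowSums(g == 1, na.rm = TRUE),
    n_hom_alt = rowSums(g == 2, na.rm = TRUE),
    n_missing = rowSums(is.na(g)),
    stringsAsFactors = FALSE
  )
}
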