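#' Size-bin schemes for deletion lengths
#'
#' A scheme is an ordered set of disjoint integer-inclusive size intervals,
#' each with a label. Printed endpoints are inclusive on both sides, so the
#' bin "20-40" contains sizes 20..40.
#'
#' @param lower,upper integer vectors of inclusive bin endpoints (bp).
#' @param labels bin labels; default `"lower-upper"`.
#' @return An object of class `size_bin_scheme` (a data.frame with columns
#'   `lower`, `upper`, `label`).
#' @examples
#' assign_size_bin(44, validation_bins())
#' @export
size_bin_scheme <- function(lower, upper, labels = paste0(lower, "-", upper)) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (length(lower) != length(upper) || length(lower) != length(labels)) {
    stop("lower, upper and labels must have equal length")
  }
  if (any(upper < lower)) stop("each bin must satisfy upper >= lower")
  o <- order(lower)
  lower <- lower[o]; upper <- upper[o]; labels <- as.character(labels)[o]
  if (length(lower) > 1 && any(lower[-1] <= upper[-length(upper)])) {
    stop("size bins overlap")
  }
  if (anyDuplicated(labels)) stop("duplicate bin labels")
  structure(data.frame(lower = lower, upper = upper, label = labels,
                       stringsAsFactors = FALSE),
            class = c("size_bin_scheme", "data.frame"))
}

#' @describeIn size_bin_scheme The six bins used for validating deletion
#'   calls: 2-19, 20-40, 41-60, 61-80, 81-100 and 101-900 bp.
#' @export
validation_bins <- function() {
  size_bin_scheme(lower = c(2, 20, 41, 61, 81, 101),
                  upper = c(19, 40, 60, 80, 100, 900))
}

#' Assign deletion sizes to bins
#'
#' @param size integer vector of deletion sizes (bp), all >= 1.
#' @param scheme a [size_bin_scheme()].
#' @return Character vector of bin labels; `NA` for sizes outside all bins.
#' @export
assign_size_bin <- function(size, scheme) {
  stopifnot(inherits(scheme, "size_bin_scheme"))
  if (any(size < 1, na.rm = TRUE)) stop("sizes must be >= 1")
  idx <- rep(NA_integer_, length(size))
  for (b in seq_len(nrow(scheme))) {
    hit <- !is.na(size) & size >= scheme$lower[b] & size <= scheme$upper[b]
    idx[hit] <- b
  }
  scheme$label[idx]
}
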