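#' Construct a pedigree
#'
#' A pedigree maps samples to families, parents and affection status. Parents
#' referenced by any sample must themselves have a row; affection is coded
#' `"affected"`, `"unaffected"` or `"unknown"`.
#'
#' @param df data.frame with columns `fid`, `iid`, `pat`, `mat`, `sex`,
#'   `affection`. `pat`/`mat` use `NA` (or `"0"`) for a missing parent; `sex`
#'   is 1 = male, 2 = female, 0/NA = unknown.
#' @return An object of class `pedigree` (a validated data.frame).
#' @seealso [read_pedigree()], [full_sib_pairs()], [founders()]
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("fid", "iid", "pat", "mat", "sex", "affection")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) stop("pedigree lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  for (col in c("fid", "iid", "pat", "mat")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] %in% c("0", "", "NA")] <- NA_character_
  }
  if (any(is.na(df$iid))) stop("sample ids must be non-missing")
  if (anyDuplicated(df$iid)) {
    stop("duplicate sample id(s) in pedigree: ",
         paste(unique(df$iid[duplicated(df$iid)]), collapse = ", "))
  }
  referenced <- stats::na.omit(unique(c(df$pat, df$mat)))
  absent <- setdiff(referenced, df$iid)
  if (length(absent)) {
    stop("parent id(s) referenced but absent from pedigree: ",
         paste(absent, collapse = ", "))
  }
  if (!all(df$affection %in% c("affected", "unaffected", "unknown"))) {
    stop("affection must be 'affected', 'unaffected' or 'unknown'")
  }
  ## no sample may be its own ancestor
  parent_of <- function(id) {
    r <- df[match(id, df$iid), c("pat", "mat")]
    stats::na.omit(unlist(r, use.names = FALSE))
  }
  for (id in df$iid) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier)) {
      if (id %in% frontier) stop("sample ", id, " is its own ancestor")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a 6-column PED file
#'
#' Whitespace-delimited PED: family id, sample id, father, mother, sex,
#' affection. Affection is coded 2 = affected, 1 = unaffected, 0 or -9 =
#' unknown; parent id `0` means no parent recorded.
#'
#' @param path path to the PED file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6) stop("PED file must have 6 columns, found ", ncol(df))
  df <- df[, 1:6]
  names(df) <- c("fid", "iid", "pat", "mat", "sex", "affection")
  df$sex <- suppressWarnings(as.integer(df$sex))
  aff <- df$affection
  df$affection <- ifelse(aff == "2", "affected",
                  ifelse(aff == "1", "unaffected", "unknown"))
  bad <- !aff %in% c("2", "1", "0", "-9")
  if (any(bad)) stop("unrecognised affection code(s): ",
                     paste(unique(aff[bad]), collapse = ", "))
  pedigree(df)
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped a [pedigree()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$pat[is.na(out$pat)] <- "0"
  out$mat[is.na(out$mat)] <- "0"
  out$sex[is.na(out$sex)] <- 0L
  out$affection <- c(affected = "2", unaffected = "1", unknown = "0")[out$affection]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Founders of a pedigree
#'
#' Samples with no recorded parents.
#'
#' @param ped a [pedigree()].
#' @return Character vector of sample ids.
#' @export
founders <- function(ped) {
  ped$iid[is.na(ped$pat) & is.na(ped$mat)]
}

#' Enumerate full-sibling pairs
#'
#' Full siblings share both (non-missing) parents. Each unordered pair is
#' listed once; sibships of size k contribute choose(k, 2) pairs.
#'
#' @param ped a [pedigree()].
#' @return data.frame with columns `id1`, `id2`, `fid` (possibly 0 rows).
#' @export
full_sib_pairs <- function(ped) {
  has_both <- !is.na(ped$pat) & !is.na(ped$mat)
  kids <- ped[has_both, , drop = FALSE]
  out <- list()
  if (nrow(kids)) {
    key <- paste(kids$pat, kids$mat, sep = "\r")
    for (grp in split(seq_len(nrow(kids)), key)) {
      if (length(grp) < 2) next
      ids <- sort(kids$iid[grp])
      pr <- utils::combn(ids, 2)
      out[[length(out) + 1]] <- data.frame(
        id1 = pr[1, ], id2 = pr[2, ], fid = kids$fid[grp[1]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      fid = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$fid, res$id1, res$id2), , drop = FALSE]
  rownames(res) <- NULL
  res
}
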