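#' Read a biallelic deletion call set from VCF
#'
#' Parses a VCF 4.x file (via vcfR) and returns the biallelic deletion
#' records as a [call_matrix()]. Deletion extent is taken from the sequence
#' alleles (`len(REF) - len(ALT)`) when both are plain sequences, or from the
#' `END` INFO key for symbolic `<DEL>` records; when both are available they
#' must agree or the record is rejected. VCF's 1-based anchored coordinates
#' are converted to 0-based half-open intervals of the deleted bases at this
#' boundary, so a record at POS p deleting s bases yields the interval
#' `[p, p + s)`.
#'
#' @param path path to an (uncompressed or gzipped) VCF file with GT fields.
#' @param min_size,max_size retain only sites with `min_size <= size <=
#'   max_size` (bp).
#' @return A [call_matrix()]. Sites on X/Y carry `sex_chrom = TRUE` in the
#'   site table. Multiallelic and non-deletion records are skipped with a
#'   warning.
#' @export
read_deletion_vcf <- function(path, min_size = 1L, max_size = Inf) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF '", path, "' contains no records")
  n <- nrow(fix)
  pos <- suppressWarnings(as.numeric(fix$POS))
  if (any(is.na(pos))) {
    stop("malformed VCF '", path, "': non-numeric POS at record ",
         which(is.na(pos))[1])
  }
  info_get <- function(info, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]+)")
    val <- rep(NA_character_, length(info))
    has <- !is.na(info) & grepl(pat, info, perl = TRUE)
    val[has] <- sub(paste0(".*", pat, ".*"), "\\1", info[has], perl = TRUE)
    val
  }
  svtype <- info_get(fix$INFO, "SVTYPE")
  end_info <- suppressWarnings(as.numeric(info_get(fix$INFO, "END")))

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
  }
  symbolic <- grepl("^<", fix$ALT)
  seq_allele <- !symbolic & !multi & grepl("^[ACGTNacgtn]+$", fix$REF) &
    grepl("^[ACGTNacgtn]+$", fix$ALT)
  size_seq <- ifelse(seq_allele, nchar(fix$REF) - nchar(fix$ALT), NA_real_)
  size_end <- ifelse(!is.na(end_info), end_info - pos, NA_real_)

  keep <- !multi
  size <- rep(NA_real_, n)
  reject <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    is_del_sym <- symbolic[i] && identical(fix$ALT[i], "<DEL>")
    if (is_del_sym) {
      if (is.na(size_end[i]) || size_end[i] < 1) { reject[i] <- TRUE; next }
      size[i] <- size_end[i]
    } else if (seq_allele[i] && size_seq[i] >= 1) {
      if (!is.na(size_end[i]) && size_end[i] != size_seq[i]) { reject[i] <- TRUE; next }
      size[i] <- size_seq[i]
    } else {
      reject[i] <- TRUE  # not a deletion (insertion, SNV, other symbolic type)
    }
  }
  if (any(reject)) {
    warning(sum(reject), " non-deletion or inconsistent record(s) skipped")
  }
  keep <- keep & !reject & size >= min_size & size <= max_size
  if (!any(keep)) stop("no biallelic deletion sites in [", min_size, ", ",
                       max_size, "] bp in '", path, "'")

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  gclean <- gsub("|", "/", gt, fixed = TRUE)
  code[gclean %in% c("0/0")] <- 0L
  code[gclean %in% c("0/1", "1/0")] <- 1L
  code[gclean %in% c("1/1")] <- 2L
  unknown <- !is.na(gclean) & !gclean %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
  if (any(unknown)) warning(sum(unknown), " unrecognised GT value(s) set to missing")

  fixk <- fix[keep, , drop = FALSE]
  posk <- pos[keep]; sizek <- size[keep]
  ## Both record dialects anchor at POS (first REF base retained), so the
  ## deleted run is (POS, POS + size] 1-based = [POS, POS + size) 0-based;
  ## symbolic DELs with END likewise span (POS, END] 1-based = [POS, END) 0-based.
  start0 <- posk
  sites <- data.frame(
    chrom = fixk$CHROM,
    start = as.numeric(start0),
    end = as.numeric(start0 + sizek),
    site_id = ifelse(is.na(fixk$ID) | fixk$ID == ".",
                     paste0(fixk$CHROM, ":", posk, ":", sizek),
                     fixk$ID),
    stringsAsFactors = FALSE
  )
  sites$sex_chrom <- sites$chrom %in% c("X", "Y", "chrX", "chrY")
  call_matrix(code, sites = sites, samples = colnames(gt))
}

#' Write a call matrix as a symbolic-DEL VCF
#'
#' Emits a minimal VCF 4.2 file with one symbolic `<DEL>` record per site
#' (`SVTYPE=DEL`, `END`, `SVLEN`) and GT-only genotype columns. Reading the
#' file back with [read_deletion_vcf()] reproduces sites, sample order and
#' genotype codes exactly.
#'
#' @param cm a [call_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_deletion_vcf <- function(cm, path) {
  stopifnot(inherits(cm, "call_matrix"))
  if (any(cm$sites$start < 1)) {
    stop("cannot write sites with start < 1: the symbolic record needs an anchor base")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End of deleted interval (1-based inclusive)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deletion length\">",
    "##ALT=<ID=DEL,Description=\"Deletion\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cm$samples), collapse = "\t")
  ), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cm$genotypes + 1L],
                   nrow = nrow(cm$genotypes))
  gt_str[is.na(cm$genotypes)] <- "./."
  s <- cm$sites
  rec <- paste(s$chrom, format(s$start, scientific = FALSE, trim = TRUE),
               s$site_id, "N", "<DEL>", ".", "PASS",
               paste0("SVTYPE=DEL;END=", format(s$end, scientific = FALSE, trim = TRUE),
                      ";SVLEN=-", s$size),
               "GT", sep = "\t")
  body <- paste(rec, apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}
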