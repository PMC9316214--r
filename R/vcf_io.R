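# Genotype string conventions used across the package:
#   * a pool call is a diploid GT string, "0/1"; "|" is normalized to "/"
#   * "./." (or any GT containing ".") is a null call: no read support
#   * allele index 0 is REF; 1, 2, ... index the ordered ALT alleles;
#     the spanning-deletion symbol "*" is an ordinary ALT allele

GT_RE <- "^(\\.|[0-9]+)[/|](\\.|[0-9]+)$"

normalize_gt <- function(gt) {
  gt[is.na(gt) | gt == ""] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  # half-missing calls collapse to the null call: a pool call is either
  # fully observed or fully missing
  gt[grepl("\\.", gt)] <- "./."
  gt
}

#' Parse a diploid genotype string into allele indices
#'
#' @param gt a GT string such as `"0/1"`, `"1|1"` or `"./."`.
#' @return integer vector of length 2 (sorted allele indices), or `NULL`
#'   for a null call.
#' @examples
#' parse_gt("0|1")
#' parse_gt("./.")
#' @export
parse_gt <- function(gt) {
  gt <- normalize_gt(gt)
  if (!grepl(GT_RE, gt))
    stop(sprintf("malformed diploid GT '%s'", gt))
  if (gt == "./.") return(NULL)
  sort(as.integer(strsplit(gt, "/", fixed = TRUE)[[1]]))
}

#' Read a multi-sample pooled-sex VCF window
#'
#' Reads a VCF v4.x file, checks that every pool label of the study design
#' is present in the header, and returns one row per variant site inside
#' the window with the diploid genotype of every pool. Phased (`|`) and
#' unphased (`/`) separators are treated identically; a pool with no GT or
#' `./.` gets a null call. Records are returned sorted by position.
#'
#' @param path VCF file (plain or bgzipped).
#' @param design an [study_design()] object; all of its pool labels must be
#'   VCF sample names.
#' @param window optional [genomic_window()]; only records on its chromosome
#'   with `start <= POS <= end` are returned.
#' @param pass_only if `TRUE`, keep only records whose FILTER is `PASS` or
#'   `.` (by default no quality filtering is applied before model
#'   filtering).
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated ALT alleles) and one normalized GT column per pool
#'   label.
#' @export
read_pool_vcf <- function(path, design, window = NULL, pass_only = FALSE) {
  if (!file.exists(path))
    stop(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  pools <- design_pools(design)

  vcf_samples <- colnames(v@gt)
  vcf_samples <- vcf_samples[vcf_samples != "FORMAT"]
  missing <- setdiff(pools, vcf_samples)
  if (length(missing))
    stop(sprintf("design pool label(s) missing from VCF header: %s",
                 paste(missing, collapse = ", ")))

  empty <- function() {
    out <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    for (p in pools) out[[p]] <- character()
    out
  }
  if (nrow(v@fix) == 0L) return(empty())

  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.numeric(fix$POS))
  bad <- which(is.na(pos) | is.na(fix$REF) | fix$REF == "")
  if (length(bad))
    stop(sprintf("malformed VCF record at data line %d (POS/REF unparsable)",
                 bad[1]))

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, vcf_samples))

  out <- data.frame(chrom = fix$CHROM, pos = pos, ref = fix$REF,
                    alt = ifelse(is.na(fix$ALT), ".", fix$ALT),
                    stringsAsFactors = FALSE)
  for (p in pools) {
    raw <- gt[, p]
    nonnull <- !(is.na(raw) | raw == "" | grepl("\\.", raw))
    badgt <- which(nonnull & !grepl(GT_RE, raw))
    if (length(badgt))
      stop(sprintf(
        "malformed or non-diploid GT '%s' for pool %s at data line %d",
        raw[badgt[1]], p, badgt[1]))
    out[[p]] <- normalize_gt(raw)
  }

  # allele indices must address REF + declared ALTs
  n_alt <- ifelse(out$alt == ".", 0L,
                  lengths(strsplit(out$alt, ",", fixed = TRUE)))
  for (p in pools) {
    idx <- strsplit(sub("\\./\\.", "", out[[p]]), "/", fixed = TRUE)
    mx <- vapply(idx, function(a)
      if (length(a)) max(as.integer(a)) else -1L, integer(1))
    badix <- which(mx > n_alt)
    if (length(badix))
      stop(sprintf(
        "allele index out of range for pool %s at data line %d", p, badix[1]))
  }

  if (pass_only && "FILTER" %in% names(fix))
    out <- out[fix$FILTER %in% c("PASS", ".", NA), , drop = FALSE]
  if (!is.null(window))
    out <- out[out$chrom == window$chrom &
               out$pos >= window$start & out$pos <= window$end, ,
               drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a variant table as a minimal multi-sample VCF
#'
#' Used by the synthetic-data generators and for building worked-example
#' fixtures. Emits a VCF v4.2 header with one sample column per design
#' pool (females first, in design order).
#'
#' @param variants data frame as returned by [read_pool_vcf()].
#' @param design an [study_design()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pool_vcf <- function(variants, design, path) {
  pools <- design_pools(design)
  chroms <- unique(variants$chrom)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sdscan",
           sprintf("##contig=<ID=%s>", chroms),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", pools), collapse = "\t"))
  body <- character(0)
  if (nrow(variants)) {
    gts <- do.call(cbind, lapply(pools, function(p) variants[[p]]))
    body <- paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                         trim = TRUE),
                  ".", variants$ref, variants$alt, ".", ".", ".", "GT",
                  apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a concordance scan report as TSV
#'
#' Column layout mirrors the worked-example table of the analysis:
#' Position, REF, ALT, per-species female/male genotypes, the fitted
#' model, male-allele conservation, region label and flanking genes.
#'
#' @param scan result of [scan_window()].
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(scan, path) {
  res <- scan$results
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
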