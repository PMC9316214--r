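STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Build a gene segment table
#'
#' @param kind character vector of `"exon"` / `"intron"`.
#' @param size segment sizes in bp.
#' @param sequence optional nucleotide sequences (length must equal
#'   `size`); by convention introns are written lowercase, exons
#'   uppercase, but parsing is case-insensitive and the `kind` column is
#'   authoritative.
#' @return data frame with `kind`, `ordinal` (1-based within kind),
#'   `size`, `sequence`.
#' @export
gene_segments <- function(kind, size, sequence = NULL) {
  kind <- match.arg(kind, c("exon", "intron"), several.ok = TRUE)
  if (is.null(sequence)) sequence <- rep(NA_character_, length(kind))
  ordinal <- stats::ave(seq_along(kind), kind, FUN = seq_along)
  data.frame(kind = kind, ordinal = ordinal, size = as.numeric(size),
             sequence = as.character(sequence), stringsAsFactors = FALSE)
}

#' Build and validate an exon/intron gene model
#'
#' Segments must alternate exon/intron, starting and ending with an
#' exon. Genomic size is the sum of all segment sizes; transcript size
#' the sum of exon sizes. When sequences are supplied, canonical
#' splice-site boundaries (introns begin `gt`, end `ag`) and open
#' reading frame structure (first ATG of the spliced transcript to an
#' in-frame stop) are checked. Validation is reporting, not rejection: a
#' model violating a rule is still constructed, with the violations
#' collected, so noncanonical structures can be examined.
#'
#' @param segments data frame from [gene_segments()] (columns `kind`,
#'   `size`, optional `sequence`).
#' @return list of class `gene_model`: `segments`, `genomic_size`,
#'   `transcript_size`, `transcript` (spliced exon sequence or `NA`),
#'   `cds`, `protein`, and `validation` (data frame `segment`, `check`,
#'   `ok`, `detail`).
#' @examples
#' gm <- build_gene_model(gene_segments(
#'   c("exon", "intron", "exon", "intron", "exon"),
#'   c(174, 1290, 147, 122, 931)))
#' gm$genomic_size    # 2664
#' gm$transcript_size # 1252
#' @export
build_gene_model <- function(segments) {
  kinds <- segments$kind
  n <- length(kinds)
  expected <- rep(c("exon", "intron"), length.out = n)
  if (n < 1L || !identical(kinds, expected) || kinds[n] != "exon")
    stop("segments must alternate exon/intron, exon-first and exon-last")
  if (any(segments$size < 1)) stop("segment sizes must be >= 1")

  val <- list()
  add <- function(segment, check, ok, detail = "")
    val[[length(val) + 1L]] <<- data.frame(segment = segment,
                                           check = check, ok = ok,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  has_seq <- !is.na(segments$sequence) & nzchar(segments$sequence)
  for (i in which(has_seq)) {
    s <- segments$sequence[i]
    lab <- paste(kinds[i], sum(kinds[seq_len(i)] == kinds[i]))
    if (nchar(s) != segments$size[i])
      add(lab, "length", FALSE,
          sprintf("sequence length %d != size %d", nchar(s),
                  segments$size[i]))
    if (kinds[i] == "intron") {
      add(lab, "splice_donor", grepl("^gt", tolower(s)),
          substr(tolower(s), 1, 2))
      add(lab, "splice_acceptor",
          grepl("ag$", tolower(s)),
          substr(tolower(s), nchar(s) - 1, nchar(s)))
    }
  }

  exons <- segments[kinds == "exon", , drop = FALSE]
  transcript <- NA_character_; cds <- NA_character_
  protein <- NA_character_
  if (all(!is.na(exons$sequence) & nzchar(exons$sequence))) {
    transcript <- toupper(paste(exons$sequence, collapse = ""))
    atg <- regexpr("ATG", transcript, fixed = TRUE)
    if (atg < 0) {
      add("transcript", "start_codon", FALSE, "no ATG found")
    } else {
      tr <- tryCatch(translate_cds(transcript, atg), error = identity)
      if (inherits(tr, "error")) {
        add("transcript", "orf", FALSE, conditionMessage(tr))
      } else {
        cds <- substr(transcript, atg, atg + tr$cds_length - 1)
        protein <- tr$protein
        add("transcript", "start_codon", TRUE, "ATG")
        add("transcript", "stop_codon", TRUE,
            substr(cds, nchar(cds) - 2, nchar(cds)))
        add("transcript", "frame", nchar(cds) %% 3 == 0, "")
      }
    }
  }

  validation <- if (length(val)) do.call(rbind, val) else
    data.frame(segment = character(), check = character(),
               ok = logical(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(segments = segments,
                 genomic_size = sum(segments$size),
                 transcript_size = sum(exons$size),
                 transcript = transcript, cds = cds, protein = protein,
                 validation = validation),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %d exon(s), %d intron(s); genomic %d bp, transcript %d bp\n",
              sum(x$segments$kind == "exon"),
              sum(x$segments$kind == "intron"),
              x$genomic_size, x$transcript_size))
  if (!is.na(x$protein))
    cat(sprintf("  protein: %d aa\n", nchar(x$protein)))
  bad <- x$validation[!x$validation$ok, , drop = FALSE]
  if (nrow(bad))
    cat(sprintf("  %d validation violation(s)\n", nrow(bad)))
  invisible(x)
}

#' Translate a CDS from a spliced transcript
#'
#' Standard-code translation starting at the ATG at `atg_offset`,
#' continuing to the first in-frame stop codon (TAA/TAG/TGA), which is
#' excluded from the protein but included in the CDS length.
#'
#' @param transcript spliced transcript nucleotide sequence.
#' @param atg_offset 1-based offset of the initiation ATG.
#' @return list: `protein` (amino-acid string), `cds_length` (bp,
#'   including the stop codon).
#' @examples
#' translate_cds("ATGAAATGA", 1)  # protein "MK", CDS length 9
#' @export
translate_cds <- function(transcript, atg_offset) {
  transcript <- toupper(transcript)
  if (substr(transcript, atg_offset, atg_offset + 2) != "ATG")
    stop(sprintf("no ATG at offset %d", atg_offset))
  code <- Biostrings::GENETIC_CODE
  aa <- character(0)
  i <- atg_offset
  repeat {
    codon <- substr(transcript, i, i + 2)
    if (nchar(codon) < 3)
      stop("no in-frame stop codon before the transcript end")
    if (codon %in% STOP_CODONS)
      return(list(protein = paste(aa, collapse = ""),
                  cds_length = i + 3 - atg_offset))
    aa <- c(aa, unname(code[codon]))
    i <- i + 3
  }
}

#' Amplicon coordinates and size from a primer pair
#'
#' @param accession template sequence accession.
#' @param start,end 1-based inclusive amplicon bounds on the template.
#' @param marker marker name.
#' @return one-row data frame: `marker`, `accession`, `start`, `end`,
#'   `size` where `size = end - start + 1`.
#' @examples
#' amplicon_from_primers("LOC116310109", 1520, 1821, "LG1y")$size  # 302
#' @export
amplicon_from_primers <- function(accession, start, end, marker) {
  if (any(start < 1)) stop("start must be >= 1")
  if (any(end < start)) stop("amplicon end before start")
  data.frame(marker = marker, accession = accession,
             start = as.numeric(start), end = as.numeric(end),
             size = as.numeric(end) - as.numeric(start) + 1,
             stringsAsFactors = FALSE)
}

#' Recompute and check the size column of a primer coordinate table
#'
#' @param table data frame with columns `marker`, `accession`, `start`,
#'   `end` and optionally a declared `size` to cross-check.
#' @return the table with `size` recomputed and, when a declared size
#'   was present, `declared_size` and `size_ok`.
#' @export
check_amplicon_table <- function(table) {
  out <- amplicon_from_primers(table$accession, table$start, table$end,
                               table$marker)
  if ("size" %in% names(table)) {
    out$declared_size <- table$size
    out$size_ok <- out$size == table$size
  }
  out
}
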