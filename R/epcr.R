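# Electronic PCR: a locus or transcript is "detected" in a raw read
# library when at least `min_reads` reads share an exact word of length
# `word_size` with a probe sequence, on either strand. Exact 64-mer
# sharing is a deterministic proxy for high-identity BLASTN seeding.

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

seq_words <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1), k:n)
}

normalize_probe <- function(sequence) {
  s <- toupper(gsub("\\s", "", sequence))
  if (!grepl("^[ACGT]+$", s))
    stop("probe sequence must contain only A/C/G/T after normalization")
  s
}

#' Count reads sharing an exact word with a probe
#'
#' A read is a hit when it contains at least one exact word of length
#' `word_size` also present in the probe (or in its reverse complement);
#' each read counts at most once regardless of how many words it shares.
#' Ambiguity codes (N etc.) in reads match nothing.
#'
#' @param probe probe nucleotide sequence (A/C/G/T; upper-cased
#'   internally). Must be at least `word_size` long.
#' @param reads character vector of read sequences (or a
#'   `DNAStringSet`).
#' @param word_size exact-match word length in bp (default 64; must be
#'   at least 8).
#' @return integer hit count.
#' @export
probe_hits <- function(probe, reads, word_size = 64) {
  if (word_size < 8) stop("word_size must be >= 8")
  probe <- normalize_probe(probe)
  if (nchar(probe) < word_size)
    stop("probe is shorter than the word size")
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  words <- unique(c(seq_words(probe, word_size),
                    seq_words(revcomp(probe), word_size)))
  hits <- vapply(toupper(reads), function(r)
    any(seq_words(r, word_size) %in% words), logical(1),
    USE.NAMES = FALSE)
  sum(hits)
}

#' Read a FASTA/FASTQ read library
#'
#' @param path sequence file (gzip accepted).
#' @param id library identifier; defaults to the file name.
#' @param format `"fasta"`, `"fastq"` or `"auto"` (by extension).
#' @param total_reads externally declared library size; defaults to the
#'   number of reads in the file.
#' @return list of class `read_library`: `id`, `reads` (character),
#'   `total_reads`.
#' @export
read_library <- function(path, id = basename(path),
                         format = c("auto", "fasta", "fastq"),
                         total_reads = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  seqs <- as.character(Biostrings::readDNAStringSet(path, format = format))
  structure(list(id = id, reads = unname(seqs),
                 total_reads = if (is.null(total_reads)) length(seqs)
                               else as.numeric(total_reads)),
            class = "read_library")
}

#' RPKM from probe hit counts
#'
#' Reads per kilobase of probe per million library reads:
#' `hits * 1e9 / (total_reads * probe_length_bp)`. The denominator uses
#' total supplied library reads.
#'
#' @param hits number of hit reads.
#' @param total_reads library size.
#' @param probe_length probe length in bp.
#' @return numeric RPKM; `NA` when `total_reads` is 0 (and `hits` is 0).
#' @examples
#' rpkm(10, 1e6, 147)  # ~68.03
#' @export
rpkm <- function(hits, total_reads, probe_length) {
  if (total_reads == 0) {
    if (hits > 0)
      stop("impossible state: hits reported from an empty library")
    return(NA_real_)
  }
  hits * 1e9 / (total_reads * probe_length)
}

#' Electronic-PCR report for one probe against one library
#'
#' @param probe_id probe identifier.
#' @param probe probe sequence.
#' @param library a [read_library()].
#' @param word_size exact-match word length (default 64).
#' @param min_reads detection threshold: at least this many hit reads
#'   (default 3).
#' @return one-row data frame: `probe_id`, `library_id`, `hit_count`,
#'   `detected`, `rpkm`.
#' @export
epcr_report <- function(probe_id, probe, library, word_size = 64,
                        min_reads = 3) {
  h <- probe_hits(probe, library$reads, word_size)
  data.frame(probe_id = probe_id, library_id = library$id,
             hit_count = h, detected = h >= min_reads,
             rpkm = rpkm(h, library$total_reads,
                         nchar(normalize_probe(probe))),
             stringsAsFactors = FALSE)
}

#' Duplex presence/absence genotype from paired probe reports
#'
#' The duplex assay detects both chromosome forms of a presence/absence
#' system: an `LG1x` probe amplifying the gene-absent form and an `LG1y`
#' probe amplifying the gene-present form. `"yy?"` is flagged with a
#' query because the assay cannot distinguish yy from xy when only the
#' y-form probe amplifies in a diploid.
#'
#' @param lg1x,lg1y either logical detection flags or one-row
#'   [epcr_report()] data frames (their `detected` column is used).
#' @return `"xx"`, `"xy"`, `"yy?"` or `"fail"` (vectorized).
#' @export
duplex_genotype <- function(lg1x, lg1y) {
  if (is.data.frame(lg1x)) lg1x <- lg1x$detected
  if (is.data.frame(lg1y)) lg1y <- lg1y$detected
  out <- ifelse(lg1x & lg1y, "xy",
         ifelse(lg1x & !lg1y, "xx",
         ifelse(!lg1x & lg1y, "yy?", "fail")))
  as.character(out)
}
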