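# cox1 barcode species-identity checks. Distances are uncorrected
# p-distances on comparable alignment columns; ~1% divergence is the
# conventional interspecies floor for this marker.

#' Percent difference between two aligned barcode sequences
#'
#' Columns where either sequence carries a gap (`-`) or any character
#' other than A/C/G/T are excluded from both numerator and denominator;
#' the percent difference is mismatching comparable columns over
#' comparable columns, times 100 (an uncorrected p-distance).
#'
#' @param seq1,seq2 aligned nucleotide sequences of equal length.
#' @param threshold_percent interspecies divergence threshold; pairs
#'   below it are called same-species (default 1).
#' @return list of class `barcode_comparison`: `percent_difference`,
#'   `comparable_columns`, `mismatches`, `same_species_call`.
#' @examples
#' compare_barcodes("ACGTACGT", "ACGTACGA")$percent_difference  # 12.5
#' @export
compare_barcodes <- function(seq1, seq2, threshold_percent = 1) {
  if (nchar(seq1) != nchar(seq2))
    stop("aligned sequences must have equal length")
  a <- strsplit(toupper(seq1), "")[[1]]
  b <- strsplit(toupper(seq2), "")[[1]]
  comparable <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  n <- sum(comparable)
  if (n == 0L)
    stop("no comparable (both-ungapped, both-unambiguous) columns")
  mm <- sum(a[comparable] != b[comparable])
  pct <- mm / n * 100
  structure(list(percent_difference = pct, comparable_columns = n,
                 mismatches = mm,
                 same_species_call = pct < threshold_percent),
            class = "barcode_comparison")
}

#' All-pairs barcode comparison for a set of aligned sequences
#'
#' @param seqs named character vector (or `DNAStringSet`) of aligned
#'   barcode sequences, all equal length.
#' @param species declared species name for each sequence (same order);
#'   defaults to sequence names.
#' @param threshold_percent see [compare_barcodes()].
#' @return data frame with one row per unordered pair: ids, declared
#'   species, `percent_difference`, `same_species_call`,
#'   `declared_same`, `flagged`.
#' @export
compare_barcode_set <- function(seqs, species = NULL,
                                threshold_percent = 1) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs); seqs <- as.character(seqs); names(seqs) <- nm
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  if (is.null(species)) species <- ids
  pairs <- utils::combn(seq_along(seqs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cmp <- compare_barcodes(seqs[[i]], seqs[[j]], threshold_percent)
    data.frame(id1 = ids[i], id2 = ids[j],
               species1 = species[i], species2 = species[j],
               percent_difference = cmp$percent_difference,
               comparable_columns = cmp$comparable_columns,
               same_species_call = cmp$same_species_call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  classify_library_set(out)
}

#' Flag declared-species labels contradicted by barcode distance
#'
#' A pair is flagged as a misidentification candidate when the declared
#' relation of its labels (same vs different species name) contradicts
#' the distance-based call: different labels at sub-threshold divergence
#' (likely mislabelled duplicates of one species), or the same label at
#' super-threshold divergence (a cryptic split).
#'
#' @param comparisons data frame with columns `species1`, `species2`,
#'   `same_species_call` (as from [compare_barcode_set()]).
#' @return the data frame with logical columns `declared_same` and
#'   `flagged` added.
#' @export
classify_library_set <- function(comparisons) {
  comparisons$declared_same <-
    comparisons$species1 == comparisons$species2
  comparisons$flagged <-
    comparisons$declared_same != comparisons$same_species_call
  comparisons
}

#' Read aligned barcode sequences from FASTA
#'
#' @param path aligned FASTA (gaps as `-`); all sequences must share one
#'   alignment length.
#' @return named character vector of aligned sequences.
#' @export
read_barcode_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  lens <- unique(Biostrings::width(seqs))
  if (length(lens) != 1L)
    stop("barcode alignment has sequences of unequal length")
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
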