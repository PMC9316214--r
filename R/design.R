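#' Define a pooled-sex study design
#'
#' A study design lists, for each species (or strain), the sample labels of
#' its female and male pooled libraries as they appear in the VCF header.
#' Each pool is one whole-genome library of many same-sex individuals,
#' genotyped as a single diploid sample.
#'
#' @param species character vector of species/strain identifiers.
#' @param female_pool character vector, VCF sample label of each female pool.
#' @param male_pool character vector, VCF sample label of each male pool.
#'
#' @return A data frame of class `sd_design` with columns `species`,
#'   `female_pool`, `male_pool`.
#' @examples
#' study_design(c("As", "Sg", "Cz"),
#'              c("As_F", "Sg_F", "Cz_F"),
#'              c("As_M", "Sg_M", "Cz_M"))
#' @export
study_design <- function(species, female_pool, male_pool) {
  if (length(species) < 1L)
    stop("a study design needs at least one species pair")
  if (length(female_pool) != length(species) ||
      length(male_pool) != length(species))
    stop("species, female_pool and male_pool must have equal length")
  pools <- c(female_pool, male_pool)
  if (anyDuplicated(pools))
    stop("pool labels must be unique across the design")
  out <- data.frame(species = as.character(species),
                    female_pool = as.character(female_pool),
                    male_pool = as.character(male_pool),
                    stringsAsFactors = FALSE)
  class(out) <- c("sd_design", "data.frame")
  out
}

#' All pool labels of a design, females first
#' @param design an [study_design()] object.
#' @return character vector of pool labels.
#' @export
design_pools <- function(design) {
  c(design$female_pool, design$male_pool)
}

#' Define a genomic analysis window
#'
#' Coordinates are 1-based and inclusive at both ends throughout the
#' package (VCF/GenBank convention).
#'
#' @param chrom sequence (chromosome / linkage group) name.
#' @param start,end 1-based inclusive bounds, `end >= start >= 1`.
#' @return A list of class `genomic_window`.
#' @examples
#' genomic_window("LG1", 25400000, 28700000)
#' @export
genomic_window <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start)
    stop("invalid window: need 1 <= start <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_window")
}

#' @export
print.genomic_window <- function(x, ...) {
  cat(sprintf("<genomic_window> %s:%s-%s (1-based inclusive)\n",
              x$chrom, format(x$start, big.mark = ","),
              format(x$end, big.mark = ",")))
  invisible(x)
}
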