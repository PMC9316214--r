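# Bundled worked-example data for the LG1 figla-like locus in tilapia:
# the published candidate-site genotypes, gene segment sizes, primer
# coordinate table and family counts that the pipeline's worked examples
# and acceptance checks recompute from.

#' Study design of the LG1 pooled-sex discovery analysis
#'
#' Three species/strains segregating sex on linkage group 1, each with a
#' female and a male pooled library: the Amherst hybrid stock (As),
#' libraries deposited as *S. melanotheron* (Sm; later re-identified as
#' *S. galilaeus* by barcode), and *C. zillii* (Cz).
#'
#' @return an [study_design()] object.
#' @export
lg1_study_design <- function() {
  sp <- c("As", "Sm", "Cz")
  study_design(sp, paste0(sp, "_F"), paste0(sp, "_M"))
}

#' The LG1 critical sex-determination window
#'
#' 25.4-28.7 Mbp on the *O. aureus* assembly of linkage group 1,
#' orthologous by synteny to the mapped 24-27 Mbp region of the
#' *O. niloticus* build.
#'
#' @return a [genomic_window()].
#' @export
lg1_sd_window <- function() genomic_window("LG1", 25400000, 28700000)

#' The six published cross-species sex-concordant candidate sites
#'
#' Positions, alleles and per-pool genotypes of the six variant sites in
#' the LG1 window that fit the same XY model in all three species: four
#' sites with a Y-specific allele (females homozygous, males
#' heterozygous, including two multiallelic sites — one with a spanning
#' deletion allele `*`) and two sites null in females (the locus absent
#' from the x form), which map inside the figla-like gene.
#'
#' @return variant data frame in [read_pool_vcf()] layout, pools as in
#'   [lg1_study_design()].
#' @export
lg1_candidate_sites <- function() {
  v <- data.frame(
    chrom = "LG1",
    pos = c(25672475, 26488670, 26490716, 26490863, 26509215, 26510329),
    ref = c("C", "T", "G", "C", "A", "C"),
    alt = c("T,G", "A", "C", "T", "C", "*,T"),
    As_F = c("0/0", "1/1", "./.", "./.", "0/0", "0/0"),
    As_M = c("0/1", "0/1", "0/0", "0/0", "0/1", "0/1"),
    Sm_F = c("0/0", "1/1", "./.", "./.", "0/0", "0/0"),
    Sm_M = c("0/2", "0/1", "1/1", "1/1", "0/1", "0/2"),
    Cz_F = c("0/0", "1/1", "./.", "./.", "0/0", "0/0"),
    Cz_M = c("0/1", "0/1", "1/1", "1/1", "0/1", "0/1"),
    stringsAsFactors = FALSE)
  v
}

#' Gene annotations around the figla-like locus
#'
#' Feature intervals (1-based inclusive) used to label candidate sites:
#' the depdc7a exon harbouring the non-conserved multiallelic site, the
#' csmd1 and chs1 neighbours, and the exon-2/intron-2 features of
#' figla-like. Interval bounds other than the feature containing each
#' published site are schematic.
#'
#' @return annotation data frame (`name`, `chrom`, `start`, `end`,
#'   `feature`).
#' @export
lg1_gene_annotations <- function() {
  data.frame(
    name = c("depdc7a", "csmd1", "figla-like", "figla-like", "chs1"),
    chrom = "LG1",
    start = c(25672400, 26400000, 26490700, 26490847, 26520000),
    end = c(25672600, 26470000, 26490846, 26490968, 26560000),
    feature = c("exon 8", "", "exon 2", "intron 2", ""),
    stringsAsFactors = FALSE)
}

#' Exon/intron segment sizes of the figla-like gene
#'
#' Three exons of 174, 147 and 931 bp separated by introns of 1290 and
#' 122 bp: a 2664 bp genomic locus spliced to a 1252 bp transcript.
#'
#' @return a [gene_segments()] data frame (sizes only).
#' @export
figla_gene_segments <- function() {
  gene_segments(c("exon", "intron", "exon", "intron", "exon"),
                c(174, 1290, 147, 122, 931))
}

#' Primer-pair coordinate table of the duplex and resequencing markers
#'
#' Template accessions and 1-based inclusive amplicon bounds for the
#' duplex presence/absence assay (LG1y spanning the figla-like second
#' intron; LG1x at the orthologous gene-absent position) and four
#' resequencing markers, with the declared amplicon sizes.
#'
#' @return data frame (`marker`, `accession`, `start`, `end`, `size`).
#' @export
duplex_primer_table <- function() {
  data.frame(
    marker = c("LG1y", "LG1x", "Reseq1", "Reseq2", "Reseq3", "Reseq4"),
    accession = c("LOC116310109", "NC_031965.2", "NC_031965.2",
                  "NC_031965.2", "ERZ9148259", "NC_031965.2"),
    start = c(1520, 24979876, 26489072, 26490237, 1556, 26490991),
    end = c(1821, 24980010, 26490461, 26491052, 2526, 26491772),
    size = c(302, 135, 1390, 816, 971, 782),
    stringsAsFactors = FALSE)
}

#' Genotype-by-sex counts of the association families
#'
#' Per family/stock: xy females, xy males, xx females, xx males from
#' the duplex figla-like assay. Two families show complete concordance
#' of genotype with sex; the Sg sample has one xx male and the
#' Chitralada (Cs) family two xy females.
#'
#' @return named list of count vectors `(a, b, c, d)` = (xy-F, xy-M,
#'   xx-F, xx-M).
#' @export
association_family_counts <- function() {
  list(OmI_Family1 = c(0, 8, 7, 0),
       OmI_Family2 = c(0, 8, 6, 0),
       Sg = c(0, 15, 18, 1),
       Cz = c(0, 9, 13, 0),
       As = c(0, 58, 33, 0),
       Cs = c(2, 11, 12, 0))
}
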