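# Three pooled-genotype models of an XX/XY sex-determination system,
# evaluated on the (female pool, male pool) diploid calls at one site:
#   Y_ALLELE - females homozygous, males heterozygous: the Y carries a
#              different allele to the X
#   X_NULL   - females null (no reads), males homozygous: the locus is
#              absent from the X chromosome
#   Y_NULL   - females heterozygous, males homozygous: the locus is
#              absent from the Y chromosome

SEX_MODELS <- c("Y_ALLELE", "X_NULL", "Y_NULL")

gt_state <- function(gt) {
  a <- parse_gt(gt)
  if (is.null(a)) return("null")
  if (a[1] == a[2]) "hom" else "het"
}

#' Classify a female/male pooled genotype pair against the XY models
#'
#' Homozygosity is allele-agnostic: `0/0`, `1/1` and `2/2` are all
#' homozygous. The three model predicates are mutually exclusive, so at
#' most one model can hold for a pair.
#'
#' @param female,male GT strings (vectors of equal length are recycled
#'   elementwise).
#' @return character vector: `"Y_ALLELE"`, `"X_NULL"`, `"Y_NULL"`, or
#'   `NA` when no model holds.
#' @examples
#' classify_pair("0/0", "0/1")   # Y_ALLELE
#' classify_pair("./.", "1/1")   # X_NULL
#' classify_pair("0/1", "0/0")   # Y_NULL
#' classify_pair("0/1", "0/1")   # NA: no model
#' @export
classify_pair <- function(female, male) {
  n <- max(length(female), length(male))
  female <- rep_len(female, n); male <- rep_len(male, n)
  vapply(seq_len(n), function(i) {
    f <- gt_state(female[i]); m <- gt_state(male[i])
    if (f == "hom"  && m == "het") return("Y_ALLELE")
    if (f == "null" && m == "hom") return("X_NULL")
    if (f == "het"  && m == "hom") return("Y_NULL")
    NA_character_
  }, character(1))
}

site_alleles <- function(ref, alt) {
  if (is.na(alt) || alt == ".") return(NULL)
  c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
}

# male allele sequences (sorted pair) per species; conservation compares
# sequences, not indices, because index 1 may denote different bases in
# different species' calls at multiallelic sites
male_allele_seqs <- function(record, design) {
  alleles <- site_alleles(record$ref, record$alt)
  lapply(seq_len(nrow(design)), function(i) {
    a <- parse_gt(record[[design$male_pool[i]]])
    if (is.null(a) || is.null(alleles)) return(NULL)
    sort(alleles[a + 1L])
  })
}

#' Classify one variant site across all species of a design
#'
#' Each species' (female, male) pool pair is classified with
#' [classify_pair()]; the site is concordant when every species fits the
#' same model. Male-allele conservation resolves allele indices to
#' sequences and compares the unordered male allele pair across species;
#' it is an annotation, not a filter.
#'
#' A site with no alternative allele (`ALT == "."`) fits no model.
#'
#' @param record one-row data frame from [read_pool_vcf()].
#' @param design an [study_design()] object.
#' @return list with `fits` (data frame: species, model, female_gt,
#'   male_gt), `concordant_model` (model code or `NA`) and
#'   `male_alleles_conserved` (logical, `NA` when any male call is null
#'   or the site fits no model).
#' @export
classify_site <- function(record, design) {
  no_alt <- is.na(record$alt) || record$alt == "."
  fits <- data.frame(
    species = design$species,
    model = if (no_alt) NA_character_ else
      classify_pair(unlist(record[design$female_pool]),
                    unlist(record[design$male_pool])),
    female_gt = unlist(record[design$female_pool], use.names = FALSE),
    male_gt = unlist(record[design$male_pool], use.names = FALSE),
    stringsAsFactors = FALSE)
  concordant <- if (!anyNA(fits$model) &&
                    length(unique(fits$model)) == 1L)
    fits$model[1] else NA_character_
  seqs <- male_allele_seqs(record, design)
  conserved <- if (any(vapply(seqs, is.null, logical(1)))) NA else
    all(vapply(seqs, identical, logical(1), y = seqs[[1]]))
  list(fits = fits, concordant_model = concordant,
       male_alleles_conserved = conserved)
}

annotate_position <- function(pos, annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(c(region = "intergenic", flank5 = "", flank3 = ""))
  hit <- annotations$start <= pos & annotations$end >= pos
  if (any(hit)) {
    a <- annotations[which(hit)[1], ]
    lab <- if (!is.null(a$feature) && !is.na(a$feature) && nzchar(a$feature))
      paste(a$name, a$feature) else a$name
    return(c(region = lab, flank5 = "", flank3 = ""))
  }
  before <- annotations[annotations$end < pos, ]
  after <- annotations[annotations$start > pos, ]
  c(region = "intergenic",
    flank5 = if (nrow(before)) before$name[which.max(before$end)] else "",
    flank3 = if (nrow(after)) after$name[which.min(after$start)] else "")
}

#' Scan a variant window for cross-species sex-concordant sites
#'
#' Applies [classify_site()] to every record and keeps the sites where
#' one XY model holds in every species. Retained sites are annotated
#' with the gene interval they fall in (1-based inclusive overlap; a
#' site on an interval boundary belongs to that interval), or labelled
#' `"intergenic"` with the nearest flanking genes.
#'
#' @param variants position-sorted data frame from [read_pool_vcf()] (or
#'   a generator).
#' @param design an [study_design()] object.
#' @param annotations optional gene interval data frame with columns
#'   `name`, `chrom`, `start`, `end` and optional `feature`, 1-based
#'   inclusive.
#' @return list of class `concordance_scan`: `results` (data frame of
#'   concordant sites with per-pool genotypes, `model`, `conserved`,
#'   `region`, `flank5`, `flank3`) and `n_scanned` (total records seen).
#' @export
scan_window <- function(variants, design, annotations = NULL) {
  if (is.unsorted(variants$pos))
    stop("variant records must be sorted by position")
  pools <- design_pools(design)
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    rec <- variants[i, , drop = FALSE]
    cls <- classify_site(rec, design)
    if (is.na(cls$concordant_model)) next
    ann <- annotate_position(rec$pos, annotations)
    row <- data.frame(chrom = rec$chrom, pos = rec$pos, ref = rec$ref,
                      alt = rec$alt, stringsAsFactors = FALSE)
    for (p in pools) row[[p]] <- rec[[p]]
    row$model <- cls$concordant_model
    row$conserved <- cls$male_alleles_conserved
    row$region <- ann[["region"]]
    row$flank5 <- ann[["flank5"]]
    row$flank3 <- ann[["flank3"]]
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  results <- if (length(rows)) do.call(rbind, rows) else {
    out <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
    for (p in pools) out[[p]] <- character()
    out$model <- character(); out$conserved <- logical()
    out$region <- character(); out$flank5 <- character()
    out$flank3 <- character()
    out
  }
  rownames(results) <- NULL
  structure(list(results = results, n_scanned = nrow(variants)),
            class = "concordance_scan")
}

#' @export
print.concordance_scan <- function(x, ...) {
  cat(sprintf("<concordance_scan> %d concordant site(s) of %d scanned\n",
              nrow(x$results), x$n_scanned))
  if (nrow(x$results))
    print.data.frame(x$results)
  invisible(x)
}

#' Read a gene annotation table
#'
#' BED-like TSV with columns `name`, `chrom`, `start`, `end` and optional
#' `feature`; coordinates are declared 1-based inclusive.
#'
#' @param path TSV file with a header row.
#' @return data frame of gene intervals.
#' @export
read_annotations <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "chrom", "start", "end")
  if (!all(need %in% names(ann)))
    stop("annotation TSV needs columns: name, chrom, start, end")
  if (!"feature" %in% names(ann)) ann$feature <- ""
  if (any(ann$start > ann$end)) stop("annotation with start > end")
  ann
}
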