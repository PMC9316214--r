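# Seeded generators for every input the pipeline consumes. Each
# generator is a pure function of its configuration (which carries the
# seed): identical configurations yield byte-identical outputs. Decoy
# genotypes and background reads are constructed (and verified at
# generation time) to be negative by construction, so recovery tests
# against the emitted truth sets are exact rather than probabilistic.

DNA <- c("A", "C", "G", "T")

random_dna <- function(n)
  paste(sample(DNA, n, replace = TRUE), collapse = "")

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the discovery study's conditions: three species
#' with one female and one male pool each, the 25.4-28.7 Mbp analysis
#' window, six planted concordant sites (four Y-allele, two X-null)
#' among decoys, a 2664 bp zero-female-coverage interval at ~26.49 Mbp
#' with ~30-fold pooled coverage, 150 bp read libraries, and family
#' tables matching the published association counts.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param species species identifiers (pools are named `<sp>_F` and
#'   `<sp>_M`).
#' @param window [genomic_window()] for variant generation.
#' @param planted named counts of planted concordant sites per model
#'   (`Y_ALLELE`, `X_NULL`, `Y_NULL`).
#' @param n_decoys number of non-concordant decoy sites.
#' @param multiallelic_fraction fraction of planted Y-allele sites made
#'   multiallelic (two ALT alleles, occasionally a spanning deletion
#'   `*`).
#' @param depth_window sub-window over which dense depth tracks are
#'   generated (100 kb around the male-specific locus by default).
#' @param null_interval list with `start`/`end` of the planted
#'   zero-female-coverage interval (2664 bp by default), or `NULL` for
#'   none.
#' @param female_depth,male_depth mean pooled read depths.
#' @param n_reads,read_length read library size and read length.
#' @param plant_counts named vector: probe copies planted per library.
#' @param word_size exact-match word length used for background-read
#'   rejection.
#' @param families named list of family specs
#'   (`xy_males`, `xx_females`, `xy_females`, `xx_males`).
#' @param barcode_length aligned barcode length in bp.
#' @return list of class `sim_config` (includes a derived
#'   [study_design()] in `$design`).
#' @export
sim_config <- function(seed = 1,
                       species = c("SpA", "SpB", "SpC"),
                       window = genomic_window("LG1", 25400000, 28700000),
                       planted = c(Y_ALLELE = 4, X_NULL = 2, Y_NULL = 0),
                       n_decoys = 500,
                       multiallelic_fraction = 0.25,
                       depth_window = genomic_window("LG1", 26440000,
                                                     26539999),
                       null_interval = list(start = 26490000,
                                            end = 26492663),
                       female_depth = 30, male_depth = 30,
                       n_reads = 1000, read_length = 150,
                       plant_counts = c(male_pool = 12, female_pool = 0),
                       word_size = 64,
                       families = list(
                         Family1 = list(xy_males = 8, xx_females = 7,
                                        xy_females = 0, xx_males = 0)),
                       barcode_length = 650) {
  planted_full <- c(Y_ALLELE = 0, X_NULL = 0, Y_NULL = 0)
  planted_full[names(planted)] <- planted
  cfg <- list(seed = as.integer(seed), species = species,
              design = study_design(species, paste0(species, "_F"),
                                    paste0(species, "_M")),
              window = window, planted = planted_full,
              n_decoys = n_decoys,
              multiallelic_fraction = multiallelic_fraction,
              depth_window = depth_window, null_interval = null_interval,
              female_depth = female_depth, male_depth = male_depth,
              n_reads = n_reads, read_length = read_length,
              plant_counts = plant_counts, word_size = word_size,
              families = families, barcode_length = barcode_length)
  class(cfg) <- "sim_config"
  cfg
}

alt_bases <- function(ref, n = 1) sample(setdiff(DNA, ref), n)

#' Generate a synthetic pooled-sex VCF with a truth set
#'
#' Plants the configured number of sites per XY model — each satisfying
#' its model in every species — among decoys drawn from classes that are
#' non-concordant by construction: monomorphic sites, sites fitting a
#' model in one species but not the others, and both-sexes-heterozygous
#' sites. Every emitted site is re-checked against the model predicates
#' at generation time. Positions are unique and sorted.
#'
#' @param config a [sim_config()].
#' @param path optional output VCF file.
#' @return list: `variants` (data frame in [read_pool_vcf()] layout),
#'   `truth` (data frame `pos`, `label` with model codes for planted
#'   sites and the decoy class otherwise), `design`, and `path` if
#'   written.
#' @export
generate_vcf <- function(config, path = NULL) {
  design <- config$design
  pools <- design_pools(design)
  n_planted <- sum(config$planted)
  n_total <- n_planted + config$n_decoys
  out <- withr::with_seed(config$seed, {
    if (n_total == 0) {
      v <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE)
      for (p in pools) v[[p]] <- character()
      list(variants = v,
           truth = data.frame(pos = numeric(), label = character(),
                              stringsAsFactors = FALSE))
    } else {
      width <- config$window$end - config$window$start + 1
      pos <- sort(sample.int(width, n_total)) + config$window$start - 1
      labels <- sample(c(rep(names(config$planted), config$planted),
                         rep(c("decoy_monomorphic", "decoy_discordant",
                               "decoy_both_het"),
                             length.out = config$n_decoys)))
      ns <- nrow(design)
      rows <- vector("list", n_total)
      for (i in seq_len(n_total)) {
        ref <- sample(DNA, 1)
        lab <- labels[i]
        fgt <- mgt <- character(ns)
        if (lab == "Y_ALLELE" &&
            runif(1) < config$multiallelic_fraction) {
          a2 <- alt_bases(ref, 1)
          a1 <- if (runif(1) < 0.3) "*" else
            sample(setdiff(DNA, c(ref, a2)), 1)
          alt <- paste(a1, a2, sep = ",")
          fgt[] <- "0/0"
          mgt <- sample(c("0/1", "0/2"), ns, replace = TRUE)
        } else if (lab == "Y_ALLELE") {
          alt <- alt_bases(ref)
          for (s in seq_len(ns)) {
            if (runif(1) < 0.5) { fgt[s] <- "0/0"; mgt[s] <- "0/1" }
            else { fgt[s] <- "1/1"; mgt[s] <- "0/1" }
          }
        } else if (lab == "X_NULL") {
          alt <- alt_bases(ref)
          fgt[] <- "./."
          mgt <- sample(c("0/0", "1/1"), ns, replace = TRUE)
        } else if (lab == "Y_NULL") {
          alt <- alt_bases(ref)
          fgt[] <- "0/1"
          mgt <- sample(c("0/0", "1/1"), ns, replace = TRUE)
        } else if (lab == "decoy_monomorphic") {
          alt <- alt_bases(ref)
          fgt[] <- "0/0"; mgt[] <- "0/0"
        } else if (lab == "decoy_discordant" && ns > 1) {
          alt <- alt_bases(ref)
          fgt[1] <- "0/0"; mgt[1] <- "0/1"      # fits Y_ALLELE here...
          fgt[-1] <- "0/1"; mgt[-1] <- "0/1"    # ...but nowhere else
        } else {                                 # decoy_both_het
          alt <- alt_bases(ref)
          fgt[] <- "0/1"; mgt[] <- "0/1"
        }
        row <- data.frame(chrom = config$window$chrom, pos = pos[i],
                          ref = ref, alt = alt, stringsAsFactors = FALSE)
        for (s in seq_len(ns)) {
          row[[design$female_pool[s]]] <- fgt[s]
          row[[design$male_pool[s]]] <- mgt[s]
        }
        rows[[i]] <- row
      }
      variants <- do.call(rbind, rows)
      # generation-time verification against the model predicates
      for (i in seq_len(n_total)) {
        cls <- classify_site(variants[i, , drop = FALSE], design)
        lab <- labels[i]
        if (lab %in% SEX_MODELS) {
          if (!identical(cls$concordant_model, lab))
            stop("generation error: planted site fails its model")
        } else if (!is.na(cls$concordant_model))
          stop("generation error: decoy is concordant")
      }
      list(variants = variants,
           truth = data.frame(pos = pos, label = labels,
                              stringsAsFactors = FALSE))
    }
  })
  out$design <- design
  if (!is.null(path)) {
    write_pool_vcf(out$variants, design, path)
    out$path <- path
  }
  out
}

#' Generate per-pool depth tracks with a planted male-specific interval
#'
#' Female tracks have depth 0 inside the configured null interval and
#' strictly positive Poisson-like depth (1 + Poisson) elsewhere; male
#' tracks are strictly positive throughout with mean `male_depth`.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; one run-length TSV per pool is
#'   written there.
#' @return list: `tracks` (list of [depth_track()]), `truth` (the
#'   planted interval or `NULL`), `files` if written.
#' @export
generate_depth_tracks <- function(config, dir = NULL) {
  w <- config$depth_window
  n <- w$end - w$start + 1
  ni <- config$null_interval
  if (!is.null(ni) &&
      (ni$start < w$start || ni$end > w$end || ni$end < ni$start))
    stop("null interval must lie within the depth window")
  design <- config$design
  tracks <- withr::with_seed(config$seed + 1L, {
    tr <- list()
    for (s in seq_len(nrow(design))) {
      fdep <- 1L + rpois(n, config$female_depth - 1)
      if (!is.null(ni))
        fdep[(ni$start - w$start + 1):(ni$end - w$start + 1)] <- 0L
      mdep <- 1L + rpois(n, config$male_depth - 1)
      tr[[design$female_pool[s]]] <-
        depth_track(design$female_pool[s], w$chrom, w$start, fdep)
      tr[[design$male_pool[s]]] <-
        depth_track(design$male_pool[s], w$chrom, w$start, mdep)
    }
    tr
  })
  out <- list(tracks = tracks, truth = ni, design = design)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$files <- vapply(names(tracks), function(p)
      write_depth_track(tracks[[p]], file.path(dir, paste0(p, ".tsv"))),
      character(1))
  }
  out
}

shares_word <- function(read, words, k)
  any(seq_words(toupper(read), k) %in% words)

#' Generate read libraries with planted probe copies
#'
#' Plants the probe verbatim (forward or reverse-complement, chosen at
#' random per read) into the configured number of reads per library;
#' background reads are random sequence rejection-sampled so that no
#' background read shares a `word_size`-mer with the probe on either
#' strand — probe hit counts against the emitted libraries are
#' therefore exactly the planted counts.
#'
#' @param config a [sim_config()]; `plant_counts` names the libraries.
#' @param probe probe sequence (length between `word_size` and
#'   `read_length`).
#' @param dir optional directory; one FASTA per library is written.
#' @return list: `libraries` (list of [read_library()]), `truth`
#'   (planted counts), `files` if written.
#' @export
generate_reads <- function(config, probe, dir = NULL) {
  probe <- normalize_probe(probe)
  k <- config$word_size
  if (nchar(probe) < k) stop("probe shorter than the word size")
  if (nchar(probe) > config$read_length)
    stop("probe longer than the read length")
  words <- unique(c(seq_words(probe, k), seq_words(revcomp(probe), k)))
  rc <- revcomp(probe)
  libs <- withr::with_seed(config$seed + 2L, {
    lapply(seq_along(config$plant_counts), function(li) {
      n_plant <- config$plant_counts[[li]]
      if (n_plant > config$n_reads)
        stop("cannot plant more reads than the library holds")
      reads <- character(config$n_reads)
      for (r in seq_len(config$n_reads)) {
        if (r <= n_plant) {
          ins <- if (runif(1) < 0.5) probe else rc
          pad <- config$read_length - nchar(ins)
          left <- sample(0:pad, 1)
          reads[r] <- paste0(random_dna(left), ins,
                             random_dna(pad - left))
        } else {
          repeat {
            cand <- random_dna(config$read_length)
            if (!shares_word(cand, words, k)) break
          }
          reads[r] <- cand
        }
      }
      structure(list(id = names(config$plant_counts)[li],
                     reads = sample(reads),
                     total_reads = config$n_reads),
                class = "read_library")
    })
  })
  names(libs) <- names(config$plant_counts)
  out <- list(libraries = libs, truth = config$plant_counts)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$files <- vapply(names(libs), function(id) {
      f <- file.path(dir, paste0(id, ".fasta"))
      writeLines(paste0(">", id, "_read", seq_along(libs[[id]]$reads),
                        "\n", libs[[id]]$reads), f)
      f
    }, character(1))
  }
  out
}

#' Generate per-individual family call tables
#'
#' Emits individual sex/genotype rows matching each configured family's
#' target 2x2 table exactly, including discordant individuals (e.g. xy
#' females); row order is shuffled.
#'
#' @param config a [sim_config()].
#' @param dir optional directory; one TSV per family is written.
#' @return list: `calls` (named list of data frames `id`, `sex`,
#'   `genotype`), `truth` (named list of `(a, b, c, d)` counts),
#'   `files` if written.
#' @export
generate_family <- function(config, dir = NULL) {
  out <- withr::with_seed(config$seed + 3L, {
    calls <- list(); truth <- list()
    for (nm in names(config$families)) {
      f <- config$families[[nm]]
      g <- function(x) if (is.null(f[[x]])) 0L else f[[x]]
      sex <- c(rep("M", g("xy_males")), rep("F", g("xx_females")),
               rep("F", g("xy_females")), rep("M", g("xx_males")))
      gt <- c(rep("xy", g("xy_males")), rep("xx", g("xx_females")),
              rep("xy", g("xy_females")), rep("xx", g("xx_males")))
      df <- data.frame(id = character(0), sex = character(0),
                       genotype = character(0), stringsAsFactors = FALSE)
      if (length(sex)) {
        ord <- sample(seq_along(sex))
        df <- data.frame(id = paste0(nm, "_", seq_along(sex)),
                         sex = sex[ord], genotype = gt[ord],
                         stringsAsFactors = FALSE)
      }
      calls[[nm]] <- df
      truth[[nm]] <- c(a = g("xy_females"), b = g("xy_males"),
                       c = g("xx_females"), d = g("xx_males"))
    }
    list(calls = calls, truth = truth)
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$files <- vapply(names(out$calls), function(nm) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      write.table(out$calls[[nm]], f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f
    }, character(1))
  }
  out
}

#' Generate a random multi-exon gene with a planted open reading frame
#'
#' Builds a spliced transcript containing an ORF of `n_aa` codons (ATG
#' to an in-frame stop), splits it into exons of the configured sizes,
#' and inserts introns with canonical `gt`...`ag` boundaries (or a
#' planted donor-site violation).
#'
#' @param seed integer seed.
#' @param exon_sizes,intron_sizes segment sizes in bp; exon total must
#'   accommodate the ORF.
#' @param n_aa protein length in amino acids (default 99).
#' @param violate_donor if `TRUE`, the first intron starts `ct` instead
#'   of `gt`.
#' @return a [gene_segments()] data frame with sequences (introns
#'   lowercase, exons uppercase).
#' @export
generate_gene <- function(seed = 1, exon_sizes = c(174, 147, 931),
                          intron_sizes = c(1290, 122), n_aa = 99,
                          violate_donor = FALSE) {
  if (length(intron_sizes) != length(exon_sizes) - 1)
    stop("need one fewer intron than exons")
  tlen <- sum(exon_sizes)
  cds_len <- 3 * (n_aa + 1)
  withr::with_seed(seed, {
    utr5_len <- sample(3:min(60, tlen - cds_len), 1)
    repeat {
      utr5 <- random_dna(utr5_len)
      if (!grepl("ATG", utr5, fixed = TRUE)) break
    }
    codons <- apply(expand.grid(DNA, DNA, DNA), 1, paste, collapse = "")
    sense <- setdiff(codons, STOP_CODONS)
    cds <- paste0("ATG",
                  paste(sample(sense, n_aa - 1, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1))
    utr3 <- random_dna(tlen - utr5_len - cds_len)
    transcript <- paste0(utr5, cds, utr3)
    bounds <- cumsum(exon_sizes)
    exons <- substring(transcript, c(1, bounds[-length(bounds)] + 1),
                       bounds)
    introns <- vapply(seq_along(intron_sizes), function(i) {
      donor <- if (violate_donor && i == 1) "ct" else "gt"
      paste0(donor, tolower(random_dna(intron_sizes[i] - 4)), "ag")
    }, character(1))
    kinds <- rep(c("exon", "intron"), length.out = 2 * length(exon_sizes) - 1)
    seqs <- character(length(kinds))
    seqs[kinds == "exon"] <- toupper(exons)
    seqs[kinds == "intron"] <- introns
    sizes <- numeric(length(kinds))
    sizes[kinds == "exon"] <- exon_sizes
    sizes[kinds == "intron"] <- intron_sizes
    gene_segments(kinds, sizes, seqs)
  })
}

#' Generate an aligned barcode pair with planted divergence
#'
#' Draws a random barcode of the configured length and a copy carrying
#' exactly `n_mismatches` substitutions at distinct positions.
#'
#' @param seed integer seed.
#' @param length aligned length in bp (default 650).
#' @param n_mismatches substitutions planted.
#' @return list: `seq1`, `seq2`, `n_mismatches`.
#' @export
generate_barcode_pair <- function(seed = 1, length = 650,
                                  n_mismatches = 0) {
  withr::with_seed(seed, {
    s1 <- strsplit(random_dna(length), "")[[1]]
    s2 <- s1
    if (n_mismatches > 0) {
      at <- sample(length, n_mismatches)
      for (i in at) s2[i] <- sample(setdiff(DNA, s1[i]), 1)
    }
    list(seq1 = paste(s1, collapse = ""),
         seq2 = paste(s2, collapse = ""),
         n_mismatches = n_mismatches)
  })
}
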