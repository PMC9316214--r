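# Shared fixtures and independent oracles.

fixture_design <- function() lg1_study_design()

# candidate sites plus decoy rows that fit no model concordantly
fixture_vcf_with_decoys <- function(n_decoys = 10, seed = 42) {
  v <- lg1_candidate_sites()
  withr::with_seed(seed, {
    pos <- sample(setdiff(seq(25400000, 28700000, by = 1000), v$pos),
                  n_decoys)
    dec <- data.frame(chrom = "LG1", pos = pos,
                      ref = sample(c("A", "C", "G", "T"), n_decoys,
                                   replace = TRUE),
                      alt = "T", stringsAsFactors = FALSE)
    dec$alt <- ifelse(dec$ref == "T", "G", "T")
    for (p in design_pools(fixture_design()))
      dec[[p]] <- sample(c("0/1", "0/0"), n_decoys, replace = TRUE)
    # both-sexes-identical genotypes fit no model
    for (sp in fixture_design()$species)
      dec[[paste0(sp, "_M")]] <- dec[[paste0(sp, "_F")]]
    out <- rbind(v, dec)
    out[order(out$pos), ]
  })
}

# brute-force model predicate evaluator, written against the verbal
# definitions and independent of classify_pair's implementation
oracle_classify <- function(female, male) {
  dec <- function(gt) {
    gt <- gsub("|", "/", gt, fixed = TRUE)
    p <- strsplit(gt, "/", fixed = TRUE)[[1]]
    if (any(p == ".")) return(NULL)
    as.integer(p)
  }
  f <- dec(female); m <- dec(male)
  f_hom <- !is.null(f) && f[1] == f[2]
  f_het <- !is.null(f) && f[1] != f[2]
  m_hom <- !is.null(m) && m[1] == m[2]
  m_het <- !is.null(m) && m[1] != m[2]
  if (f_hom && m_het) return("Y_ALLELE")
  if (is.null(f) && m_hom) return("X_NULL")
  if (f_het && m_hom) return("Y_NULL")
  NA_character_
}

# all diploid calls over allele indices 0..2 plus the null call
all_calls <- function() {
  idx <- expand.grid(a = 0:2, b = 0:2)
  c("./.", unique(sprintf("%d/%d", pmin(idx$a, idx$b),
                          pmax(idx$a, idx$b))))
}

# naive all-substrings probe-hit oracle (either strand)
oracle_probe_hits <- function(probe, reads, word_size) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(probe)))
  subwords <- function(x, k) {
    n <- nchar(x)
    if (n < k) character(0) else substring(x, 1:(n - k + 1), k:n)
  }
  pw <- c(subwords(toupper(probe), word_size),
          subwords(rc, word_size))
  sum(vapply(toupper(reads), function(r) {
    rw <- subwords(r, word_size)
    any(outer(rw, pw, "=="))
  }, logical(1)))
}

random_seq <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = ""))
}
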