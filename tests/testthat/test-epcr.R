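test_that("planted probe copies are counted exactly and absent probes give zero", {
  probe <- random_seq(147, seed = 101)
  cfg <- sim_config(seed = 101, n_reads = 1000,
                    plant_counts = c(libA = 12, libB = 0))
  rd <- generate_reads(cfg, probe)
  expect_equal(probe_hits(probe, rd$libraries$libA$reads), 12L)
  expect_equal(probe_hits(probe, rd$libraries$libB$reads), 0L)
  expect_equal(probe_hits(probe, character(0)), 0L)
})

test_that("probe_hits equals the naive all-substrings oracle on small libraries", {
  probe <- random_seq(60, seed = 7)
  cfg <- sim_config(seed = 7, n_reads = 60, read_length = 80,
                    word_size = 20, plant_counts = c(lib = 9))
  rd <- generate_reads(cfg, probe)
  reads <- rd$libraries$lib$reads
  for (w in c(20, 40, 60))
    expect_equal(probe_hits(probe, reads, word_size = w),
                 oracle_probe_hits(probe, reads, w))
})

test_that("hits respect strand symmetry and are monotone in word size", {
  probe <- random_seq(100, seed = 13)
  cfg <- sim_config(seed = 13, n_reads = 200, read_length = 120,
                    plant_counts = c(lib = 15))
  reads <- generate_reads(cfg, probe)$libraries$lib$reads
  rc_reads <- vapply(reads, function(r)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(r))),
    character(1), USE.NAMES = FALSE)
  h <- vapply(c(32, 64, 100), function(w)
    probe_hits(probe, reads, w), numeric(1))
  h_rc <- vapply(c(32, 64, 100), function(w)
    probe_hits(probe, rc_reads, w), numeric(1))
  expect_equal(h, h_rc)
  expect_true(all(diff(h) <= 0))
  # ambiguity codes match nothing
  n_read <- paste0(substr(probe, 1, 63), "N",
                   substr(probe, 65, 100))
  expect_equal(probe_hits(probe, n_read, 64), 0L)
})

test_that("probe/word-size preconditions are enforced", {
  expect_error(probe_hits(random_seq(40, 1), "ACGT", word_size = 64),
               "shorter")
  expect_error(probe_hits(random_seq(40, 1), "ACGT", word_size = 4),
               ">= 8")
  expect_error(probe_hits("ACGTXN", "ACGT", word_size = 8), "A/C/G/T")
})

test_that("detection threshold and RPKM follow their definitions", {
  probe <- random_seq(147, seed = 23)
  mk_lib <- function(n_plant) {
    cfg <- sim_config(seed = 23, n_reads = 500,
                      plant_counts = c(lib = n_plant))
    generate_reads(cfg, probe)$libraries$lib
  }
  r2 <- epcr_report("p", probe, mk_lib(2))
  r3 <- epcr_report("p", probe, mk_lib(3))
  expect_false(r2$detected)   # two reads: below the three-read limit
  expect_true(r3$detected)
  expect_equal(r3$hit_count, 3L)

  expect_equal(rpkm(10, 1e6, 147), 10 * 1e9 / (1e6 * 147))
  expect_equal(rpkm(10, 1e6, 147), 68.027, tolerance = 1e-4)
  # linear in hits at fixed library size and probe length
  expect_equal(rpkm(20, 1e6, 147), 2 * rpkm(10, 1e6, 147))
  expect_true(is.na(rpkm(0, 0, 147)))
  expect_error(rpkm(1, 0, 147), "impossible")
})

test_that("duplex genotypes cover all four detection outcomes", {
  expect_equal(duplex_genotype(TRUE, FALSE), "xx")
  expect_equal(duplex_genotype(TRUE, TRUE), "xy")
  expect_equal(duplex_genotype(FALSE, TRUE), "yy?")
  expect_equal(duplex_genotype(FALSE, FALSE), "fail")
  expect_equal(duplex_genotype(c(TRUE, TRUE), c(FALSE, TRUE)),
               c("xx", "xy"))
})

test_that("FASTA and FASTQ libraries load with declared or counted sizes", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "lib.fasta")
  writeLines(c(">r1", "ACGTACGT", ">r2", "TTTTAAAA"), fa)
  lib <- read_library(fa)
  expect_equal(lib$total_reads, 2)
  expect_equal(lib$reads, c("ACGTACGT", "TTTTAAAA"))
  fq <- file.path(dir, "lib.fastq")
  writeLines(c("@r1", "ACGTACGT", "+", "IIIIIIII"), fq)
  expect_equal(read_library(fq)$reads, "ACGTACGT")
  expect_equal(read_library(fa, total_reads = 1e6)$total_reads, 1e6)
})
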