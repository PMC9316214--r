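test_that("generators are byte-identical under the same seed and differ across seeds", {
  cfg <- sim_config(seed = 5, planted = c(Y_ALLELE = 3, X_NULL = 1),
                    n_decoys = 40)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  generate_vcf(cfg, f1)
  generate_vcf(cfg, f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg2 <- sim_config(seed = 6, planted = c(Y_ALLELE = 3, X_NULL = 1),
                     n_decoys = 40)
  generate_vcf(cfg2, f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("emitted VCFs validate against their truth set by independent re-parse", {
  cfg <- sim_config(seed = 7, planted = c(Y_ALLELE = 2, X_NULL = 2),
                    n_decoys = 50)
  f <- withr::local_tempfile(fileext = ".vcf")
  g <- generate_vcf(cfg, f)
  reread <- read_pool_vcf(f, cfg$design, cfg$window)
  expect_equal(reread$pos, g$truth$pos)
  sc <- scan_window(reread, cfg$design)
  planted <- g$truth$pos[g$truth$label %in% c("Y_ALLELE", "X_NULL",
                                              "Y_NULL")]
  expect_equal(sort(sc$results$pos), sort(planted))
  expect_equal(sc$n_scanned, 54L)
})

test_that("a zero-planted zero-decoy configuration emits a header-only VCF", {
  cfg <- sim_config(seed = 1, planted = c(Y_ALLELE = 0), n_decoys = 0)
  f <- withr::local_tempfile(fileext = ".vcf")
  g <- generate_vcf(cfg, f)
  expect_equal(nrow(g$variants), 0L)
  expect_false(any(!startsWith(readLines(f), "#")))
})

test_that("planted and decoy positions are disjoint, sorted and unique across seeds", {
  for (seed in c(3, 14, 159)) {
    cfg <- sim_config(seed = seed,
                      planted = c(Y_ALLELE = 5, X_NULL = 3, Y_NULL = 2),
                      n_decoys = 100)
    g <- generate_vcf(cfg)
    expect_false(anyDuplicated(g$truth$pos) > 0)
    expect_false(is.unsorted(g$variants$pos))
    expect_true(all(g$truth$pos >= cfg$window$start &
                    g$truth$pos <= cfg$window$end))
  }
})

test_that("depth, read and family generators agree with their truth sets", {
  cfg <- sim_config(seed = 8, species = c("A", "B"),
                    depth_window = genomic_window("LG1", 1, 50000),
                    null_interval = list(start = 20001, end = 22664),
                    n_reads = 400,
                    plant_counts = c(m = 5, f = 0),
                    families = list(
                      fam1 = list(xy_males = 8, xx_females = 7),
                      fam2 = list(xy_males = 11, xx_females = 12,
                                  xy_females = 2)))
  dep <- generate_depth_tracks(cfg)
  iv <- find_male_specific_intervals(dep$tracks, cfg$design,
                                     min_length = 500)
  expect_equal(c(iv$start, iv$end), c(20001, 22664))
  # no-null-interval config yields no detection
  cfg0 <- cfg; cfg0$null_interval <- NULL
  expect_equal(nrow(find_male_specific_intervals(
    generate_depth_tracks(cfg0)$tracks, cfg$design)), 0L)

  probe <- random_seq(147, seed = 8)
  rd <- generate_reads(cfg, probe)
  expect_equal(probe_hits(probe, rd$libraries$m$reads), 5L)
  expect_equal(probe_hits(probe, rd$libraries$f$reads), 0L)

  fam <- generate_family(cfg)
  t1 <- tabulate_calls(fam$calls$fam1)
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(0, 8, 7, 0))
  t2 <- tabulate_calls(fam$calls$fam2)
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(2, 11, 12, 0))
  expect_equal(unname(fam$truth$fam2), c(2, 11, 12, 0))
})

test_that("family generator emits an empty table for an empty family", {
  cfg <- sim_config(seed = 2, families = list(none = list()))
  fam <- generate_family(cfg)
  expect_equal(nrow(fam$calls$none), 0L)
})
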