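test_that("classify_pair matches the published genotype patterns", {
  expect_equal(classify_pair("0/0", "0/1"), "Y_ALLELE")
  expect_equal(classify_pair("1/1", "0/1"), "Y_ALLELE")
  expect_equal(classify_pair("0/0", "0/2"), "Y_ALLELE")
  expect_equal(classify_pair("./.", "1/1"), "X_NULL")
  expect_equal(classify_pair("./.", "0/0"), "X_NULL")
  expect_equal(classify_pair("0/1", "0/0"), "Y_NULL")
  expect_true(is.na(classify_pair("0/1", "0/1")))
  expect_true(is.na(classify_pair("0/0", "0/0")))
  expect_true(is.na(classify_pair("./.", "0/1")))
})

test_that("classify_pair agrees with a brute-force predicate evaluator on every call pair", {
  calls <- all_calls()
  for (f in calls) for (m in calls)
    expect_identical(classify_pair(f, m), oracle_classify(f, m),
                     info = sprintf("F=%s M=%s", f, m))
})

test_that("no call pair satisfies two models (mutual exclusivity)", {
  calls <- all_calls()
  for (f in calls) for (m in calls) {
    hits <- c(
      Y_ALLELE = !is.null(parse_gt(f)) && !is.null(parse_gt(m)) &&
        parse_gt(f)[1] == parse_gt(f)[2] &&
        parse_gt(m)[1] != parse_gt(m)[2],
      X_NULL = is.null(parse_gt(f)) && !is.null(parse_gt(m)) &&
        parse_gt(m)[1] == parse_gt(m)[2],
      Y_NULL = !is.null(parse_gt(f)) && !is.null(parse_gt(m)) &&
        parse_gt(f)[1] != parse_gt(f)[2] &&
        parse_gt(m)[1] == parse_gt(m)[2])
    expect_lte(sum(hits), 1L)
  }
})

test_that("the six candidate sites classify to their published models and conservation flags", {
  d <- fixture_design()
  v <- lg1_candidate_sites()
  cls <- lapply(seq_len(nrow(v)),
                function(i) classify_site(v[i, ], d))
  expect_equal(vapply(cls, `[[`, character(1), "concordant_model"),
               c("Y_ALLELE", "Y_ALLELE", "X_NULL", "X_NULL",
                 "Y_ALLELE", "Y_ALLELE"))
  # the tri-allelic depdc7a site: same model everywhere, but male
  # allele *sequences* differ across species
  expect_false(cls[[1]]$male_alleles_conserved)
  expect_true(cls[[2]]$male_alleles_conserved)
  expect_true(cls[[5]]$male_alleles_conserved)
})

test_that("mixed models, no-ALT sites and null mixtures are not concordant", {
  d <- fixture_design()
  row <- lg1_candidate_sites()[2, ]
  row$Sm_F <- "./."; row$Sm_M <- "1/1"    # X_NULL in one species only
  expect_true(is.na(classify_site(row, d)$concordant_model))
  row2 <- lg1_candidate_sites()[2, ]
  row2$alt <- "."
  for (p in design_pools(d)) row2[[p]] <- "0/0"
  expect_true(is.na(classify_site(row2, d)$concordant_model))
})

test_that("scan keeps exactly the six concordant sites among decoys and counts all scanned", {
  d <- fixture_design()
  v <- fixture_vcf_with_decoys(10)
  scan <- scan_window(v, d, lg1_gene_annotations())
  expect_equal(scan$n_scanned, 16L)
  expect_equal(sort(scan$results$pos), sort(lg1_candidate_sites()$pos))
  expect_equal(sum(scan$results$model == "Y_ALLELE"), 4L)
  expect_equal(sum(scan$results$model == "X_NULL"), 2L)
  expect_equal(scan$results$region[scan$results$pos == 26490716],
               "figla-like exon 2")
  expect_equal(scan$results$flank5[scan$results$pos == 26488670], "csmd1")
  expect_equal(scan$results$flank3[scan$results$pos == 26488670],
               "figla-like")
})

test_that("empty input, unsorted input, and all-decoy windows behave as specified", {
  d <- fixture_design()
  empty <- lg1_candidate_sites()[0, ]
  scan <- scan_window(empty, d)
  expect_equal(nrow(scan$results), 0L)
  expect_equal(scan$n_scanned, 0L)

  v <- lg1_candidate_sites()[c(2, 1), ]
  expect_error(scan_window(v, d), "sorted")

  cfg <- sim_config(seed = 11, planted = c(Y_ALLELE = 0), n_decoys = 500)
  g <- generate_vcf(cfg)
  sc <- scan_window(g$variants, cfg$design)
  expect_equal(nrow(sc$results), 0L)
  expect_equal(sc$n_scanned, 500L)
})

test_that("permuting species order never changes the concordant model", {
  d <- fixture_design()
  v <- fixture_vcf_with_decoys(10)
  perm <- study_design(d$species[c(3, 1, 2)],
                       d$female_pool[c(3, 1, 2)],
                       d$male_pool[c(3, 1, 2)])
  s1 <- scan_window(v, d)
  s2 <- scan_window(v, perm)
  expect_equal(s1$results$pos, s2$results$pos)
  expect_equal(s1$results$model, s2$results$model)
  expect_equal(s1$results$conserved, s2$results$conserved)
})
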