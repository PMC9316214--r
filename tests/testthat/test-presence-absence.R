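small_cfg <- function(seed = 1, null_interval = list(start = 50001,
                                                     end = 52664)) {
  sim_config(seed = seed, species = c("A", "B"),
             depth_window = genomic_window("LG1", 1, 100000),
             null_interval = null_interval,
             female_depth = 30, male_depth = 30)
}

test_that("a planted zero-female interval is recovered with exact boundaries", {
  cfg <- small_cfg()
  dep <- generate_depth_tracks(cfg)
  iv <- find_male_specific_intervals(dep$tracks, cfg$design,
                                     female_ceiling = 0, male_floor = 5,
                                     min_length = 500)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 50001)
  expect_equal(iv$end, 52664)
  expect_equal(iv$length, 2664)
  expect_equal(iv$max_female_depth, 0)
  expect_gte(iv$min_male_depth, 5)
  # brute-force position scan confirms the marked set
  fem <- pmax(dep$tracks$A_F$depth, dep$tracks$B_F$depth)
  mal <- pmin(dep$tracks$A_M$depth, dep$tracks$B_M$depth)
  marked <- which(fem <= 0 & mal >= 5)
  expect_equal(range(marked), c(50001, 52664))
})

test_that("boundaries are invariant to doubling male coverage", {
  iv1 <- find_male_specific_intervals(
    generate_depth_tracks(small_cfg())$tracks, small_cfg()$design,
    male_floor = 5, min_length = 500)
  cfg2 <- small_cfg(); cfg2$male_depth <- 60
  iv2 <- find_male_specific_intervals(
    generate_depth_tracks(cfg2)$tracks, cfg2$design,
    male_floor = 5, min_length = 500)
  expect_equal(iv1[c("start", "end")], iv2[c("start", "end")])
})

test_that("an all-female-covered window yields no interval", {
  cfg <- small_cfg(null_interval = NULL)
  dep <- generate_depth_tracks(cfg)
  iv <- find_male_specific_intervals(dep$tracks, cfg$design)
  expect_equal(nrow(iv), 0L)
})

test_that("nearby runs merge across gaps up to merge_gap and results stay disjoint and sorted", {
  d <- study_design("A", "A_F", "A_M")
  fem <- rep(5L, 3000)
  fem[1001:1500] <- 0L; fem[1511:2000] <- 0L   # two runs, 10 bp apart
  tracks <- list(depth_track("A_F", "c", 1, fem),
                 depth_track("A_M", "c", 1, rep(20L, 3000)))
  merged <- find_male_specific_intervals(tracks, d, merge_gap = 50,
                                         min_length = 100)
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$start, merged$end), c(1001, 2000))
  split <- find_male_specific_intervals(tracks, d, merge_gap = 5,
                                        min_length = 100)
  expect_equal(nrow(split), 2L)
  expect_true(all(diff(split$start) > 0))
  expect_true(all(split$end[-nrow(split)] < split$start[-1]))
})

test_that("tightening thresholds never enlarges reported intervals", {
  cfg <- small_cfg(seed = 9)
  dep <- generate_depth_tracks(cfg)
  base <- find_male_specific_intervals(dep$tracks, cfg$design,
                                       female_ceiling = 2,
                                       male_floor = 3, min_length = 100)
  tight <- find_male_specific_intervals(dep$tracks, cfg$design,
                                        female_ceiling = 0,
                                        male_floor = 10,
                                        min_length = 100)
  total <- function(iv) sum(iv$length)
  expect_lte(total(tight), total(base))
})

test_that("degenerate thresholds return the whole window; mismatched windows error", {
  cfg <- small_cfg()
  dep <- generate_depth_tracks(cfg)
  iv <- find_male_specific_intervals(dep$tracks, cfg$design,
                                     female_ceiling = Inf,
                                     male_floor = 0, min_length = 1)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(1, 100000))

  short <- dep$tracks
  short$A_F <- depth_track("A_F", "LG1", 1, short$A_F$depth[1:10])
  expect_error(find_male_specific_intervals(short, cfg$design),
               "mismatched")
})

test_that("interval-gene overlap is inclusive at shared boundary base pairs", {
  iv <- data.frame(chrom = "LG1", start = 100, end = 200, length = 101,
                   min_male_depth = 10, max_female_depth = 0)
  ann <- data.frame(name = c("figla-like", "other"), chrom = "LG1",
                    start = c(200, 300), end = c(500, 400),
                    feature = "")
  ov <- interval_gene_overlap(iv, ann)
  expect_equal(ov[["LG1:100-200"]], "figla-like")
})

test_that("depth tracks round-trip through run-length TSV files", {
  cfg <- small_cfg()
  dir <- withr::local_tempdir()
  dep <- generate_depth_tracks(cfg, dir)
  back <- read_depth_track(dep$files[["A_F"]], "A_F")
  expect_equal(back$depth, dep$tracks$A_F$depth)
  expect_equal(back$start, dep$tracks$A_F$start)
})
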