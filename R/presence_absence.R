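#' Construct a per-position depth track
#'
#' A depth track is the read depth of one pooled library at every
#' position of the analysis window (dense, 1-based inclusive).
#'
#' @param pool pool label (must match the study design).
#' @param chrom sequence name.
#' @param start 1-based start of the covered window.
#' @param depth integer vector of per-position depths, `depth[i]` being
#'   the depth at `start + i - 1`.
#' @return list of class `depth_track`.
#' @export
depth_track <- function(pool, chrom, start, depth) {
  if (any(depth < 0)) stop("depths must be >= 0")
  structure(list(pool = pool, chrom = chrom,
                 start = as.numeric(start),
                 end = as.numeric(start) + length(depth) - 1,
                 depth = as.integer(depth)),
            class = "depth_track")
}

#' Read a depth track from a BED-like TSV
#'
#' Four columns `chrom`, `start`, `end`, `depth` (header row), coordinates
#' declared 1-based inclusive; rows are expanded to a dense track.
#' Positions not covered by any row get depth 0.
#'
#' @param path TSV file.
#' @param pool pool label to attach.
#' @return a [depth_track()].
#' @export
read_depth_track <- function(path, pool) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "depth")
  if (!all(need %in% names(d)))
    stop("depth TSV needs columns: chrom, start, end, depth")
  if (length(unique(d$chrom)) != 1L)
    stop("depth track must cover a single chromosome")
  lo <- min(d$start); hi <- max(d$end)
  dep <- integer(hi - lo + 1)
  for (i in seq_len(nrow(d)))
    dep[(d$start[i] - lo + 1):(d$end[i] - lo + 1)] <- d$depth[i]
  depth_track(pool, d$chrom[1], lo, dep)
}

#' Write a depth track as a run-length BED-like TSV (1-based inclusive)
#' @param track a [depth_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depth_track <- function(track, path) {
  r <- rle(track$depth)
  end_off <- cumsum(r$lengths)
  start_off <- end_off - r$lengths + 1
  write.table(data.frame(chrom = track$chrom,
                         start = track$start + start_off - 1,
                         end = track$start + end_off - 1,
                         depth = r$values),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Detect male-specific genomic intervals
#'
#' Marks positions where every female pool's depth is at most
#' `female_ceiling` and every male pool's depth is at least `male_floor`;
#' maximal runs of marked positions separated by gaps of at most
#' `merge_gap` bp are merged, and merged runs shorter than `min_length`
#' bp are discarded. This formalizes the presence/absence signal of a
#' locus carried on the Y form of a chromosome only: covered by male
#' reads, with no female coverage.
#'
#' @param tracks list of [depth_track()] objects, one per design pool,
#'   all covering the identical window.
#' @param design an [study_design()] object.
#' @param female_ceiling maximum tolerated female depth (default 0:
#'   literally no aligned female reads).
#' @param male_floor minimum male depth (default 3, mirroring the
#'   three-read detection limit used for probe detection).
#' @param min_length minimum reported interval length in bp.
#' @param merge_gap maximum gap in bp bridged when merging runs.
#' @return data frame of intervals, sorted by start: `chrom`, `start`,
#'   `end`, `length`, `min_male_depth`, `max_female_depth`.
#' @export
find_male_specific_intervals <- function(tracks, design,
                                         female_ceiling = 0,
                                         male_floor = 3,
                                         min_length = 200,
                                         merge_gap = 100) {
  by_pool <- stats::setNames(tracks,
                             vapply(tracks, `[[`, character(1), "pool"))
  pools <- design_pools(design)
  if (!all(pools %in% names(by_pool)))
    stop("need one depth track per design pool")
  tr <- by_pool[pools]
  starts <- vapply(tr, `[[`, numeric(1), "start")
  ends <- vapply(tr, `[[`, numeric(1), "end")
  chroms <- vapply(tr, `[[`, character(1), "chrom")
  if (length(unique(starts)) != 1L || length(unique(ends)) != 1L ||
      length(unique(chroms)) != 1L)
    stop("depth tracks cover mismatched windows")

  fem <- do.call(cbind, lapply(design$female_pool,
                               function(p) by_pool[[p]]$depth))
  mal <- do.call(cbind, lapply(design$male_pool,
                               function(p) by_pool[[p]]$depth))
  mask <- apply(fem, 1L, max) <= female_ceiling &
          apply(mal, 1L, min) >= male_floor
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(),
                      min_male_depth = numeric(),
                      max_female_depth = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)

  r <- rle(mask)
  off_end <- cumsum(r$lengths)
  off_start <- off_end - r$lengths + 1
  runs <- IRanges::IRanges(off_start[r$values], off_end[r$values])
  merged <- IRanges::reduce(runs, min.gapwidth = merge_gap + 1L)
  merged <- merged[IRanges::width(merged) >= min_length]
  if (!length(merged)) return(empty)

  w0 <- unname(starts[1])
  out <- data.frame(
    chrom = unname(chroms[1]),
    start = w0 + IRanges::start(merged) - 1,
    end = w0 + IRanges::end(merged) - 1,
    length = IRanges::width(merged),
    min_male_depth = vapply(seq_along(merged), function(i)
      min(mal[IRanges::start(merged)[i]:IRanges::end(merged)[i], ]),
      numeric(1)),
    max_female_depth = vapply(seq_along(merged), function(i)
      max(fem[IRanges::start(merged)[i]:IRanges::end(merged)[i], ]),
      numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap male-specific intervals with gene annotations
#'
#' Inclusive-coordinate overlap join: an interval touching an annotation
#' at a single shared base pair overlaps it.
#'
#' @param intervals data frame from [find_male_specific_intervals()].
#' @param annotations gene interval data frame (`name`, `chrom`, `start`,
#'   `end`), 1-based inclusive.
#' @return named list: one element per interval (named
#'   `"chrom:start-end"`), each a character vector of overlapping gene
#'   names (possibly empty).
#' @export
interval_gene_overlap <- function(intervals, annotations) {
  if (nrow(intervals) == 0L) return(stats::setNames(list(), character()))
  keys <- sprintf("%s:%s-%s", intervals$chrom,
                  format(intervals$start, scientific = FALSE, trim = TRUE),
                  format(intervals$end, scientific = FALSE, trim = TRUE))
  out <- stats::setNames(vector("list", nrow(intervals)), keys)
  for (i in seq_len(nrow(intervals))) {
    ann <- annotations[annotations$chrom == intervals$chrom[i], ,
                       drop = FALSE]
    hit <- ann$start <= intervals$end[i] & ann$end >= intervals$start[i]
    out[[i]] <- ann$name[hit]
  }
  out
}
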