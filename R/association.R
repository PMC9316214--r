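#' Tabulate individual assay calls into a genotype-by-sex 2x2 table
#'
#' Counts individuals by duplex-assay genotype (`xx`/`xy`) and
#' phenotypic sex (`F`/`M`). Individuals with a missing sex or genotype
#' are excluded from the table and reported in an exclusion tally.
#'
#' @param calls data frame with columns `id`, `sex` (`"F"`/`"M"`),
#'   `genotype` (`"xx"`/`"xy"`).
#' @return list of class `sex_table`: `a` (xy females), `b` (xy males),
#'   `c` (xx females), `d` (xx males), `n_excluded`.
#' @examples
#' fam <- data.frame(id = 1:15,
#'                   sex = rep(c("M", "F"), c(8, 7)),
#'                   genotype = rep(c("xy", "xx"), c(8, 7)))
#' tabulate_calls(fam)
#' @export
tabulate_calls <- function(calls) {
  if (nrow(calls) == 0L)
    return(structure(list(a = 0L, b = 0L, c = 0L, d = 0L,
                          n_excluded = 0L), class = "sex_table"))
  ok <- !is.na(calls$sex) & !is.na(calls$genotype) &
    calls$sex %in% c("F", "M") & calls$genotype %in% c("xx", "xy")
  kept <- calls[ok, , drop = FALSE]
  structure(list(
    a = sum(kept$genotype == "xy" & kept$sex == "F"),
    b = sum(kept$genotype == "xy" & kept$sex == "M"),
    c = sum(kept$genotype == "xx" & kept$sex == "F"),
    d = sum(kept$genotype == "xx" & kept$sex == "M"),
    n_excluded = sum(!ok)), class = "sex_table")
}

#' @export
print.sex_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("xy", "xx"), c("Females", "Males")))
  print(m)
  if (x$n_excluded) cat(sprintf("(%d excluded)\n", x$n_excluded))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact enumeration over every table with the observed margins, using
#' log-factorial (`lgamma`) arithmetic for the hypergeometric
#' probabilities. The two-sided p-value follows the probability-mass
#' criterion: the sum of probabilities of all tables at least as
#' improbable as the observed one, with a relative tie tolerance of
#' 1e-7 guarding floating-point equality.
#'
#' @param table a `sex_table` from [tabulate_calls()], or a numeric
#'   vector/matrix of four counts `(a, b, c, d)` = (xy-F, xy-M, xx-F,
#'   xx-M).
#' @return list of class `fisher_result`: `p_two_sided`, `p_observed`
#'   (the observed table's own probability).
#' @examples
#' fisher_two_sided(c(0, 8, 7, 0))$p_two_sided  # 1/6435
#' @export
fisher_two_sided <- function(table) {
  if (inherits(table, "sex_table"))
    table <- c(table$a, table$b, table$c, table$d)
  table <- as.numeric(table)
  if (length(table) != 4 || any(table < 0) || any(table != round(table)))
    stop("need four non-negative integer counts (a, b, c, d)")
  a <- table[1]; b <- table[2]; cc <- table[3]; d <- table[4]
  n <- a + b + cc + d
  if (n == 0) stop("Fisher test undefined for an all-zero table")
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc

  lfact <- function(x) lgamma(x + 1)
  logp <- function(k)
    lfact(r1) - lfact(k) - lfact(r1 - k) +
    lfact(r2) - lfact(c1 - k) - lfact(r2 - c1 + k) -
    (lfact(n) - lfact(c1) - lfact(n - c1))
  ks <- max(0, c1 - r2):min(r1, c1)
  lp <- vapply(ks, logp, numeric(1))
  lp_obs <- logp(a)
  p <- sum(exp(lp[lp <= lp_obs + log1p(1e-7)]))
  structure(list(p_two_sided = min(p, 1), p_observed = exp(lp_obs)),
            class = "fisher_result")
}

#' Format a p-value for reporting
#'
#' Rounds to `digits` decimals at display time only; values rounding to
#' zero are shown as a bound (e.g. `"<0.0001"`).
#'
#' @param p numeric p-value(s).
#' @param digits decimals shown (default 4).
#' @return character vector.
#' @export
format_p_value <- function(p, digits = 4) {
  floor_val <- 10^(-digits)
  ifelse(round(p, digits) < floor_val,
         paste0("<", format(floor_val, scientific = FALSE)),
         sprintf(paste0("%.", digits, "f"), p))
}

#' Sex-association report for a set of families
#'
#' Tabulates each family's calls (or uses pre-tabulated counts) and
#' applies [fisher_two_sided()], mirroring the worked-example layout:
#' genotype rows, per-sex counts, and the exact p-value both at full
#' precision and display-rounded.
#'
#' @param families named list; each element either a calls data frame
#'   (see [tabulate_calls()]) or a numeric vector `(a, b, c, d)`.
#' @return data frame with one row per family: counts, `p_value`,
#'   `p_display`.
#' @export
sex_association_report <- function(families) {
  rows <- lapply(names(families), function(nm) {
    x <- families[[nm]]
    tab <- if (is.data.frame(x)) tabulate_calls(x) else
      structure(list(a = x[1], b = x[2], c = x[3], d = x[4],
                     n_excluded = 0L), class = "sex_table")
    fr <- fisher_two_sided(tab)
    data.frame(family = nm, xy_females = tab$a, xy_males = tab$b,
               xx_females = tab$c, xx_males = tab$d,
               p_value = fr$p_two_sided,
               p_display = format_p_value(fr$p_two_sided),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
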