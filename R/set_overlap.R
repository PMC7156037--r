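# Venn-style set overlap with a one-sided Fisher's exact test against a
# stated universe.

#' Build the 2x2 overlap table of two sets in a universe
#'
#' @param setA,setB character vectors of locus IDs, both subsets of
#'   `universe`.
#' @param universe character vector of all eligible IDs.
#' @return 2x2 integer matrix: rows = in A / not in A, columns = in B /
#'   not in B, i.e. counts (in-both, A-only, B-only, neither).
#' @examples
#' overlap_table(c("a", "b"), c("b", "c"), letters[1:10])
#' @export
overlap_table <- function(setA, setB, universe) {
  universe <- unique(as.character(universe))
  setA <- unique(as.character(setA)); setB <- unique(as.character(setB))
  for (nm in c("setA", "setB")) {
    s <- get(nm)
    out <- setdiff(s, universe)
    if (length(out) > 0)
      stop("overlap_table: ", nm, " member(s) outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
  }
  a <- length(intersect(setA, setB))
  b <- length(setdiff(setA, setB))
  c_ <- length(setdiff(setB, setA))
  d <- length(universe) - a - b - c_
  matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
         dimnames = list(c("inA", "notA"), c("inB", "notB")))
}

#' One-sided Fisher's exact test of set overlap
#'
#' Upper-tail (enrichment) test of the overlap count: with N = universe
#' size, K = |A| and n = |B|, the p-value is P(X >= a) for X ~
#' hypergeometric(N, K, n). The odds ratio is the sample odds ratio
#' (a d)/(b c), reported as `Inf` when bc = 0 and ad > 0. Set
#' `alternative = "two.sided"` for the standard two-sided test (delegated
#' to [stats::fisher.test]).
#'
#' @param table 2x2 matrix from [overlap_table] (or any nonnegative integer
#'   2x2 table with the overlap in cell \[1,1\]).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An object of class `overlap_result`: list with `table`,
#'   `odds_ratio`, `p`.
#' @examples
#' fisher_exact_upper(overlap_table(letters[1:5], letters[3:8], letters))
#' @export
fisher_exact_upper <- function(table, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(table), all(dim(table) == 2))
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_exact_upper: table must contain nonnegative integers")
  if (sum(table) == 0)
    stop("fisher_exact_upper: all-zero table")
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  N <- sum(table); K <- a + b; n <- a + c_
  p <- if (alternative == "greater") {
    stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::fisher.test(table)$p.value
  }
  odds <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c_)
  structure(list(table = table, odds_ratio = odds, p = p,
                 alternative = alternative),
            class = "overlap_result")
}

#' Format a p-value with the conventional reporting floor
#'
#' Values below 2.2e-16 print as `"< 2.2e-16"`; the stored value keeps full
#' precision.
#'
#' @param p numeric p-value(s).
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  vapply(p, function(x)
    if (x < 2.2e-16) "< 2.2e-16" else format(x, digits = 3), character(1))
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("set overlap (", x$alternative, " Fisher's exact test)\n", sep = "")
  print(x$table)
  cat(sprintf("  odds ratio = %.4g, p = %s\n", x$odds_ratio,
              format_pvalue(x$p)))
  invisible(x)
}

#' Pairwise overlap tests among several sets
#'
#' Applies [overlap_table] + [fisher_exact_upper] to every pair of named
#' sets, the tabular companion of a Venn diagram.
#'
#' @param sets named list of character ID vectors.
#' @param universe character vector of all eligible IDs.
#' @param alternative passed to [fisher_exact_upper].
#' @return data.frame with one row per pair: `setA`, `setB`, `nA`, `nB`,
#'   `overlap`, `odds_ratio`, `p`, `p_label`.
#' @export
pairwise_overlap <- function(sets, universe, alternative = "greater") {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  pairs <- utils::combn(names(sets), 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    tab <- overlap_table(sets[[pr[1]]], sets[[pr[2]]], universe)
    res <- fisher_exact_upper(tab, alternative)
    data.frame(setA = pr[1], setB = pr[2],
               nA = tab[1, 1] + tab[1, 2], nB = tab[1, 1] + tab[2, 1],
               overlap = tab[1, 1], odds_ratio = res$odds_ratio, p = res$p,
               p_label = format_pvalue(res$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
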