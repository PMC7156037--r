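# Exactly testable expression/proteomics utilities: DE threshold filtering,
# 2^-ddCt relative quantification, NSAF spectral-count scoring.

#' Differential-expression thresholds
#'
#' Fold-change boundaries are inclusive (log2FC >= 2 is up, <= -2 is down);
#' the adjusted-p threshold is strict (padj < 0.01).
#'
#' @param log2fc_up,log2fc_down log2 fold-change cutoffs (defaults 2, -2).
#' @param padj_max adjusted p-value cutoff, exclusive (default 0.01).
#' @return An object of class `de_thresholds`.
#' @export
de_thresholds <- function(log2fc_up = 2, log2fc_down = -2, padj_max = 0.01) {
  if (!(log2fc_up > 0 && log2fc_down < 0))
    stop("de_thresholds: need log2fc_up > 0 > log2fc_down")
  if (padj_max <= 0 || padj_max >= 1)
    stop("de_thresholds: padj_max must lie in (0, 1)")
  structure(list(log2fc_up = log2fc_up, log2fc_down = log2fc_down,
                 padj_max = padj_max),
            class = "de_thresholds")
}

#' Filter a differential-expression table into up/down sets
#'
#' A locus is upregulated iff log2FC >= `log2fc_up` and padj < `padj_max`;
#' downregulated iff log2FC <= `log2fc_down` and padj < `padj_max`. Rows
#' with a missing padj are skipped with a warning.
#'
#' @param table data.frame with columns `locus`, `log2FC`, `padj`.
#' @param thresholds a [de_thresholds].
#' @return list with character vectors `up` and `down` (always disjoint).
#' @examples
#' tab <- data.frame(locus = c("a", "b", "c"),
#'                   log2FC = c(2.0, -2.5, 3.0), padj = c(0.005, 1e-4, 0.02))
#' de_filter(tab)
#' @export
de_filter <- function(table, thresholds = de_thresholds()) {
  stopifnot(all(c("locus", "log2FC", "padj") %in% names(table)))
  miss <- is.na(table$padj)
  if (any(miss)) {
    warning(sum(miss), " row(s) with missing padj skipped")
    table <- table[!miss, , drop = FALSE]
  }
  sig <- table$padj < thresholds$padj_max
  list(up = table$locus[sig & table$log2FC >= thresholds$log2fc_up],
       down = table$locus[sig & table$log2FC <= thresholds$log2fc_down])
}

#' Relative expression by the 2^-ddCt method
#'
#' For each group, Ct values are first averaged over replicates, then
#' dCt = mean target Ct - mean reference (housekeeping) Ct. ddCt is the
#' sample dCt minus the calibrator (wild-type) dCt, and the fold change is
#' 2^-ddCt, i.e. 1 for the calibrator relative to itself.
#'
#' @param sample,calibrator data.frames (or lists) with numeric `target_ct`
#'   and `reference_ct` (one value per replicate).
#' @return list with `dct_sample`, `dct_calibrator`, `ddct`, `fold`.
#' @examples
#' ddct_relative_expression(
#'   sample = data.frame(target_ct = 22, reference_ct = 20),
#'   calibrator = data.frame(target_ct = 25, reference_ct = 20)
#' )$fold  # 8
#' @export
ddct_relative_expression <- function(sample, calibrator) {
  dct <- function(x, who) {
    if (is.null(x$target_ct) || is.null(x$reference_ct) ||
        anyNA(x$target_ct) || anyNA(x$reference_ct))
      stop("ddct_relative_expression: missing target or reference Ct for ", who)
    if (any(c(x$target_ct, x$reference_ct) <= 0) ||
        any(!is.finite(c(x$target_ct, x$reference_ct))))
      stop("ddct_relative_expression: Ct values must be finite and positive")
    mean(x$target_ct) - mean(x$reference_ct)
  }
  dct_s <- dct(sample, "sample")
  dct_c <- dct(calibrator, "calibrator")
  ddct <- dct_s - dct_c
  list(dct_sample = dct_s, dct_calibrator = dct_c, ddct = ddct,
       fold = 2^(-ddct))
}

#' Normalized spectral abundance factor (NSAF)
#'
#' Length-normalized spectral counts: SAF_i = count_i / length_i, NSAF_i =
#' SAF_i / sum_j SAF_j, reported as NSAF_i x `scale` (the NSAFe5 convention
#' uses scale = 1e5). The reported values sum to `scale`.
#'
#' @param counts data.frame with `protein`, `count` (spectral counts >= 0)
#'   and `length` (protein length in residues, > 0).
#' @param scale reporting scale factor (default 1e5).
#' @return data.frame `protein`, `count`, `length`, `saf`, `nsaf` (already
#'   scaled).
#' @examples
#' nsaf(data.frame(protein = c("p1", "p2"), count = c(10, 10),
#'                 length = c(100, 200)))
#' @export
nsaf <- function(counts, scale = 1e5) {
  stopifnot(all(c("protein", "count", "length") %in% names(counts)))
  if (any(counts$count < 0)) stop("nsaf: negative spectral count")
  if (any(counts$length <= 0)) stop("nsaf: protein length must be > 0")
  if (all(counts$count == 0)) stop("nsaf: all spectral counts are zero")
  saf <- counts$count / counts$length
  data.frame(protein = counts$protein, count = counts$count,
             length = counts$length, saf = saf,
             nsaf = saf / sum(saf) * scale, stringsAsFactors = FALSE)
}
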