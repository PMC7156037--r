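# Mapping-by-sequencing scan: EMS-spectrum filter -> zygosity classification
# by pooled allele frequency -> windowed homozygote/heterozygote ratio ->
# linkage-interval call.

#' EMS-spectrum variant filter
#'
#' EMS (ethyl methane sulfonate) alkylates guanine and induces almost
#' exclusively G:C -> A:T transitions, so candidate induced mutations are the
#' records with ref G / alt A, or ref C / alt T (the same event read on the
#' other strand). Records whose ref or alt is not a single A/C/G/T base
#' (indels, ambiguity codes) are rejected with a warning, not an error.
#'
#' @param variants data.frame with character columns `ref` and `alt`.
#' @return The subset of rows matching the EMS spectrum, input order
#'   preserved.
#' @export
ems_filter <- function(variants) {
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  valid <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!valid))
    warning(sum(!valid), " record(s) with non-ACGT ref/alt rejected ",
            "(indel or ambiguity code)")
  keep <- valid & ((ref == "G" & alt == "A") | (ref == "C" & alt == "T"))
  variants[keep, , drop = FALSE]
}

#' Zygosity classification thresholds
#'
#' Pooled-frequency bands used to call a variant homozygous (freq >=
#' `hom_min`) or heterozygous (`het_min` <= freq <= `het_max`) in the
#' selected pool; frequencies in neither band are discarded.
#'
#' @param hom_min minimum frequency of a homozygous call (default 0.80).
#' @param het_min,het_max heterozygous band bounds (defaults 0.45, 0.55).
#' @return An object of class `zygosity_thresholds`.
#' @export
zygosity_thresholds <- function(hom_min = 0.80, het_min = 0.45, het_max = 0.55) {
  if (!(0 < het_min && het_min <= het_max && het_max < hom_min && hom_min <= 1))
    stop("zygosity_thresholds: need 0 < het_min <= het_max < hom_min <= 1")
  structure(list(hom_min = hom_min, het_min = het_min, het_max = het_max),
            class = "zygosity_thresholds")
}

#' Classify variant zygosity from pooled allele frequency
#'
#' Band boundaries are inclusive: a variant is homozygous iff its frequency
#' is >= `hom_min`, heterozygous iff `het_min` <= freq <= `het_max`, and
#' discarded otherwise.
#'
#' @param freq numeric vector of allele frequencies in \[0, 1\].
#' @param thresholds a [zygosity_thresholds].
#' @return factor with levels `homozygous`, `heterozygous`, `discarded`.
#' @examples
#' classify_zygosity(c(0.85, 0.50, 0.70))
#' @export
classify_zygosity <- function(freq, thresholds = zygosity_thresholds()) {
  stopifnot(inherits(thresholds, "zygosity_thresholds"))
  if (any(is.na(freq)) || any(freq < 0 | freq > 1))
    stop("classify_zygosity: frequencies must lie in [0, 1]")
  out <- rep("discarded", length(freq))
  out[freq >= thresholds$hom_min] <- "homozygous"
  out[freq >= thresholds$het_min & freq <= thresholds$het_max] <- "heterozygous"
  factor(out, levels = c("homozygous", "heterozygous", "discarded"))
}

#' Windowed homozygote/heterozygote ratio scan
#'
#' Tiles each chromosome with non-overlapping windows (the terminal window
#' may be shorter), assigns every classified variant to exactly one window,
#' and scores each window with ratio = n_hom / max(n_het, 1). An empty
#' window scores 0. Counts are not length-normalized.
#'
#' @param variants data.frame with `chrom`, `pos` and a `zygosity` column
#'   (as produced by [classify_zygosity]); `discarded` variants are ignored.
#' @param genome a [genome_model].
#' @param window_size window width in bp (default 500 kb).
#' @return data.frame of window statistics: `chrom`, `start`, `end` (1-based
#'   inclusive), `n_hom`, `n_het`, `ratio`, covering every window of every
#'   chromosome.
#' @export
window_ratio_scan <- function(variants, genome, window_size = 5e5) {
  stopifnot(inherits(genome, "genome_model"), window_size >= 1)
  if (!"zygosity" %in% names(variants))
    stop("window_ratio_scan: variants lack a 'zygosity' column")
  chrn <- genome$chromosomes$name
  unknown <- !(variants$chrom %in% chrn)
  if (any(unknown))
    stop("window_ratio_scan: variant on unknown chromosome at ",
         variants$chrom[unknown][1], ":", variants$pos[unknown][1])
  beyond <- variants$pos > chrom_length(genome, variants$chrom) | variants$pos < 1
  if (any(beyond))
    stop("window_ratio_scan: variant position outside chromosome at ",
         variants$chrom[beyond][1], ":", variants$pos[beyond][1])

  out <- lapply(seq_along(chrn), function(ci) {
    len <- genome$chromosomes$length[ci]
    nw <- ceiling(len / window_size)
    idx <- variants$chrom == chrn[ci] & variants$zygosity != "discarded"
    wi <- floor((variants$pos[idx] - 1) / window_size) + 1
    n_hom <- tabulate(wi[variants$zygosity[idx] == "homozygous"], nw)
    n_het <- tabulate(wi[variants$zygosity[idx] == "heterozygous"], nw)
    data.frame(chrom = chrn[ci],
               start = (seq_len(nw) - 1) * window_size + 1,
               end = pmin(seq_len(nw) * window_size, len),
               n_hom = n_hom, n_het = n_het,
               ratio = n_hom / pmax(n_het, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# centered running sum over `smooth` windows, shrinking at chromosome ends
.run_sum <- function(x, smooth) {
  if (smooth <= 1) return(x)
  h <- smooth %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  cs[hi + 1] - cs[lo]
}

#' Call the linkage interval from a window scan
#'
#' Locates the window with the genome-wide maximum hom/het ratio and reports
#' the maximal run of contiguous windows on that chromosome, containing the
#' peak, whose ratios all reach `tau` times the peak ratio.
#'
#' Because a single 500-kb window holds few markers at typical EMS densities
#' (a handful of mutations per Mb), per-window ratios are noisy; the caller
#' therefore first pools the hom/het counts in a centered running sum over
#' `smooth` windows and applies the peak/run rule to the smoothed ratios.
#' The default (11 windows, i.e. a 5.5-Mb span at the 500-kb default) pools
#' on the order of ten classified markers per evaluation point under
#' realistic densities. `smooth = 1` disables pooling and applies the rule
#' to the raw per-window ratios.
#'
#' @param scan data.frame from [window_ratio_scan].
#' @param tau run threshold as a fraction of the peak ratio, in (0, 1\].
#' @param smooth odd number of windows pooled per evaluation point.
#' @return An object of class `linkage_interval`: list with `chrom`,
#'   `start`, `end`, `peak_start`, `peak_end`, `peak_ratio` (the maximum
#'   smoothed ratio) and `windows` (the scan rows of the interval).
#' @export
call_linkage_interval <- function(scan, tau = 0.5, smooth = 11L) {
  stopifnot(nrow(scan) > 0, tau > 0, tau <= 1, smooth >= 1)
  if (all(scan$ratio == 0))
    stop("call_linkage_interval: no linkage signal (all window ratios zero); ",
         "consider a larger pool or higher sequencing depth")
  chrn <- unique(scan$chrom)
  sm <- do.call(rbind, lapply(chrn, function(ch) {
    sub <- scan[scan$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    sub$sm_ratio <- .run_sum(sub$n_hom, smooth) /
      pmax(.run_sum(sub$n_het, smooth), 1)
    sub
  }))
  # earliest chromosome, then smallest coordinate, on ties
  pk <- which(sm$sm_ratio == max(sm$sm_ratio))[1]
  pk_chrom <- sm$chrom[pk]
  peak_ratio <- sm$sm_ratio[pk]
  sub <- sm[sm$chrom == pk_chrom, , drop = FALSE]
  pki <- which(sub$start == sm$start[pk])
  ok <- sub$sm_ratio >= tau * peak_ratio
  lo <- pki; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- pki; while (hi < nrow(sub) && ok[hi + 1]) hi <- hi + 1
  structure(list(chrom = pk_chrom,
                 start = sub$start[lo], end = sub$end[hi],
                 peak_start = sub$start[pki], peak_end = sub$end[pki],
                 peak_ratio = peak_ratio,
                 windows = sub[lo:hi, setdiff(names(sub), "sm_ratio"),
                               drop = FALSE]),
            class = "linkage_interval")
}

#' @export
print.linkage_interval <- function(x, ...) {
  cat(sprintf("linkage interval %s:%d-%d (%.2f Mb), peak %s:%d-%d, ratio %.2f\n",
              x$chrom, x$start, x$end, (x$end - x$start + 1) / 1e6,
              x$chrom, x$peak_start, x$peak_end, x$peak_ratio))
  invisible(x)
}

#' Run the full mapping-by-sequencing pipeline
#'
#' Deterministic composition of [ems_filter], [classify_zygosity],
#' [window_ratio_scan] and [call_linkage_interval]. Accepts either a VCF
#' path (read with [read_bsa_vcf]; frequencies recomputed from AD/DP, AF as
#' fallback) or an in-memory variant data.frame.
#'
#' @param vcf VCF file path, or a variant data.frame with `chrom`, `pos`,
#'   `ref`, `alt`, `allele_freq` (and optionally `alt_depth`/`total_depth`).
#' @param genome a [genome_model].
#' @param thresholds a [zygosity_thresholds].
#' @param window_size window width in bp.
#' @param tau,smooth interval-calling parameters, see
#'   [call_linkage_interval].
#' @param exclude optional data.frame (`chrom`, `pos`) of known background
#'   polymorphisms to remove before EMS filtering.
#' @param outdir if non-NULL, writes `windows.bed` (score = ratio),
#'   `interval.bed` and `scan.tsv` there.
#' @return list with `interval` (a `linkage_interval`), `scan` (window
#'   statistics) and `variants` (the classified EMS variants).
#' @export
run_mapping <- function(vcf, genome, thresholds = zygosity_thresholds(),
                        window_size = 5e5, tau = 0.5, smooth = 11L,
                        exclude = NULL, outdir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_mapping [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  variants <- if (is.character(vcf)) stage("read_vcf", read_bsa_vcf(vcf)) else vcf
  if (!is.null(exclude) && nrow(variants) > 0) {
    drop <- paste(variants$chrom, variants$pos) %in%
      paste(exclude$chrom, exclude$pos)
    variants <- variants[!drop, , drop = FALSE]
  }
  if (nrow(variants) == 0)
    stop("run_mapping [read_vcf]: no variants; nothing to map", call. = FALSE)
  variants <- stage("ems_filter", ems_filter(variants))
  if (nrow(variants) == 0)
    stop("run_mapping [ems_filter]: no EMS-spectrum variants left", call. = FALSE)
  variants$zygosity <- stage("classify_zygosity",
                             classify_zygosity(variants$allele_freq, thresholds))
  scan <- stage("window_ratio_scan",
                window_ratio_scan(variants, genome, window_size))
  interval <- stage("call_linkage_interval",
                    call_linkage_interval(scan, tau = tau, smooth = smooth))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_bed(scan, file.path(outdir, "windows.bed"),
              name = sprintf("%s_w%d", scan$chrom,
                             seq_len(nrow(scan))),
              score = scan$ratio)
    write_bed(data.frame(chrom = interval$chrom, start = interval$start,
                         end = interval$end),
              file.path(outdir, "interval.bed"),
              name = "linkage_interval", score = interval$peak_ratio)
    utils::write.table(scan, file.path(outdir, "scan.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(interval = interval, scan = scan, variants = variants)
}
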