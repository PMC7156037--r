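# Compartment classification (chromosome arm vs pericentromere), chi-square
# goodness-of-fit enrichment against a genomic background, and heterochromatin
# chromatin-state overlap fractions.

#' Classify loci into chromosome arms vs pericentromeres
#'
#' A locus is pericentromeric iff its midpoint, floor((start + end) / 2),
#' lies within the chromosome's pericentromere interval (boundaries
#' inclusive); otherwise it is on an arm. Midpoints are used because the two
#' compartments partition the chromosome, so every locus gets exactly one
#' label.
#'
#' @param loci data.frame with `chrom`, `start`, `end`.
#' @param genome a [genome_model] with pericentromere intervals.
#' @return factor with levels `arm`, `pericentromeric`, one per locus.
#' @export
classify_compartment <- function(loci, genome) {
  stopifnot(inherits(genome, "genome_model"))
  if (is.null(genome$pericentromere))
    stop("classify_compartment: genome has no pericentromere intervals")
  i <- match(loci$chrom, genome$pericentromere$chrom)
  if (anyNA(i))
    stop("classify_compartment: unknown chromosome: ",
         paste(unique(loci$chrom[is.na(i)]), collapse = ", "))
  mid <- floor((loci$start + loci$end) / 2)
  peri <- mid >= genome$pericentromere$start[i] &
    mid <= genome$pericentromere$end[i]
  factor(ifelse(peri, "pericentromeric", "arm"),
         levels = c("arm", "pericentromeric"))
}

#' Background compartment proportions
#'
#' The expected arm/pericentromere split of a locus class (all annotated
#' genes, or all TEs), used as the null of [chi2_enrichment].
#'
#' @param all_loci data.frame of background loci with `chrom`, `start`,
#'   `end` and a `class` column.
#' @param class keep only loci of this class (`"gene"` or `"TE"`); `NULL`
#'   keeps everything.
#' @param genome a [genome_model].
#' @return named numeric vector `c(p_arm, p_peri)` summing to 1.
#' @export
background_proportions <- function(all_loci, class = NULL, genome) {
  if (!is.null(class)) all_loci <- all_loci[all_loci$class == class, , drop = FALSE]
  if (nrow(all_loci) == 0)
    stop("background_proportions: empty background after class filtering")
  comp <- classify_compartment(all_loci, genome)
  n <- length(comp)
  c(p_arm = sum(comp == "arm") / n,
    p_peri = sum(comp == "pericentromeric") / n)
}

#' Chi-square test of compartment enrichment
#'
#' Goodness-of-fit of the observed arm/pericentromere counts of a locus set
#' against the genomic background proportions: chi2 = sum((O - E)^2 / E)
#' with E = n * p and df = 1, no continuity correction; p is the upper-tail
#' chi-square probability. Significance labels follow the usual convention:
#' `**` for p <= 0.01, `*` for p <= 0.05, `n.s` otherwise.
#'
#' @param set data.frame of loci (`chrom`, `start`, `end`).
#' @param background named proportions `c(p_arm, p_peri)` from
#'   [background_proportions].
#' @param genome a [genome_model].
#' @return An object of class `enrichment_result`: list with `observed`
#'   (named counts), `expected`, `proportions`, `chi2`, `df`, `p`, `stars`.
#' @examples
#' gm <- genome_model(data.frame(name = "Chr1", length = 1e6),
#'                    data.frame(chrom = "Chr1", start = 4e5, end = 6e5))
#' set <- data.frame(chrom = "Chr1", start = c(1e5, 5e5), end = c(1.1e5, 5.1e5))
#' chi2_enrichment(set, c(p_arm = 0.8, p_peri = 0.2), gm)
#' @export
chi2_enrichment <- function(set, background, genome) {
  stopifnot(nrow(set) >= 1, length(background) == 2)
  if (abs(sum(background) - 1) > 1e-9)
    stop("chi2_enrichment: background proportions must sum to 1")
  comp <- classify_compartment(set, genome)
  observed <- c(n_arm = sum(comp == "arm"),
                n_peri = sum(comp == "pericentromeric"))
  n <- sum(observed)
  expected <- n * as.numeric(background)
  if (any(expected <= 0))
    stop("chi2_enrichment: an expected count is zero; ",
         "use a background containing both compartments")
  chi2 <- sum((observed - expected)^2 / expected)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  stars <- if (p <= 0.01) "**" else if (p <= 0.05) "*" else "n.s"
  structure(list(observed = observed,
                 expected = stats::setNames(expected, c("E_arm", "E_peri")),
                 proportions = background, chi2 = chi2, df = 1L, p = p,
                 stars = stars),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("compartment enrichment: arm %d / peri %d (expected %.1f / %.1f)\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  cat(sprintf("  chi2 = %.4g, df = 1, p = %s  %s\n", x$chi2, format_pvalue(x$p),
              x$stars))
  invisible(x)
}

#' Fraction of loci in heterochromatic chromatin states
#'
#' Fraction of a locus set overlapping a chromatin-state annotation (e.g.
#' the heterochromatin states 8 and 9 of the Arabidopsis nine-state
#' segmentation, a proxy for DNA-methylated / H3K9me2 targets). Because
#' state segmentations are fragmented, membership is by overlap fraction: a
#' locus counts as targeted when at least `min_overlap` of its length is
#' covered by intervals of the requested states.
#'
#' @param set data.frame of loci with `id`, `chrom`, `start`, `end`.
#' @param states_annotation data.frame with `chrom`, `start`, `end`,
#'   `state` (integer labels), e.g. from [read_bed] with states in the name
#'   column.
#' @param states state labels that count (default `c(8, 9)`).
#' @param min_overlap minimum covered fraction of the locus (default 0.5;
#'   a locus with exactly half its length covered counts).
#' @return list with `fraction`, `n_targeted`, `n` and `targeted` (named
#'   logical vector).
#' @export
chromatin_state_fraction <- function(set, states_annotation, states = c(8, 9),
                                     min_overlap = 0.5) {
  if (is.null(states_annotation) || nrow(states_annotation) == 0)
    stop("chromatin_state_fraction: no chromatin-state annotation loaded")
  ann <- states_annotation[states_annotation$state %in% states, , drop = FALSE]
  loci_gr <- .as_granges(set)
  cov <- if (nrow(ann) > 0) {
    ann_gr <- GenomicRanges::reduce(.as_granges(ann))
    hits <- GenomicRanges::findOverlaps(loci_gr, ann_gr)
    ov <- GenomicRanges::pintersect(loci_gr[S4Vectors::queryHits(hits)],
                                    ann_gr[S4Vectors::subjectHits(hits)])
    tapply(BiocGenerics::width(ov), S4Vectors::queryHits(hits), sum)
  } else NULL
  covered <- numeric(nrow(set))
  if (!is.null(cov)) covered[as.integer(names(cov))] <- cov
  frac_cov <- covered / (set$end - set$start + 1)
  targeted <- frac_cov >= min_overlap
  names(targeted) <- if ("id" %in% names(set)) set$id else seq_len(nrow(set))
  list(fraction = mean(targeted), n_targeted = sum(targeted),
       n = nrow(set), targeted = targeted)
}
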