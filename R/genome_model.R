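#' Genome model: chromosomes, pericentromeres, recombination rate
#'
#' The coordinate authority shared by every stage of the pipeline: an ordered
#' set of chromosomes with lengths, one pericentromeric interval per
#' chromosome (1-based, inclusive), and a uniform recombination rate used to
#' convert physical to genetic distance.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp), in
#'   karyotype order.
#' @param pericentromere data.frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), one row per chromosome. May be `NULL` if no
#'   compartment analysis is intended.
#' @param cm_per_mb uniform recombination rate in centimorgan per megabase.
#'   The Arabidopsis genome-wide average is close to 4 cM/Mb, the default.
#'
#' @return An object of class `genome_model`.
#' @examples
#' gm <- genome_model(
#'   data.frame(name = c("Chr1", "Chr2"), length = c(3e7, 2e7)),
#'   data.frame(chrom = c("Chr1", "Chr2"), start = c(12e6, 8e6),
#'              end = c(18e6, 12e6))
#' )
#' chrom_length(gm, "Chr1")
#' @export
genome_model <- function(chromosomes, pericentromere = NULL, cm_per_mb = 4) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  if (nrow(chromosomes) < 1L)
    stop("genome_model: at least one chromosome is required")
  if (anyDuplicated(chromosomes$name))
    stop("genome_model: duplicated chromosome names")
  if (any(chromosomes$length <= 0))
    stop("genome_model: chromosome lengths must be > 0")
  if (!is.numeric(cm_per_mb) || cm_per_mb <= 0)
    stop("genome_model: cm_per_mb must be > 0")
  chromosomes$name <- as.character(chromosomes$name)
  if (!is.null(pericentromere)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(pericentromere)))
    pericentromere$chrom <- as.character(pericentromere$chrom)
    bad <- !(pericentromere$chrom %in% chromosomes$name)
    if (any(bad))
      stop("genome_model: pericentromere on unknown chromosome: ",
           paste(pericentromere$chrom[bad], collapse = ", "))
    len <- chromosomes$length[match(pericentromere$chrom, chromosomes$name)]
    if (any(pericentromere$start < 1 | pericentromere$end > len |
            pericentromere$start > pericentromere$end))
      stop("genome_model: pericentromere interval not contained in its chromosome")
  }
  structure(
    list(chromosomes = chromosomes, pericentromere = pericentromere,
         cm_per_mb = cm_per_mb),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosome(s),",
      sprintf("%.1f Mb total,", sum(x$chromosomes$length) / 1e6),
      x$cm_per_mb, "cM/Mb\n")
  invisible(x)
}

#' @rdname genome_model
#' @param genome a `genome_model`.
#' @param chrom chromosome name(s).
#' @export
chrom_length <- function(genome, chrom) {
  stopifnot(inherits(genome, "genome_model"))
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i))
    stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$chromosomes$length[i]
}

#' Haldane recombination model
#'
#' Converts physical distance to genetic distance at a uniform rate and maps
#' genetic distance d (Morgans) to a recombination fraction with Haldane's
#' function r = (1 - exp(-2 d)) / 2, so r(0) = 0 and r -> 1/2 as d grows.
#'
#' @param cm_per_mb recombination rate (centimorgan per megabase).
#' @return An object of class `recomb_model` with elements `map_function`
#'   (always "haldane") and `cm_per_mb`.
#' @examples
#' rm <- recomb_model(4)
#' recomb_fraction(0.5)            # (1 - exp(-1)) / 2
#' genetic_distance(rm, 1e6)       # 0.04 Morgans
#' @export
recomb_model <- function(cm_per_mb = 4) {
  if (!is.numeric(cm_per_mb) || cm_per_mb <= 0)
    stop("recomb_model: cm_per_mb must be > 0")
  structure(list(map_function = "haldane", cm_per_mb = cm_per_mb),
            class = "recomb_model")
}

#' @rdname recomb_model
#' @param d genetic distance in Morgans (non-negative).
#' @export
recomb_fraction <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d)) / 2
}

#' @rdname recomb_model
#' @param model a `recomb_model`.
#' @param bp physical distance in base pairs.
#' @export
genetic_distance <- function(model, bp) {
  stopifnot(inherits(model, "recomb_model"))
  bp / 1e6 * model$cm_per_mb / 100
}
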