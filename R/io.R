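# File formats: VCF v4.2 for pooled variants (vcfR on the way in), BED via
# rtracklayer (1-based GRanges <-> 0-based half-open on disk), FASTA via
# Biostrings, TSV via write.table.

#' Write pooled variants to a VCF v4.2 file
#'
#' Emits one record per variant with INFO fields AD (alternate read depth),
#' DP (total depth) and AF (alternate allele frequency), plus contig header
#' lines taken from the genome model.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `alt_depth`, `total_depth`, `allele_freq`.
#' @param genome a [genome_model] supplying contig lengths.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bsa_vcf <- function(variants, genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamapr",
    sprintf("##contig=<ID=%s,length=%d>", genome$chromosomes$name,
            as.integer(genome$chromosomes$length)),
    '##INFO=<ID=AD,Number=1,Type=Integer,Description="Alternate allele read depth">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele frequency">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- if (nrow(variants) > 0) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAD=%d;DP=%d;AF=%s",
            variants$chrom, as.integer(variants$pos), variants$ref,
            variants$alt, as.integer(variants$alt_depth),
            as.integer(variants$total_depth),
            sprintf("%.6g", variants$allele_freq))
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled variants from a VCF file
#'
#' Parses a VCF with `vcfR` and rebuilds the variant table the pipeline
#' operates on. Allele frequencies are recomputed from AD/DP when both are
#' present; the AF INFO field is used only as a fallback.
#'
#' @param path VCF file path.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `alt_depth`, `total_depth`, `allele_freq`.
#' @export
read_bsa_vcf <- function(path) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      ref = character(0), alt = character(0),
                      alt_depth = numeric(0), total_depth = numeric(0),
                      allele_freq = numeric(0), stringsAsFactors = FALSE)
  n_body <- sum(!startsWith(readLines(path, warn = FALSE), "#"))
  if (n_body == 0) return(empty)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AD")))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  freq <- ifelse(!is.na(ad) & !is.na(dp), ifelse(dp > 0, ad / dp, 0), af)
  data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             alt_depth = ad, total_depth = dp, allele_freq = freq,
             stringsAsFactors = FALSE)
}

# 1-based inclusive data.frame -> GRanges (rtracklayer converts to 0-based
# half-open on export)
.as_granges <- function(df, genome = NULL, name = NULL, score = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- score
  if (!is.null(genome)) {
    sl <- stats::setNames(genome$chromosomes$length, genome$chromosomes$name)
    GenomeInfoDb::seqlengths(gr) <- sl[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Write genomic intervals to a BED file
#'
#' Coordinates are converted from the package's 1-based inclusive convention
#' to BED's 0-based half-open convention by `rtracklayer`.
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive).
#' @param path output file path.
#' @param name,score optional vectors for the BED name and score columns.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, name = NULL, score = NULL) {
  rtracklayer::export(.as_granges(df, name = name, score = score), path,
                      format = "BED")
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file path.
#' @return data.frame `chrom`, `start`, `end` (1-based inclusive) plus
#'   `name` and `score` columns when present in the file.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if ("name" %in% names(mc)) df$name <- mc$name
  if ("score" %in% names(mc)) df$score <- mc$score
  df
}
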