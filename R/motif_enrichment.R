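# Promoter motif scanning and carrier enrichment: IUPAC consensus or PWM
# models, 1-kb promoter extraction anchored at the translation start, exact
# both-strand scanning, carrier proportions and a random-gene resampling
# null.

#' Motif model: IUPAC consensus or position weight matrix
#'
#' Either representation of a DNA motif. In consensus mode scanning is an
#' exact IUPAC match; in PWM mode each window is scored with the log2-odds
#' of the column probabilities against a uniform background, and a window is
#' a hit when its score reaches `threshold` times the maximal achievable
#' score.
#'
#' @param consensus IUPAC consensus string (A/C/G/T plus ambiguity codes).
#' @param pwm 4 x L numeric matrix with rownames A, C, G, T; each column
#'   must sum to 1 (tolerance 1e-9).
#' @param threshold PWM hit threshold as a fraction of the maximal score,
#'   in (0, 1]. Ignored in consensus mode.
#' @return An object of class `motif_model`.
#' @examples
#' motif_model(consensus = "TGACGT")
#' @export
motif_model <- function(consensus = NULL, pwm = NULL, threshold = 0.9) {
  if (is.null(consensus) == is.null(pwm))
    stop("motif_model: supply exactly one of consensus or pwm")
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    if (nchar(consensus) == 0) stop("motif_model: empty motif")
    ok <- strsplit(consensus, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
    if (!all(ok)) stop("motif_model: consensus contains non-IUPAC characters")
    mode <- "consensus"
    len <- nchar(consensus)
  } else {
    stopifnot(is.matrix(pwm), nrow(pwm) == 4)
    if (is.null(rownames(pwm))) rownames(pwm) <- c("A", "C", "G", "T")
    pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
    if (ncol(pwm) == 0) stop("motif_model: empty motif")
    if (any(abs(colSums(pwm) - 1) > 1e-9))
      stop("motif_model: PWM columns must each sum to 1")
    if (threshold <= 0 || threshold > 1)
      stop("motif_model: threshold must lie in (0, 1]")
    mode <- "pwm"
    len <- ncol(pwm)
  }
  structure(list(mode = mode, consensus = consensus, pwm = pwm,
                 threshold = threshold, length = len),
            class = "motif_model")
}

#' @rdname motif_model
#' @param motif a `motif_model`.
#' @return `motif_consensus`: the consensus string (in PWM mode, the
#'   per-column argmax letter; ties resolved toward the first of A, C, G, T).
#' @export
motif_consensus <- function(motif) {
  stopifnot(inherits(motif, "motif_model"))
  if (motif$mode == "consensus") return(motif$consensus)
  paste(rownames(motif$pwm)[apply(motif$pwm, 2, which.max)], collapse = "")
}

#' Read a motif from MEME minimal format
#'
#' Parses the first (or named) motif of a MEME minimal-format file: the
#' `letter-probability matrix` block under a `MOTIF` line, with columns in
#' A, C, G, T order.
#'
#' @param path file path.
#' @param name optional motif name; default is the first motif in the file.
#' @param threshold PWM hit threshold passed to [motif_model].
#' @return a [motif_model] in PWM mode.
#' @export
read_meme_motif <- function(path, name = NULL, threshold = 0.9) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0) stop("read_meme_motif: no MOTIF block in ", path)
  if (!is.null(name)) {
    nm <- vapply(strsplit(lines[starts], "\\s+"), function(x) x[2], character(1))
    starts <- starts[nm == name]
    if (length(starts) == 0) stop("read_meme_motif: motif '", name, "' not found")
  }
  i <- starts[1]
  hdr <- grep("letter-probability matrix", lines)
  hdr <- hdr[hdr > i][1]
  if (is.na(hdr)) stop("read_meme_motif: no letter-probability matrix block")
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
  rows <- lines[(hdr + 1):(hdr + w)]
  mat <- t(vapply(strsplit(trimws(rows), "\\s+"),
                  function(x) as.numeric(x[1:4]), numeric(4)))
  pwm <- t(mat)  # 4 x w, rows A C G T
  rownames(pwm) <- c("A", "C", "G", "T")
  pwm <- sweep(pwm, 2, colSums(pwm), "/")  # renormalize printed rounding
  motif_model(pwm = pwm, threshold = threshold)
}

#' Extract promoter sequences upstream of the translation start
#'
#' Returns the `length`-bp sequence 5' of each gene's translation start
#' (ATG) on the coding strand: for a plus-strand gene the window ends one bp
#' before the ATG; for a minus-strand gene the downstream genomic window is
#' reverse-complemented. Promoters running off the chromosome edge are
#' truncated with a warning.
#'
#' @param genes data.frame with `id`, `chrom`, `strand` (`"+"`/`"-"`) and
#'   either `tstart` (translation-start coordinate) or `start`/`end` (the
#'   translation start is then `start` on `+`, `end` on `-`).
#' @param genome_seq named [Biostrings::DNAStringSet] of chromosome
#'   sequences.
#' @param length promoter length in bp (default 1000).
#' @return [Biostrings::DNAStringSet] named by gene ID.
#' @export
extract_promoters <- function(genes, genome_seq, length = 1000) {
  stopifnot(is.data.frame(genes), all(c("id", "chrom") %in% names(genes)))
  if (!"strand" %in% names(genes) || anyNA(genes$strand) ||
      !all(genes$strand %in% c("+", "-")))
    stop("extract_promoters: every gene needs strand '+' or '-'")
  tstart <- if ("tstart" %in% names(genes)) genes$tstart else
    ifelse(genes$strand == "+", genes$start, genes$end)
  if (!all(genes$chrom %in% names(genome_seq)))
    stop("extract_promoters: chromosome sequence missing for some gene")
  chrlen <- Biostrings::width(genome_seq)[match(genes$chrom, names(genome_seq))]
  from <- ifelse(genes$strand == "+", tstart - length, tstart + 1)
  to <- ifelse(genes$strand == "+", tstart - 1, tstart + length)
  truncated <- from < 1 | to > chrlen
  if (any(truncated))
    warning(sum(truncated), " promoter(s) truncated at a chromosome edge: ",
            paste(utils::head(genes$id[truncated], 5), collapse = ", "))
  from <- pmax(from, 1)
  to <- pmin(to, chrlen)
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(genes)), function(i) {
    s <- Biostrings::subseq(genome_seq[[genes$chrom[i]]], from[i], to[i])
    if (genes$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    as.character(s)
  }, character(1)))
  names(seqs) <- genes$id
  seqs
}

# integer codes 1..4 for A,C,G,T; NA for anything else (N never matches)
.dna_codes <- function(seq_chr) {
  match(strsplit(toupper(seq_chr), "")[[1]], c("A", "C", "G", "T"))
}

.pwm_logodds <- function(pwm) log2(pwm / 0.25)

.pwm_scores <- function(codes, lo) {
  L <- ncol(lo); n <- length(codes)
  if (n < L) return(numeric(0))
  np <- n - L + 1
  s <- numeric(np)
  for (j in seq_len(L)) {
    v <- lo[cbind(codes[j:(j + np - 1)], j)]
    v[is.na(v)] <- -Inf
    s <- s + v
  }
  s
}

#' Scan a sequence for motif occurrences
#'
#' Both strands are scanned by default. Hit positions are reported as
#' 1-based starts on the forward strand regardless of the hit's strand. In
#' consensus mode the match is an exact IUPAC match (an N in the sequence
#' never matches); in PWM mode a window is a hit when its log2-odds score
#' (vs a uniform background) reaches `threshold` times the maximal
#' achievable score.
#'
#' @param sequence a [Biostrings::DNAString], or a single character string.
#' @param motif a [motif_model].
#' @param both_strands scan the reverse strand too (default TRUE).
#' @return data.frame with columns `position`, `strand`, `score` (NA in
#'   consensus mode), ordered by position.
#' @export
scan_motif <- function(sequence, motif, both_strands = TRUE) {
  stopifnot(inherits(motif, "motif_model"))
  if (is.character(sequence)) sequence <- Biostrings::DNAString(sequence)
  if (motif$mode == "consensus") {
    pat <- Biostrings::DNAString(motif$consensus)
    fwd <- Biostrings::matchPattern(pat, sequence,
                                    fixed = c(pattern = FALSE, subject = TRUE))
    hits <- data.frame(position = BiocGenerics::start(fwd),
                       strand = rep("+", length(fwd)),
                       score = rep(NA_real_, length(fwd)),
                       stringsAsFactors = FALSE)
    if (both_strands) {
      rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                      sequence,
                                      fixed = c(pattern = FALSE, subject = TRUE))
      hits <- rbind(hits,
                    data.frame(position = BiocGenerics::start(rev),
                               strand = rep("-", length(rev)),
                               score = rep(NA_real_, length(rev)),
                               stringsAsFactors = FALSE))
    }
  } else {
    lo <- .pwm_logodds(motif$pwm)
    max_score <- sum(apply(lo, 2, max))
    cutoff <- motif$threshold * max_score
    codes <- .dna_codes(as.character(sequence))
    s_fwd <- .pwm_scores(codes, lo)
    i <- which(s_fwd >= cutoff)
    hits <- data.frame(position = i, strand = rep("+", length(i)),
                       score = s_fwd[i], stringsAsFactors = FALSE)
    if (both_strands) {
      lo_rc <- lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
      s_rev <- .pwm_scores(codes, lo_rc)
      i <- which(s_rev >= cutoff)
      hits <- rbind(hits, data.frame(position = i, strand = rep("-", length(i)),
                                     score = s_rev[i], stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

# carrier status (>= 1 hit) for every sequence of a set; vectorized in
# consensus mode, per-sequence scoring in PWM mode
.carrier_status <- function(promoters, motif, both_strands = TRUE) {
  if (motif$mode == "consensus") {
    pat <- Biostrings::DNAString(motif$consensus)
    n <- Biostrings::vcountPattern(pat, promoters,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    if (both_strands)
      n <- n + Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                         promoters,
                                         fixed = c(pattern = FALSE, subject = TRUE))
    n > 0
  } else {
    vapply(seq_along(promoters),
           function(i) nrow(scan_motif(promoters[[i]], motif, both_strands)) > 0,
           logical(1))
  }
}

#' Carrier proportion of a gene set
#'
#' Scans the promoter of every gene in the set; a gene is a carrier when its
#' promoter holds at least one motif occurrence.
#'
#' @param gene_set character vector of gene IDs.
#' @param promoters named [Biostrings::DNAStringSet] containing a promoter
#'   for every set member.
#' @param motif a [motif_model].
#' @param both_strands scan both strands (default TRUE).
#' @param name label for the report.
#' @return An object of class `carrier_report`: list with `name`,
#'   `n_genes`, `n_carriers`, `proportion`, and `hits` (per-gene data.frame
#'   of positions and strands).
#' @export
carrier_proportion <- function(gene_set, promoters, motif,
                               both_strands = TRUE, name = "set") {
  gene_set <- as.character(gene_set)
  if (length(gene_set) == 0) stop("carrier_proportion: empty gene set")
  missing <- setdiff(gene_set, names(promoters))
  if (length(missing) > 0)
    stop("carrier_proportion: missing promoter for ",
         paste(utils::head(missing, 5), collapse = ", "))
  hits <- lapply(gene_set, function(g) {
    h <- scan_motif(promoters[[g]], motif, both_strands)
    if (nrow(h) > 0) cbind(id = g, h, stringsAsFactors = FALSE) else NULL
  })
  hits <- do.call(rbind, hits)
  carriers <- if (is.null(hits)) character(0) else unique(hits$id)
  structure(list(name = name, n_genes = length(gene_set),
                 n_carriers = length(carriers),
                 proportion = length(carriers) / length(gene_set),
                 carriers = carriers, hits = hits),
            class = "carrier_report")
}

#' @export
print.carrier_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d promoters carry the motif (%.1f%%)\n",
              x$name, x$n_carriers, x$n_genes, 100 * x$proportion))
  invisible(x)
}

#' Random-gene resampling test of motif-carrier enrichment
#'
#' Null distribution of the carrier proportion for a gene set of the
#' observed size: each draw samples that many genes without replacement
#' from the full promoter universe and records its carrier proportion. The
#' empirical p-value uses the add-one correction
#' p = (1 + #\{draws >= observed\}) / (1 + n_draws), so it can never be zero
#' and its floor is 1 / (n_draws + 1). Universe carrier status is computed
#' once, so draws are cheap.
#'
#' @param observed a `carrier_report` from [carrier_proportion], or a list
#'   with `n_genes` and `proportion`.
#' @param promoters named [Biostrings::DNAStringSet]: the full promoter
#'   universe.
#' @param motif a [motif_model].
#' @param n_draws number of resampling draws (default 10,000).
#' @param seed integer random seed (deterministic result for a fixed seed).
#' @param both_strands scan both strands (default TRUE).
#' @return An object of class `resampling_result`: list with
#'   `observed_proportion`, `n_genes`, `n_draws`, `null_mean`, `null_sd`,
#'   `p`, `seed`, and `universe_rate` (genome-wide carrier rate).
#' @export
random_gene_test <- function(observed, promoters, motif, n_draws = 10000,
                             seed = 1, both_strands = TRUE) {
  if (n_draws < 1) stop("random_gene_test: n_draws must be >= 1")
  n_genes <- observed$n_genes
  if (n_genes > length(promoters))
    stop("random_gene_test: set larger than the promoter universe")
  status <- .carrier_status(promoters, motif, both_strands)
  set.seed(.op_seed(seed, "random_gene_test"))
  null_props <- vapply(seq_len(n_draws), function(i)
    mean(status[sample.int(length(status), n_genes)]), numeric(1))
  p <- (1 + sum(null_props >= observed$proportion)) / (1 + n_draws)
  structure(list(observed_proportion = observed$proportion,
                 n_genes = n_genes, n_draws = n_draws,
                 null_mean = mean(null_props), null_sd = stats::sd(null_props),
                 null_proportions = null_props,
                 universe_rate = mean(status), p = p, seed = seed),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf(paste0("resampling test: observed %.3f vs null %.4f +/- %.4f ",
                     "(%d draws of %d genes), p = %s\n"),
              x$observed_proportion, x$null_mean, x$null_sd, x$n_draws,
              x$n_genes, format_pvalue(x$p)))
  invisible(x)
}
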