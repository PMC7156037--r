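# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. Random streams are per-operation: each operation seeds its own
# stream as seed + a fixed operation index, so adding an operation never
# shifts the draws of another.

.op_index <- c(simulate_genome = 1L, simulate_bsa_pool = 2L,
               simulate_promoter_set = 3L, simulate_de_table = 4L,
               random_gene_test = 5L)

.op_seed <- function(seed, op) {
  stopifnot(op %in% names(.op_index))
  as.integer(seed) + .op_index[[op]]
}

#' Simulation parameters for a bulk-segregant F2 pool
#'
#' @param n_mutations number of EMS-induced sites drawn genome-wide (the
#'   forced causal site is added on top if not drawn).
#' @param causal list or vector `(chrom, pos)` of the causal mutation.
#' @param pool_size number of phenotype-selected F2 individuals in the pool.
#' @param mean_depth expected sequencing depth per site (Poisson mean).
#' @param seed integer random seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_mutations = 400, causal = list(chrom = "Chr1", pos = 15e6),
                       pool_size = 60, mean_depth = 50, seed = 1) {
  if (n_mutations < 1) stop("sim_params: n_mutations must be >= 1")
  if (pool_size < 1) stop("sim_params: pool_size must be >= 1")
  if (mean_depth <= 0) stop("sim_params: mean_depth must be > 0")
  causal <- as.list(causal)
  names(causal) <- c("chrom", "pos")
  causal$pos <- as.numeric(causal$pos)
  structure(list(n_mutations = as.integer(n_mutations), causal = causal,
                 pool_size = as.integer(pool_size), mean_depth = mean_depth,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate a genome landscape with annotated loci
#'
#' Builds a `genome_model` whose pericentromere occupies a central fraction
#' of each chromosome, and places genes and transposable elements (TEs) on
#' it. Genes are placed uniformly; TE placement is compartment-weighted so
#' that TE density inside pericentromeres is `te_peri_factor` times the arm
#' density, emulating the TE-dense heterochromatic pericentromeres of the
#' Arabidopsis karyotype.
#'
#' @param chr_lengths named numeric vector of chromosome lengths (bp).
#' @param peri_fraction fraction of each chromosome occupied by the central
#'   pericentromeric interval, in (0, 1).
#' @param n_genes,n_tes number of gene / TE loci to place.
#' @param te_peri_factor TE density inside pericentromeres relative to arms.
#' @param cm_per_mb recombination rate for the resulting `genome_model`.
#' @param seed integer random seed.
#' @return list with `genome` (a [genome_model]) and `loci` (data.frame with
#'   columns `id`, `chrom`, `start`, `end`, `class` in gene|TE).
#' @export
simulate_genome <- function(chr_lengths = stats::setNames(rep(30e6, 5), paste0("Chr", 1:5)),
                            peri_fraction = 0.3, n_genes = 2000, n_tes = 2000,
                            te_peri_factor = 4, cm_per_mb = 4, seed = 1) {
  if (length(chr_lengths) < 1) stop("simulate_genome: at least one chromosome")
  if (any(chr_lengths <= 0)) stop("simulate_genome: zero-length chromosome")
  if (peri_fraction <= 0 || peri_fraction >= 1)
    stop("simulate_genome: peri_fraction must lie in (0, 1)")
  if (is.null(names(chr_lengths)))
    names(chr_lengths) <- paste0("Chr", seq_along(chr_lengths))

  mid <- chr_lengths / 2
  half <- chr_lengths * peri_fraction / 2
  peri <- data.frame(chrom = names(chr_lengths),
                     start = floor(mid - half) + 1,
                     end = floor(mid + half),
                     stringsAsFactors = FALSE)
  genome <- genome_model(
    data.frame(name = names(chr_lengths), length = as.numeric(chr_lengths),
               stringsAsFactors = FALSE),
    pericentromere = peri, cm_per_mb = cm_per_mb
  )

  set.seed(.op_seed(seed, "simulate_genome"))
  place_uniform <- function(n, len_min, len_max) {
    chrom <- sample(names(chr_lengths), n, replace = TRUE,
                    prob = chr_lengths / sum(chr_lengths))
    len <- floor(stats::runif(n, len_min, len_max))
    mid <- floor(stats::runif(n, 1, chr_lengths[chrom] + 1))
    data.frame(chrom = chrom, mid = mid, len = len, stringsAsFactors = FALSE)
  }
  # TEs: pick compartment with probability proportional to density * span,
  # then a uniform midpoint within that compartment
  peri_len <- peri$end - peri$start + 1
  arm_len <- chr_lengths - peri_len
  w_peri <- te_peri_factor * sum(peri_len)
  w_arm <- sum(arm_len)
  in_peri <- stats::runif(n_tes) < w_peri / (w_peri + w_arm)
  te_chrom <- character(n_tes); te_mid <- numeric(n_tes)
  n_in <- sum(in_peri)
  if (n_in > 0) {
    ch <- sample(peri$chrom, n_in, replace = TRUE, prob = peri_len / sum(peri_len))
    i <- match(ch, peri$chrom)
    te_chrom[in_peri] <- ch
    te_mid[in_peri] <- floor(stats::runif(n_in, peri$start[i], peri$end[i] + 1))
  }
  if (n_tes - n_in > 0) {
    ch <- sample(names(chr_lengths), n_tes - n_in, replace = TRUE,
                 prob = arm_len / sum(arm_len))
    i <- match(ch, peri$chrom)
    # uniform over the two arms: draw on the arm length then skip the peri block
    u <- floor(stats::runif(n_tes - n_in, 1, arm_len[ch] + 1))
    pos <- ifelse(u < peri$start[i], u, u + peri_len[i])
    te_chrom[!in_peri] <- ch
    te_mid[!in_peri] <- pos
  }
  te_len <- floor(stats::runif(n_tes, 300, 3000))
  genes <- place_uniform(n_genes, 500, 4000)

  clamp <- function(chrom, mid, len) {
    start <- pmax(1, mid - floor(len / 2))
    end <- pmin(chr_lengths[chrom], start + len - 1)
    data.frame(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
               stringsAsFactors = FALSE)
  }
  g <- clamp(genes$chrom, genes$mid, genes$len)
  t <- clamp(te_chrom, te_mid, te_len)
  loci <- rbind(
    cbind(id = sprintf("GENE%05d", seq_len(n_genes)), g, class = "gene"),
    cbind(id = sprintf("TE%05d", seq_len(n_tes)), t, class = "TE")
  )
  rownames(loci) <- NULL
  list(genome = genome, loci = loci)
}

#' Simulate a sequenced bulk-segregant F2 pool
#'
#' Emulates the mapping population of an EMS forward screen: a homozygous
#' mutagenized line crossed to wild type, F2 individuals selected for the
#' mutant phenotype (hence homozygous at the causal locus), pooled and
#' sequenced. EMS sites are drawn uniformly over the genome and always obey
#' the EMS spectrum (ref G -> alt A, or ref C -> alt T). For a site at
#' genetic distance d Morgans from the causal locus (Haldane map), each of
#' the 2 * pool_size sampled gametes carries the mutant allele with
#' probability 1 - r(d); sites on other chromosomes segregate freely (1/2).
#' Read depth is Poisson(mean_depth) and alternate reads are Binomial(depth,
#' pooled allele frequency).
#'
#' @param genome a [genome_model].
#' @param params a [sim_params].
#' @param recomb a [recomb_model]; defaults to the genome's `cm_per_mb`.
#' @param sites optional data.frame (`chrom`, `pos`) of marker positions to
#'   simulate instead of drawing `n_mutations` uniform sites; useful for
#'   placing markers at chosen genetic distances from the causal locus.
#' @return data.frame of variant records: `chrom`, `pos`, `ref`, `alt`,
#'   `alt_depth`, `total_depth`, `allele_freq`, plus ground-truth columns
#'   `true_freq` (pooled allele frequency in the sampled gametes) and
#'   `is_causal`. Sorted by (chrom, pos) in genome order.
#' @export
simulate_bsa_pool <- function(genome, params, recomb = recomb_model(genome$cm_per_mb),
                              sites = NULL) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "sim_params"),
            inherits(recomb, "recomb_model"))
  if (!(params$causal$chrom %in% genome$chromosomes$name))
    stop("simulate_bsa_pool: causal chromosome not in genome")
  if (params$causal$pos < 1 ||
      params$causal$pos > chrom_length(genome, params$causal$chrom))
    stop("simulate_bsa_pool: causal position outside its chromosome")
  if (params$mean_depth <= 0) stop("simulate_bsa_pool: mean_depth must be > 0")

  set.seed(.op_seed(params$seed, "simulate_bsa_pool"))
  chrn <- genome$chromosomes$name
  chrl <- genome$chromosomes$length
  if (is.null(sites)) {
    n <- params$n_mutations
    chrom <- sample(chrn, n, replace = TRUE, prob = chrl / sum(chrl))
    pos <- floor(stats::runif(n, 1, chrl[match(chrom, chrn)] + 1))
  } else {
    chrom <- as.character(sites$chrom)
    pos <- as.numeric(sites$pos)
    if (!all(chrom %in% chrn))
      stop("simulate_bsa_pool: site on unknown chromosome")
  }
  dup <- chrom == params$causal$chrom & pos == params$causal$pos
  chrom <- c(chrom[!dup], params$causal$chrom)
  pos <- c(pos[!dup], params$causal$pos)
  is_causal <- c(rep(FALSE, sum(!dup)), TRUE)

  ems_ref <- sample(c("G", "C"), length(pos), replace = TRUE)
  ref <- ems_ref
  alt <- ifelse(ref == "G", "A", "T")

  linked <- chrom == params$causal$chrom
  p_gamete <- rep(0.5, length(pos))
  p_gamete[linked] <- 1 - recomb_fraction(
    genetic_distance(recomb, abs(pos[linked] - params$causal$pos)))
  gametes <- 2L * params$pool_size
  mut <- stats::rbinom(length(pos), gametes, p_gamete)
  mut[is_causal] <- gametes  # selection: causal homozygous in every individual
  true_freq <- mut / gametes

  dp <- stats::rpois(length(pos), params$mean_depth)
  ad <- stats::rbinom(length(pos), dp, true_freq)
  af <- ifelse(dp > 0, ad / dp, 0)

  v <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                  alt_depth = ad, total_depth = dp, allele_freq = af,
                  true_freq = true_freq, is_causal = is_causal,
                  stringsAsFactors = FALSE)
  v <- v[order(match(v$chrom, chrn), v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Simulate promoter sets with an embedded motif
#'
#' Generates i.i.d. random promoter sequences for a background set and a
#' target set. With probability `background_rate` (resp. `target_rate`) a
#' promoter carries one embedded occurrence of the motif consensus at a
#' uniform position, on a random strand. The returned truth table records
#' carrier status, position and strand of every embedded occurrence.
#'
#' @param n_background,n_target number of promoters in each set.
#' @param motif a [motif_model] (its consensus is embedded) or an IUPAC
#'   consensus string; ambiguity codes are resolved uniformly per embedding.
#' @param background_rate,target_rate embedding probabilities in \[0, 1\].
#' @param promoter_length promoter length in bp (>= motif length).
#' @param gc GC content of the random background sequence.
#' @param seed integer random seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet], names are
#'   locus IDs) and `truth` (data.frame `id`, `set`, `carrier`, `pos`,
#'   `strand`; `pos` is the forward-strand start of the embedded occurrence).
#' @export
simulate_promoter_set <- function(n_background, n_target, motif,
                                  background_rate, target_rate,
                                  promoter_length = 1000, gc = 0.5, seed = 1) {
  cons <- if (inherits(motif, "motif_model")) motif_consensus(motif) else toupper(motif)
  k <- nchar(cons)
  if (k < 1) stop("simulate_promoter_set: empty motif")
  if (promoter_length < k)
    stop("simulate_promoter_set: motif longer than promoter")
  if (any(c(background_rate, target_rate) < 0 | c(background_rate, target_rate) > 1))
    stop("simulate_promoter_set: rates must lie in [0, 1]")

  set.seed(.op_seed(seed, "simulate_promoter_set"))
  n <- n_background + n_target
  ids <- c(sprintf("BG%05d", seq_len(n_background)),
           sprintf("TG%05d", seq_len(n_target)))
  setlab <- rep(c("background", "target"), c(n_background, n_target))
  rate <- rep(c(background_rate, target_rate), c(n_background, n_target))
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  carrier <- stats::runif(n) < rate
  pos <- ifelse(carrier,
                floor(stats::runif(n, 1, promoter_length - k + 2)), NA_real_)
  strand <- ifelse(carrier, ifelse(stats::runif(n) < 0.5, "+", "-"), NA_character_)

  iupac <- Biostrings::IUPAC_CODE_MAP
  resolve <- function() {
    letters <- strsplit(cons, "")[[1]]
    paste(vapply(letters, function(l) {
      opts <- strsplit(iupac[[l]], "")[[1]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(names(base_prob), promoter_length, replace = TRUE, prob = base_prob)
    if (carrier[i]) {
      ins <- resolve()
      if (strand[i] == "-")
        ins <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ins)))
      s[pos[i]:(pos[i] + k - 1)] <- strsplit(ins, "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))

  sequences <- Biostrings::DNAStringSet(seqs)
  names(sequences) <- ids
  truth <- data.frame(id = ids, set = setlab, carrier = carrier,
                      pos = pos, strand = strand, stringsAsFactors = FALSE)
  list(sequences = sequences, truth = truth)
}

#' Simulate a differential-expression table with planted up/down calls
#'
#' Constructs a (locus, log2FC, padj) table in which exactly `n_up` rows pass
#' the up-regulation thresholds (log2FC >= 2 and padj < 0.01), exactly
#' `n_down` pass the down-regulation thresholds (log2FC <= -2, padj < 0.01),
#' and every other row fails at least one threshold.
#'
#' @param n_loci total number of rows.
#' @param n_up,n_down planted significant counts; `n_up + n_down <= n_loci`.
#' @param thresholds a [de_thresholds] defining the planted semantics.
#' @param seed integer random seed.
#' @return data.frame `locus`, `log2FC`, `padj` with attribute `truth`
#'   (list of planted `up` and `down` locus IDs).
#' @export
simulate_de_table <- function(n_loci, n_up, n_down,
                              thresholds = de_thresholds(), seed = 1) {
  if (any(c(n_loci, n_up, n_down) < 0))
    stop("simulate_de_table: negative counts")
  if (n_up + n_down > n_loci)
    stop("simulate_de_table: n_up + n_down exceeds n_loci")
  set.seed(.op_seed(seed, "simulate_de_table"))
  locus <- sprintf("LOC%05d", seq_len(n_loci))
  status <- rep(c("up", "down", "null"),
                c(n_up, n_down, n_loci - n_up - n_down))
  log2fc <- numeric(n_loci); padj <- numeric(n_loci)
  up <- status == "up"; dn <- status == "down"; nl <- status == "null"
  log2fc[up] <- stats::runif(sum(up), thresholds$log2fc_up, thresholds$log2fc_up + 6)
  log2fc[dn] <- stats::runif(sum(dn), thresholds$log2fc_down - 6, thresholds$log2fc_down)
  padj[up | dn] <- stats::runif(sum(up) + sum(dn), 0, thresholds$padj_max * 0.99)
  # null rows: either a sub-threshold fold change, or a non-significant padj
  log2fc[nl] <- stats::runif(sum(nl), thresholds$log2fc_down - 2, thresholds$log2fc_up + 2)
  padj[nl] <- ifelse(log2fc[nl] >= thresholds$log2fc_up |
                       log2fc[nl] <= thresholds$log2fc_down,
                     stats::runif(sum(nl), thresholds$padj_max, 1),
                     stats::runif(sum(nl), 0, 1))
  ord <- sample.int(n_loci)
  tab <- data.frame(locus = locus, log2FC = log2fc[ord], padj = padj[ord],
                    stringsAsFactors = FALSE)
  attr(tab, "truth") <- list(up = locus[match(which(up), ord)],
                             down = locus[match(which(dn), ord)])
  tab
}
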