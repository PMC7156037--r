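# Promoter extraction, exact motif scanning, carrier proportions and the
# random-gene resampling null.

test_that("promoters are anchored at the translation start on either strand", {
  chr <- paste(rep("ACGT", 2500), collapse = "")  # 10 kb
  genome_seq <- Biostrings::DNAStringSet(c(Chr1 = chr))

  plus <- data.frame(id = "gp", chrom = "Chr1", strand = "+", tstart = 5001)
  prom <- extract_promoters(plus, genome_seq, length = 1000)
  expect_equal(unname(as.character(prom)), substr(chr, 4001, 5000))
  expect_equal(Biostrings::width(prom), 1000)

  minus <- data.frame(id = "gm", chrom = "Chr1", strand = "-", tstart = 5000)
  promm <- extract_promoters(minus, genome_seq, length = 1000)
  expect_equal(unname(as.character(promm)),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(substr(chr, 5001, 6000)))))

  near_edge <- data.frame(id = "ge", chrom = "Chr1", strand = "+", tstart = 400)
  expect_warning(prome <- extract_promoters(near_edge, genome_seq, 1000),
                 "truncated")
  expect_equal(Biostrings::width(prome), 399)

  nostrand <- data.frame(id = "gx", chrom = "Chr1", strand = NA, tstart = 5001)
  expect_error(extract_promoters(nostrand, genome_seq), "strand")
})

test_that("consensus scanning finds planted occurrences exactly", {
  m <- motif_model(consensus = "TGACGT")
  s <- paste0(strrep("A", 20), "TGACGT", strrep("A", 20))
  hits <- scan_motif(s, m)
  expect_equal(hits$position, 21)
  expect_equal(hits$strand, "+")

  rc <- paste0(strrep("A", 10), "ACGTCA", strrep("A", 30))
  hits <- scan_motif(rc, m)
  expect_equal(hits$position, 11)
  expect_equal(hits$strand, "-")

  # N never matches, even where the surrounding bases fit
  withn <- paste0(strrep("A", 20), "TGANGT", strrep("A", 20))
  expect_equal(nrow(scan_motif(withn, m)), 0)

  # IUPAC ambiguity in the motif matches its allowed letters only
  iupac <- motif_model(consensus = "TGASGT")  # S = C or G
  expect_equal(scan_motif(paste0("AAAA", "TGACGT", "AAAA"), iupac,
                          both_strands = FALSE)$position, 5)
  expect_equal(scan_motif(paste0("AAAA", "TGAGGT", "AAAA"), iupac,
                          both_strands = FALSE)$position, 5)
  expect_equal(nrow(scan_motif(paste0("AAAA", "TGATGT", "AAAA"), iupac,
                               both_strands = FALSE)), 0)
})

test_that("planted occurrences across a promoter set are recovered with strands", {
  m <- motif_model(consensus = "TGACGTCATCGA")
  ps <- simulate_promoter_set(0, 200, m, 0, target_rate = 1,
                              promoter_length = 400, seed = 6)
  for (i in seq_len(200)) {
    tr <- ps$truth[i, ]
    hits <- scan_motif(ps$sequences[[tr$id]], m)
    found <- hits[hits$position == tr$pos & hits$strand == tr$strand, ]
    expect_equal(nrow(found), 1)
  }
})

test_that("PWM mode at threshold 1 reproduces consensus carrier labels", {
  set.seed(15)
  # sharply peaked PWM without column ties
  L <- 8
  pwm <- sapply(seq_len(L), function(j) {
    v <- rep(0.02, 4); v[sample(4, 1)] <- 0.94; v
  })
  rownames(pwm) <- c("A", "C", "G", "T")
  m_pwm <- motif_model(pwm = pwm, threshold = 1)
  m_cons <- motif_model(consensus = motif_consensus(m_pwm))

  ps <- simulate_promoter_set(150, 50, m_cons, 0.3, 0.9,
                              promoter_length = 300, seed = 8)
  lab_pwm <- vapply(seq_along(ps$sequences), function(i)
    nrow(scan_motif(ps$sequences[[i]], m_pwm)) > 0, logical(1))
  lab_cons <- vapply(seq_along(ps$sequences), function(i)
    nrow(scan_motif(ps$sequences[[i]], m_cons)) > 0, logical(1))
  expect_identical(lab_pwm, lab_cons)

  # and the hit positions coincide too
  i <- which(lab_cons)[1]
  expect_equal(scan_motif(ps$sequences[[i]], m_pwm)$position,
               scan_motif(ps$sequences[[i]], m_cons)$position)
})

test_that("PWM thresholds below 1 admit near-consensus words", {
  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.1, 0.7, 0.1, 0.1,
                  0.1, 0.1, 0.7, 0.1,
                  0.1, 0.1, 0.1, 0.7), nrow = 4)
  rownames(pwm) <- c("A", "C", "G", "T")
  m <- motif_model(pwm = pwm, threshold = 0.5)
  # one mismatch against consensus ACGT still scores above half-max
  expect_gt(nrow(scan_motif("AAAACGGTAAAA", m, both_strands = FALSE)), 0)
  m1 <- motif_model(pwm = pwm, threshold = 1)
  expect_equal(nrow(scan_motif("AAAACGGTAAAA", m1, both_strands = FALSE)), 0)
  expect_equal(scan_motif("AAAACGTAAAA", m1, both_strands = FALSE)$position, 4)
})

test_that("carrier proportions count genes with at least one hit", {
  m <- motif_model(consensus = "TGACGTCATCGA")
  ps <- simulate_promoter_set(0, 26, m, 0, 1, promoter_length = 200, seed = 12)
  ids <- ps$truth$id
  # remove the motif from one promoter: 25 of 26 carriers
  seqs <- as.character(ps$sequences)
  seqs[ids[3]] <- strrep("A", 200)
  proms <- Biostrings::DNAStringSet(seqs)
  rep26 <- carrier_proportion(ids, proms, m, name = "down")
  expect_equal(rep26$n_carriers, 25)
  expect_equal(rep26$proportion, 25 / 26)
  expect_equal(round(100 * rep26$proportion), 96)

  all_carrier <- carrier_proportion(ids[-3], proms, m)
  expect_equal(all_carrier$proportion, 1)

  expect_error(carrier_proportion(character(0), proms, m), "empty gene set")
  expect_error(carrier_proportion(c(ids, "missing"), proms, m), "missing")
})

test_that("the resampling null is calibrated and deterministic", {
  m <- motif_model(consensus = "TGACGTCATCGA")
  ps <- simulate_promoter_set(1500, 0, m, 0.2, 0, promoter_length = 300,
                              seed = 14)
  universe <- ps$sequences
  obs <- list(n_genes = 26, proportion = 25 / 26)
  rt <- random_gene_test(obs, universe, m, n_draws = 2000, seed = 5)
  expect_equal(rt$p, 1 / 2001)  # nothing in the null reaches 25/26
  # null mean tracks the realized universe carrier rate
  expect_lt(abs(rt$null_mean - rt$universe_rate),
            3 * rt$null_sd / sqrt(rt$n_draws))

  rt2 <- random_gene_test(obs, universe, m, n_draws = 2000, seed = 5)
  expect_identical(rt$null_mean, rt2$null_mean)
  expect_identical(rt$p, rt2$p)

  # observed at the background rate sits mid-null; observed 0 is never exceeded
  mid <- random_gene_test(list(n_genes = 26, proportion = rt$universe_rate),
                          universe, m, n_draws = 2000, seed = 5)
  expect_gt(mid$p, 0.2)
  null_obs <- random_gene_test(list(n_genes = 26, proportion = 0),
                               universe, m, n_draws = 500, seed = 5)
  expect_equal(null_obs$p, 1)

  # p is monotone non-increasing in the observed carrier count
  ps_count <- vapply(c(5, 10, 15, 20, 25), function(k)
    random_gene_test(list(n_genes = 26, proportion = k / 26), universe, m,
                     n_draws = 500, seed = 5)$p, numeric(1))
  expect_true(all(diff(ps_count) <= 0))

  expect_error(random_gene_test(obs, universe, m, n_draws = 0), "n_draws")
})

test_that("MEME minimal format motifs round-trip through the reader", {
  tmp <- tempfile(fileext = ".meme")
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF DOWN1 synthetic",
    "letter-probability matrix: alength= 4 w= 4 nsites= 20 E= 1e-5",
    " 0.900000 0.033333 0.033333 0.033334",
    " 0.033333 0.900000 0.033333 0.033334",
    " 0.033333 0.033333 0.900000 0.033334",
    " 0.033334 0.033333 0.033333 0.900000"
  ), tmp)
  m <- read_meme_motif(tmp)
  expect_s3_class(m, "motif_model")
  expect_equal(m$mode, "pwm")
  expect_equal(ncol(m$pwm), 4)
  expect_equal(motif_consensus(m), "ACGT")
  expect_equal(colSums(m$pwm), rep(1, 4), tolerance = 1e-12)
  expect_error(read_meme_motif(tmp, name = "NOPE"), "not found")
})
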