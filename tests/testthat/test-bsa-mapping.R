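# Mapping scan: spectrum filter, zygosity bands, window partition, interval
# calling and the composed pipeline on simulated ground truth.

test_that("EMS filter keeps exactly the G:C -> A:T spectrum", {
  v <- data.frame(chrom = "Chr1", pos = 1:5,
                  ref = c("G", "C", "A", "T", "G"),
                  alt = c("A", "T", "G", "C", "C"),
                  stringsAsFactors = FALSE)
  kept <- ems_filter(v)
  expect_equal(kept$pos, c(1, 2))
  expect_equal(kept$ref, c("G", "C"))

  withindel <- rbind(v, data.frame(chrom = "Chr1", pos = 6, ref = "GA", alt = "A"))
  expect_warning(kept2 <- ems_filter(withindel), "rejected")
  expect_equal(kept2$pos, c(1, 2))
})

test_that("zygosity bands follow the inclusive threshold semantics exactly", {
  cases <- c("0.8" = "homozygous", "0.45" = "heterozygous",
             "0.55" = "heterozygous", "0.7999" = "discarded",
             "0.5501" = "discarded", "0.4499" = "discarded",
             "0.85" = "homozygous", "0.5" = "heterozygous",
             "0.7" = "discarded", "1" = "homozygous", "0" = "discarded")
  got <- classify_zygosity(as.numeric(names(cases)))
  expect_equal(as.character(got), unname(cases))

  expect_error(classify_zygosity(1.2), "\\[0, 1\\]")
  expect_error(classify_zygosity(-0.1), "\\[0, 1\\]")
  expect_error(zygosity_thresholds(het_min = 0.6, het_max = 0.5), "het_min")
})

test_that("window scan tiles chromosomes and scores the stated ratio", {
  gm <- genome_model(data.frame(name = "Chr1", length = 1.5e6))
  v <- data.frame(chrom = "Chr1", pos = c(1e5, 2e5, 1.5e5, 6e5),
                  zygosity = c("homozygous", "homozygous", "heterozygous",
                               "homozygous"))
  scan <- window_ratio_scan(v, gm, window_size = 5e5)
  expect_equal(nrow(scan), 3)
  expect_equal(scan$start, c(1, 5e5 + 1, 1e6 + 1))
  expect_equal(scan$end, c(5e5, 1e6, 1.5e6))
  expect_equal(scan$n_hom, c(2, 1, 0))
  expect_equal(scan$n_het, c(1, 0, 0))
  expect_equal(scan$ratio, c(2, 1, 0))

  allhet <- v; allhet$zygosity <- "heterozygous"
  expect_true(max(window_ratio_scan(allhet, gm, 5e5)$ratio) < 1)

  toofar <- rbind(v, data.frame(chrom = "Chr1", pos = 2e6, zygosity = "homozygous"))
  expect_error(window_ratio_scan(toofar, gm, 5e5), "Chr1:2e\\+06|Chr1:2000000")
})

test_that("every classified variant lands in exactly one window", {
  gm <- tiny_genome()
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:80, 1)
    chrom <- sample(c("Chr1", "Chr2"), n, replace = TRUE)
    v <- data.frame(
      chrom = chrom,
      pos = floor(runif(n, 1, chrom_length(gm, chrom) + 1)),
      zygosity = sample(c("homozygous", "heterozygous", "discarded"), n,
                        replace = TRUE)
    )
    scan <- window_ratio_scan(v, gm, window_size = 3e5)
    expect_equal(sum(scan$n_hom + scan$n_het), sum(v$zygosity != "discarded"))
    # window tiling covers each chromosome without gap or overlap
    for (ch in c("Chr1", "Chr2")) {
      sub <- scan[scan$chrom == ch, ]
      expect_equal(sub$start, c(1, head(sub$end, -1) + 1))
      expect_equal(sub$end[nrow(sub)], chrom_length(gm, ch))
    }
  }
})

test_that("interval calling applies the tau-of-peak run rule on raw ratios", {
  gm <- genome_model(data.frame(name = "Chr1", length = 3e6))
  scan <- data.frame(chrom = "Chr1",
                     start = (0:5) * 5e5 + 1, end = (1:6) * 5e5,
                     n_hom = c(1, 1, 5, 6, 5, 1), n_het = rep(1, 6),
                     ratio = c(1, 1, 5, 6, 5, 1))
  int <- call_linkage_interval(scan, tau = 0.5, smooth = 1)
  expect_equal(int$start, 2 * 5e5 + 1)   # windows 3-5
  expect_equal(int$end, 5 * 5e5)
  expect_equal(int$peak_start, 3 * 5e5 + 1)
  expect_equal(int$peak_ratio, 6)

  single <- scan; single$ratio <- c(0, 0, 0, 4, 0, 0)
  single$n_hom <- c(0, 0, 0, 4, 0, 0)
  int <- call_linkage_interval(single, tau = 0.5, smooth = 1)
  expect_equal(c(int$start, int$end), c(3 * 5e5 + 1, 4 * 5e5))

  flat <- scan; flat$ratio <- rep(2, 6); flat$n_hom <- rep(2, 6)
  int <- call_linkage_interval(flat, tau = 0.5, smooth = 1)
  expect_equal(c(int$start, int$end), c(1, 3e6))  # ties break to the earliest

  zero <- scan; zero$ratio <- 0; zero$n_hom <- 0
  expect_error(call_linkage_interval(zero), "no linkage signal")
})

test_that("the composed pipeline recovers a simulated causal locus", {
  gm <- study_genome()
  v <- simulate_bsa_pool(gm, sim_params(seed = 8))
  tmp <- tempfile(fileext = ".vcf")
  write_bsa_vcf(v, gm, tmp)
  res <- run_mapping(tmp, gm, outdir = td <- tempfile())
  expect_s3_class(res$interval, "linkage_interval")
  expect_equal(res$interval$chrom, "Chr1")
  expect_true(res$interval$start <= 15e6 && 15e6 <= res$interval$end)
  expect_true(file.exists(file.path(td, "windows.bed")))
  expect_true(file.exists(file.path(td, "interval.bed")))
  # BED of the interval round-trips to the same coordinates
  bed <- read_bed(file.path(td, "interval.bed"))
  expect_equal(c(bed$start, bed$end), c(res$interval$start, res$interval$end))

  empty <- tempfile(fileext = ".vcf")
  write_bsa_vcf(v[0, ], gm, empty)
  expect_error(run_mapping(empty, gm), "no variants")
})

test_that("an unselected pool yields no homozygous-enriched peak", {
  gm <- study_genome()
  set.seed(31)
  n <- 400
  chrom <- sample(paste0("Chr", 1:5), n, replace = TRUE)
  pos <- floor(runif(n, 1, 30e6))
  f <- rbinom(n, 120, 0.5) / 120
  dp <- rpois(n, 50)
  af <- ifelse(dp > 0, rbinom(n, dp, f) / dp, 0)
  v <- data.frame(chrom = chrom, pos = pos, ref = "G", alt = "A",
                  allele_freq = af,
                  zygosity = classify_zygosity(af))
  scan <- window_ratio_scan(v, gm)
  expect_lt(max(scan$ratio), 2)  # nothing resembling a linkage peak
})

test_that("window ratio decays with genetic distance from the causal locus", {
  gm <- study_genome()
  reps <- 60
  acc <- NULL
  for (s in seq_len(reps)) {
    v <- simulate_bsa_pool(gm, sim_params(n_mutations = 400, seed = 5000 + s))
    v$zygosity <- classify_zygosity(v$allele_freq)
    scan <- window_ratio_scan(v[v$chrom == "Chr1", ], gm)
    scan <- scan[scan$chrom == "Chr1", ]
    acc <- if (is.null(acc)) scan$ratio else acc + scan$ratio
  }
  mean_ratio <- acc / reps
  dist <- abs((gm$chromosomes$length[1] / 2) - (seq_along(mean_ratio) - 0.5) * 5e5)
  ct <- suppressWarnings(stats::cor.test(dist, mean_ratio, method = "spearman",
                                         alternative = "less"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
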