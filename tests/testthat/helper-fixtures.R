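# Shared fixtures built in code: a small two-chromosome genome and a
# convenience builder for variant tables.

tiny_genome <- function() {
  genome_model(
    data.frame(name = c("Chr1", "Chr2"), length = c(3e6, 2e6)),
    pericentromere = data.frame(chrom = c("Chr1", "Chr2"),
                                start = c(1.2e6, 0.8e6),
                                end = c(1.8e6, 1.2e6)),
    cm_per_mb = 4
  )
}

variant_table <- function(chrom, pos, ref = "G", alt = "A", freq = 0.5) {
  n <- max(length(chrom), length(pos))
  data.frame(chrom = rep_len(chrom, n), pos = rep_len(pos, n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             allele_freq = rep_len(freq, n), stringsAsFactors = FALSE)
}

# default study-scale simulation conditions used across tests
study_genome <- function() {
  gm <- genome_model(
    data.frame(name = paste0("Chr", 1:5), length = rep(30e6, 5)),
    pericentromere = data.frame(chrom = paste0("Chr", 1:5),
                                start = rep(10.5e6, 5), end = rep(19.5e6, 5)),
    cm_per_mb = 4
  )
  gm
}
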