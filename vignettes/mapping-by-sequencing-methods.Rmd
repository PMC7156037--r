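---
title: "Methods: bulk-segregant mapping-by-sequencing and downstream enrichment statistics"
author: "bsamapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulk-segregant mapping-by-sequencing and downstream enrichment statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`bsamapr` implements the computational core of an EMS forward-genetic screen
in *Arabidopsis thaliana*: locating a causal point mutation by sequencing a
pooled, phenotype-selected F2 population, and the battery of enrichment
statistics used once misregulated locus sets are in hand. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where the procedure was genuinely open.

```{r setup}
library(bsamapr)
```

## The mapping model

An EMS-mutagenized line, homozygous for a recessive causal mutation, is
crossed to wild type; F2 individuals showing the mutant phenotype are pooled
and sequenced. Every F2 in the pool is homozygous mutant at the causal locus.
At a marker at genetic distance $d$ (Morgans) from it on the same chromosome,
each of the $2N$ sampled gametes carries the mutant-linked allele with
probability $1 - r(d)$, where the Haldane map function

$$r(d) = \tfrac{1}{2}\left(1 - e^{-2d}\right)$$

converts genetic distance to a recombination fraction. Markers on other
chromosomes assort independently (frequency $\tfrac12$). The pooled
alternate-allele frequency therefore decays from 1 at the causal site toward
0.5 with distance, and that decay is the mapping signal.

The scan itself follows the classic homozygosity-ratio recipe:

1. **EMS-spectrum filter** (`ems_filter`): EMS alkylates guanine, producing
   almost exclusively G:C→A:T transitions, so only records with ref G/alt A
   or ref C/alt T are candidate induced mutations.
2. **Zygosity call** (`classify_zygosity`): a variant is *homozygous* when
   its pooled frequency is ≥ 0.80 and *heterozygous* when it lies in
   [0.45, 0.55]; anything else is discarded. Boundaries are inclusive
   exactly as the inequality signs state; the bands deliberately leave a
   dead zone (0.55–0.80) where sampling noise makes the call unreliable.
3. **Window scan** (`window_ratio_scan`): non-overlapping 500-kb windows
   tile each chromosome; each window scores
   $\text{ratio} = n_\text{hom} / \max(n_\text{het}, 1)$. The floor of 1 in
   the denominator keeps the score finite where no heterozygous call
   landed; an empty window scores 0. Counts are not length-normalized — the
   terminal window of a chromosome may be shorter.
4. **Interval call** (`call_linkage_interval`): find the genome-wide
   maximum ratio and report the maximal run of contiguous windows around
   that peak whose ratios all reach $\tau \cdot \text{peak}$ (default
   $\tau = 0.5$). Ties at the peak break toward the earliest chromosome and
   smallest coordinate.

### Why the interval caller smooths counts

With a few hundred EMS sites over a ~150-Mb genome, a 500-kb window holds on
the order of one classified marker, so raw per-window ratios are extremely
noisy: the window containing the causal site is frequently not the maximum,
and the $\tau$-run collapses to the single peak window. We therefore pool
the hom/het counts in a centered running sum over `smooth` windows (default
11, a 5.5-Mb span at the default window size) before applying the same
peak/run rule. The default span was sized so that, at realistic densities of
a few EMS mutations per megabase, an evaluation point aggregates roughly ten
classified markers — enough for the ratio to be stable — while remaining
narrow relative to the homozygosity plateau itself, which spans several
megabases on either side of the causal locus (frequency stays above the 0.80
homozygous threshold out to $r \approx 0.2$, i.e. ±5–6 Mb at 4 cM/Mb).
`smooth = 1` disables pooling and reproduces the raw rule, which is also the
form used for the worked single-window examples in the tests. The reported
`peak_ratio` is the maximum smoothed ratio.

At the default study conditions (pool of 60, 50× depth, 400 EMS sites,
five 30-Mb chromosomes), the called interval spans ~11 Mb and contains the
causal position in ≥ 95% of seeded simulations; this is an honest
reflection of the resolution a first-pass 400-marker scan can deliver, not
a deficiency of the caller.

```{r mapping-example}
gm <- simulate_genome(seed = 7)
pool <- simulate_bsa_pool(gm$genome, sim_params(seed = 3))
res <- run_mapping(pool, gm$genome)
res$interval
```

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known ground
truth, so all stages are testable without external sequencing data.

* **Genome** (`simulate_genome`): five 30-Mb chromosomes by default, with a
  central pericentromere occupying 30% of each chromosome — a stylized
  Arabidopsis karyotype. Genes are placed uniformly; TE placement is
  weighted so pericentromeric TE density is 4× the arm density, mirroring
  the TE-dense heterochromatic pericentromeres of the real genome.
* **Pool** (`simulate_bsa_pool`): marker sites uniform over the genome;
  per-site mutant gametes Binomial$(2N, 1 - r(d))$; depth
  Poisson(`mean_depth`); alternate reads Binomial(depth, pooled frequency).
  Defaults — pool of 60 selected F2s, 50× mean depth, 400 EMS sites — are
  plausible round numbers for this kind of screen (the studies this models
  do not publish their pool sizes or depths). No sequencing-error model is
  applied: miscalled bases are exactly what the 0.45–0.55 and ≥ 0.80 bands
  are designed to tolerate, and an error model would add a parameter the
  downstream statistics never see.
* **Promoters** (`simulate_promoter_set`): i.i.d. uniform-composition
  sequences; with the stated probability one motif-consensus occurrence is
  embedded at a uniform position on a random strand, and the truth table
  records it. The default background carrier rate used throughout the
  tests, 12.46%, matches the genome-wide carrier fraction reported for the
  downregulated-promoter motif this module was built around.
* **DE tables** (`simulate_de_table`): exactly the requested numbers of
  rows pass the up/down thresholds; every other row fails at least one.

Random streams are per-operation (`seed + operation index`), so adding an
operation to a workflow never shifts the draws of another, and identical
seeds give byte-identical VCF/FASTA/TSV outputs.

What the generator does **not** emulate: linkage disequilibrium between
neighbouring markers within an individual (per-site gamete draws are
independent, which leaves marginal frequencies — the quantity the scan
uses — exactly correct but understates the covariance of nearby windows),
read-level errors, mapping artefacts, and non-uniform recombination
(a single genome-wide cM/Mb rate). Passing tests therefore validate the
statistical machinery, not robustness to alignment noise.

## Compartment enrichment

`classify_compartment` assigns each locus to *arm* or *pericentromeric* by
its midpoint — compartments partition the chromosome, so midpoint membership
gives each locus exactly one label. `chi2_enrichment` then compares the
observed split of a locus set against the genomic background proportions of
its class with the plain goodness-of-fit statistic
$\chi^2 = \sum (O - E)^2 / E$, df = 1, no continuity correction, and labels
significance `**` (p ≤ 0.01), `*` (p ≤ 0.05) or `n.s`.

`chromatin_state_fraction` reports the fraction of a set overlapping
heterochromatic chromatin states (states 8 and 9 of the nine-state
Arabidopsis segmentation, a proxy for DNA methylation/H3K9me2 targeting).
Because state segmentations are fragmented, membership here is by covered
fraction — a locus counts when ≥ 50% of its length lies in the requested
states — rather than by midpoint. Both conventions are parameters.
Pericentromere boundaries and state intervals are inputs (BED), since the
published segmentations are not reproduced here; the bundled synthetic
genome provides stand-ins for testing.

## Set overlap

`overlap_table` + `fisher_exact_upper` formalize Venn-diagram overlaps: with
universe size $N$, $|A| = K$, $|B| = n$ and overlap $a$, the one-sided
p-value is the hypergeometric upper tail $P(X \ge a)$ — enrichment is the
question being asked of such overlaps, so the one-sided test is the default
and the two-sided variant is a flag. The odds ratio is the sample odds
ratio $ad/bc$ (infinite when $bc = 0 < ad$). Text output floors p-values at
the conventional `< 2.2e-16`; stored values keep full precision. The
universe is always an explicit argument: overlap significance is meaningless
without one, and the right universe (all genes, all TEs, expressed genes) is
a scientific choice the caller must make.

## Promoter motifs and the resampling null

Promoters are the 1 kb upstream of the **translation start** (ATG), not the
TSS — the convention of the standard TAIR "upstream_1000_translation_start"
promoter sets that genome-wide carrier rates are computed against; the
anchor is a parameter for callers who prefer TSS-anchored windows. Minus-
strand promoters are reverse-complemented; edge-truncated promoters warn.

A motif is either an IUPAC consensus (exact matching, both strands, N never
matches) or a position weight matrix. PWM scoring is log2-odds against a
uniform background, and a window is a hit when its score reaches
`threshold` × the maximal achievable score. This "fraction of maximum"
rule is deliberately simple and makes threshold 1.0 exactly equivalent to
consensus matching (a tested invariant); it differs from the score-range
convention some scanners use, which is why the scanner is implemented here
rather than delegated. MEME minimal format is read directly
(`read_meme_motif`); the motif itself is always an input — motif
*discovery* is out of scope, and the bundled test motifs are synthetic
stand-ins, not any published matrix.

`random_gene_test` calibrates an observed carrier proportion against draws
of equally sized random gene sets (without replacement) from the full
promoter universe, with the add-one empirical p-value
$p = (1 + \#\{\text{draws} \ge \text{obs}\}) / (1 + n_\text{draws})$, whose
floor $1/(n_\text{draws}+1)$ is the honest limit of a resampling test.
Universe carrier status is computed once, so 10,000 draws cost seconds.

```{r motif-example}
m <- motif_model(consensus = "TGACGTCATCGA")
ps <- simulate_promoter_set(2000, 26, m, background_rate = 0.1246,
                            target_rate = 25 / 26, seed = 5)
cr <- carrier_proportion(ps$truth$id[ps$truth$set == "target"],
                         ps$sequences, m, name = "downregulated")
cr
random_gene_test(cr, ps$sequences[ps$truth$set == "background"], m,
                 n_draws = 2000, seed = 2)
```

## Expression utilities

* `de_filter`: up iff log2FC ≥ 2 **and** padj < 0.01; down iff log2FC ≤ −2
  and padj < 0.01. The fold-change bound is inclusive and the p bound
  strict, matching the usual statement of these thresholds.
* `ddct_relative_expression`: Ct values are averaged over replicates
  *before* differencing (ΔCt = target − housekeeping reference;
  ΔΔCt = sample − calibrator; fold = $2^{-\Delta\Delta Ct}$). Averaging
  first is a choice — published descriptions of the method rarely state the
  aggregation order — and guarantees the calibrator's self-fold is exactly 1.
* `nsaf`: the standard normalized spectral abundance factor,
  $\text{SAF}_i = \text{count}_i/\text{length}_i$ normalized to sum to 1 and
  scaled by $10^5$ (the "NSAFe5" convention). The formula is the standard
  spectral-count definition, adopted because the quantity is customarily
  reported under that name without a printed formula.

## Numerical and testing notes

* Coordinates are 1-based inclusive throughout; BED I/O converts to 0-based
  half-open at the file boundary (`rtracklayer`).
* Allele frequencies are recomputed from AD/DP on VCF input; the AF field
  is only a fallback, so rounding in the file never propagates.
* The chi-square and Fisher implementations are validated against
  independent oracles in the test suite (explicit $\sum(O-E)^2/E$ arithmetic
  and an exhaustive binomial-coefficient hypergeometric tail sum, plus
  `chisq.test`/`fisher.test` cross-checks) rather than being delegated to
  them, keeping the statistic definitions under this package's control.
* Simulation-based tests use fixed seeds and study-scale defaults
  (100 pools for recovery, 200 pools for the frequency law, 2,000 sets for
  type-I calibration, 10,000 resampling draws); tolerances are three
  standard errors of the quantity under test.

## Known limitations

* The interval caller assumes a single causal locus; two linked causal
  sites would merge into one interval.
* Marker draws are independent across sites within a pool, so inter-window
  noise correlation in real data is understated (see above).
* The compartment test treats loci as exchangeable points; it ignores locus
  length and local gene density.
* The resampling null conditions on the realized promoter universe; its
  mean tracks the *realized* carrier rate, which differs from the nominal
  embedding rate by binomial sampling error.
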