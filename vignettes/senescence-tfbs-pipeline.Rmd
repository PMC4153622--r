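---
title: "Methods: expression profiling and promoter TFBS enrichment in replicative senescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression profiling and promoter TFBS enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`senotf` implements the computational chain of a replicative-senescence
expression study on serially passaged human diploid fibroblasts, sampled at
three population-doubling (PD) levels with three biological replicates each.
The chain is:

1. **Differential expression (DE)** of each later PD level against the
   earliest (reference) level, at explicit fold-change and significance
   thresholds.
2. **Degenerate motif scanning**: exact (no-mismatch) matching of IUPAC
   transcription-factor binding motifs over fixed 1 kb upstream promoter
   windows, restricted to motifs with fewer than 1,000 concrete variants.
3. **Candidate-target calling** by a per-motif occurrence outlier rule
   (outside mean ± SD over all promoters).
4. **TF ranking** by how many candidate targets' expression correlates with
   the TF's own expression.
5. **Enrichment** of each motif's target promoters among DE-gene promoters
   versus all promoters (Fisher's exact test, BH across motifs).

Real array and sequence data for the original study are not publicly
deposited, so a first-class synthetic-data module generates every input with
known ground truth; all calibration and power statements in the test suite
are statements about that generator's output.

# The synthetic-data model

`sim_config()` fixes the study conditions. Defaults: 5,000 genes, 2,000
promoters of 1,000 bp, groups PD38/PD47/PD54 with 3 replicates, DE fraction
0.10, effect size 1.0 log2 units, noise SD 0.25 log2 units, GC content 0.41
(human promoter-like), planting rates 2 (targets) and 0.2 (background)
sites per promoter.

* **Promoters** are i.i.d. base strings with P(G)=P(C)=GC/2. They emulate
  fixed-width upstream windows only: no CpG islands, no repeat structure, no
  positional composition gradient toward the TSS.
* **Planted motif sites** per promoter are Poisson-distributed (so the
  mean ± SD outlier rule is exercised with realistic dispersion), written at
  uniform non-overlapping positions on the forward strand as independently
  drawn concrete variants of the degenerate pattern. Planted counts are
  recorded exactly; chance background matches are accepted, so scans report
  *at least* the planted count.
* **Expression** is Gaussian on the log2 scale: baselines N(8, 2) (a typical
  array log-intensity range; the source study states none), a single random
  ± effect-size shift per true-DE gene applied to both non-reference groups,
  and i.i.d. N(0, noise_sd) measurement noise. The number of true-DE genes
  is `round(de_fraction * n_genes)` (round-half-to-even, tested). The
  generator does not emulate probe-level artifacts, normalization residue,
  or mean–variance dependence, so passing tests show correctness of the
  pipeline's logic, not robustness to array-specific artifacts.
* **qPCR Ct tables** follow quantity = E^(−Ct) with per-sample loading
  shifts shared across genes (removed exactly by reference normalization)
  and optional Gaussian Ct noise; reference genes have fold 1 by
  construction.

Everything is deterministic given `seed`: generators evaluate under a local
Mersenne–Twister state (fixed small offsets per stage) without touching the
caller's RNG, and identical configurations give byte-identical files.

# Differential expression

Per gene, the log2 fold change is the difference of group means on the log2
scale, with the earliest PD level as reference. Significance is a per-gene
two-sample t-test.

**Pooled vs Welch.** The default is the pooled-variance Student t. With
three replicates per side the Welch unequal-variance form is measurably
conservative — its Satterthwaite df estimate is noisy and bounded above by
the pooled df of 4, pushing the null fraction of p < 0.05 to ≈ 0.035 —
while the pooled form is exactly calibrated under normality, and the study
design has no reason to expect grossly unequal group variances. `welch =
TRUE` selects the Welch form.

P-values are BH-adjusted within each contrast, and a gene is called DE iff
its q-value (or raw p with `use_raw_p = TRUE`; the looser reading of a
"p < 0.05 plus FDR" filter) is strictly below `alpha = 0.05` **and** its
log2FC is strictly outside ± 0.4. Both inequalities are strict; a gene at
exactly 0.4 is not called. Degenerate variance conventions: both groups
constant and equal → p = 1; constant but different → p = 0.

**Power at n = 3.** A per-gene two-sample test with 2 + 2 df has essentially
no BH-adjusted power at effect 1.0 log2 and noise SD 0.25 over thousands of
genes: p-values small enough to survive step-up correction require variance
estimates far below their expectation, so the default pipeline calls few
genes and its sensitivity against planted truth is near zero (the raw-p
reading trades this for a large empirical FDR). The acceptance suite
measures both numbers rather than hiding them; variance-moderated models
would change this trade-off but are deliberately out of scope. This is a
property of per-gene testing at this design size, and a known limitation.

# Motif representation and scanning

A motif is a string over the 15 IUPAC codes; its variant count is the
product of per-position degeneracies and must be strictly below
`max_variants` (default 1,000) for the motif to be scanned — a specificity
guard against uninformative patterns. Scanning is exact set-membership per
position; the scanner:

* treats `N` in a *sequence* as matching nothing (masked bases never
  inflate counts);
* scans both strands by default (binding sites are double-stranded
  features; `forward` available and recorded in outputs), implemented by
  also matching the reverse-complement pattern on the forward sequence;
  identical intervals from palindromic patterns are reported once;
* counts overlapping hits by default; `disallowed` selects matches greedily
  left-to-right per strand;
* reports 0-based half-open coordinates.

Collections are scanned as one concatenated sequence with `N` spacers wide
enough that greedy selection cannot couple adjacent promoters; a test
verifies equality with per-promoter scanning. A brute-force
position-by-position oracle, and independently Biostrings' fixed-subject
ambiguity matching, verify the scanner on fuzzed cases.

# Target calling, correlation, ranking, enrichment

* **Background statistics** per motif are the sample mean and sample SD
  (n − 1 denominator) of occurrence counts over *all* promoters; a promoter
  is a candidate target iff its count is strictly outside mean ± SD.
  Strictness matters at SD = 0: constant counts yield no candidates.
* **Correlation** between TF and candidate expression is Pearson on
  replicate-level values (9 points) by default; per-group means (3 points)
  are selectable. A candidate counts as correlated iff |r| ≥ 0.8 —
  anti-correlation counts, since repressor targets move opposite to the
  repressor. With 9 samples this is a screening heuristic and is documented
  as such, never an inference.
* **Ranking** is by descending correlated-target count, ties by smaller
  enrichment p, then lexicographic TF id, so ranks are a reproducible
  permutation of 1..n.
* **Enrichment** cross-tabulates target-set membership against DE status
  over the promoter universe and uses the two-sided Fisher exact test, with
  the sample odds ratio (a·d)/(b·c) (0 when a·d = 0, ∞ when only b·c = 0),
  BH across motifs, and the call `enriched = q < 0.05 & OR > 1`. An empty DE
  set yields p = 1 by convention. The target set defaults to the mean ± SD
  candidate set (the pipeline's order); `any_site` (≥ 1 match) is available
  for comparison, as is a seeded permutation test on mean occurrence counts
  (10,000 label shuffles, add-one one-sided p) as a count-based sensitivity
  analysis.

The orchestrated run (`run_pipeline()`) follows the study's order: DE genes
first, then only motifs of DE transcription factors (after the eligibility
filter) are scanned, and filter counts at every step are recorded in
`summary.json` alongside the configuration hash.

With unplanted promoters and random DE labels the enrichment p-values are
approximately uniform and, at BH 0.05, typically no motif is called
enriched — the negative-result behaviour of the original analysis. The
approximation is limited by the discreteness of exact tests on small count
tables: the null p distribution is uniform only up to that granularity.

# Quantification utilities

* **Population doublings**: ΔPD = log2(n_f/n_i) per subculture, summed from
  an initial PD level. By log additivity the endpoint is invariant to how
  the expansion is partitioned into subcultures (tested).
* **qPCR NRQ**: technical replicates are averaged on the Ct scale *before*
  exponentiation (the order matters); RQ = E^(ΔCt) against the
  calibrator-group mean; each target is divided by the geometric mean of
  the reference genes' RQs per sample (cancelling loading differences
  exactly); finally each gene is rescaled so the calibrator group's
  geometric-mean NRQ is 1. The reference-gene set is a required explicit
  argument — published figures in this field sometimes use two of three
  named references, so defaulting it silently would be a trap. Noiseless
  tables round-trip to the true folds within 1e−9.
* **Error progression**: relative SDs entering products/quotients combine
  in quadrature, √Σσᵢ².
* **ChIP-qPCR**: fold over IgG control E^(Ct_control − Ct_IP), or percent
  input 100·E^((Ct_input − log_E dilution) − Ct_IP) with the input aliquot's
  dilution factor made explicit.
* **Band densitometry**: target/loading-control ratio rescaled to the
  reference-group mean ratio.
* **Group comparisons** for these assays use the classical pooled-variance
  two-tailed Student t (matching the study's stated statistics), with the
  same degenerate-variance conventions as the DE test.

# Problem sizes and runtimes

The test suite and acceptance script regenerate everything from code:
DE calibration uses 5,000 genes × 9 samples; enrichment power uses 100
seeded replicates of 2,000 × 1 kb promoters with one planted motif; null
calibration uses ≥ 200 random eligible motifs over the same universe;
the Fisher oracle check enumerates all 2×2 tables with total n ≤ 26 plus
random tables with margins ≤ 50. These sizes keep a full run in a few
minutes on one CPU while leaving the statistical checks well-powered.

# Known limitations

* Synthetic promoters and expression lack the correlation structure,
  composition biases and heavy tails of real data; conclusions from passing
  tests are about pipeline logic and calibration under the stated model.
* Per-gene DE testing at n = 3 with FDR control has very low sensitivity
  (see above); the package reports what the thresholds yield rather than
  moderating variances.
* The correlation screen at 9 samples is descriptive; |r| ≥ 0.8 is an
  arbitrary, documented default.
* Exact-match scanning has no mismatch tolerance or PWM scoring by design;
  motifs near the 1,000-variant bound are scanned exactly but are weakly
  informative.
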