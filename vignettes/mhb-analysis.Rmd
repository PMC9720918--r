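---
title: "Methylation haplotype block analysis with mhbkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation haplotype block analysis with mhbkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhbkit)
```

## The problem

Methylation sequencing reads carry the joint methylation state of
neighbouring CpG sites on individual DNA molecules. Neighbouring CpGs
are not independent: within short genomic stretches their states are
strongly co-inherited, forming *methylation haplotype blocks* (MHBs).
Statistics computed on whole haplotypes — rather than on per-CpG
averages — exploit this structure, which is particularly valuable for
cell-free DNA, where tumor-derived fragments are a small minority and a
single fully methylated multi-CpG fragment is far stronger evidence than
a marginal shift in a beta value.

`mhbkit` implements the full analysis chain: block discovery from
adjacent-CpG linkage, methylated / un-methylated haplotype load (MHL /
UMHL) scoring, a filter-and-test marker cascade, classification with
repeated stratified cross-validation, tissue-to-plasma model transfer,
and survival validation of predicted subgroups, together with a
synthetic cohort generator so every stage can be exercised and verified
without access to patient data.

## Data model and formats

All coordinates are 0-based, half-open at file boundaries (BED
semantics); internally CpGs are addressed by their 1-based ordinal in a
per-chromosome sorted position index (`cpg_index()`). A haplotype record
is a run of calls over consecutive CpG ordinals with a multiplicity
count; calls are `1` (methylated), `0` (unmethylated) or `?` (missing).
The on-disk dialect is a minimal mHap-style TSV (`chrom`, `start`,
`end`, `hap`, `count`, `strand`), with `strand` accepted and ignored.
Records whose coordinates do not resolve to consecutive reference CpGs
are rejected with line numbers; records with more than half their calls
missing are loaded but flagged, leaving policy to the scoring layer.
Score matrices are samples × blocks TSV with `NA` marking blocks
undetected in a sample — missingness is informative (no qualifying
reads), never silently imputed at the I/O layer.

## Block discovery

For each adjacent CpG pair, linkage is the squared Pearson correlation
of the two binary call vectors over reads covering both sites with
observed calls at both, weighted by record counts. It is computed from
the 2×2 contingency table as `(n·n11 − nL·nR)² / (nL(n−nL)nR(n−nR))`,
avoiding a square root so that rational values (e.g. exactly 0.5) are
represented exactly. A pair's r² is *undefined* when fewer than
`min_pairs` (default 10) reads co-cover the sites or when either margin
is constant — correlation with a constant is undefined, and treating it
as linkage would inflate blocks; undefined pairs break the chain.
Blocks are maximal runs of consecutive CpGs in which every adjacent
pair has defined r² strictly greater than the threshold (default 0.5 —
"higher than" is read as strict, so a tie at exactly 0.5 does not link),
and runs of a single site are discarded. Two deliberate choices:

* *Adjacency is ordinal, capped by distance.* "Adjacent" means
  consecutive in the CpG index regardless of gap, but a genomic gap
  above `max_gap` (default 500 bp) is never linkable: methylation
  co-inheritance is a local property and chaining across kilobase gaps
  would produce biologically meaningless blocks.
* *Pooled reads.* By default r² is estimated from reads pooled across
  the reference samples. Pooling maximises the pair coverage and
  mirrors how a block catalog would be built once and reused; the
  per-sample alternative can be had by calling `partition_blocks()` on a
  single sample's records. A precomputed region set can also be
  supplied directly (`regions = "known"` in the pipeline), since block
  catalogs are often taken from prior work.

## Haplotype load

For a block of `l` CpGs, each read is clipped to the block and split at
missing calls; every contiguous window of length `i` inside a segment
contributes `count` copies to the length-`i` denominator, and to the
numerator when fully methylated. MHL is the weighted average of these
fully methylated fractions with weights `w_i = i^3`; UMHL mirrors it for
un-methylated windows. The cubic exponent follows the convention of
weighting long consecutive runs heavily; it is a parameter
(`weight_exponent`), with `1` giving the original linear weighting. Note
the weights must depend on `i` — a constant weight per block would
cancel between numerator and denominator.

Numerical conventions: lengths with zero evaluable windows are dropped
from both sums (avoiding 0/0); a block with no evaluable window at any
length, or fewer than `min_reads_detect` overlapping reads, scores `NA`
(undetected). Windows never span missing calls. Sub-haplotypes are
count-weighted by default; `count_weighted = FALSE` counts distinct
haplotype strings once, for data where duplicate counts reflect PCR
rather than molecules. Consequences that the test suite verifies
exactly: MHL and UMHL are bounded in [0, 1]; `UMHL(X) =
MHL(complement(X))`; the statistic is invariant to duplicating reads or
splitting a count-`c` record into `c` records; and on a single-CpG
window length it reduces to the classical methylation frequency. The
window counting is implemented in C++ (`src/windows.cpp`) and verified
against an independent brute-force enumerator on ten thousand random
blocks at tolerance 1e-12.

## Marker selection

The cascade reproduces the standard detection/variability/test order:

1. **Sample floor** — samples with fewer detected blocks than
   `min_detected_per_sample` are dropped. The full-genome convention of
   25,000 detected MHBs presumes a catalog of ~225,000 regions; the
   pipeline scales the floor proportionally to the region set in use
   (`ceiling(n_regions * 25000 / 225025)`), so the default desk-scale
   cohort of 2,000 blocks uses a floor of 223.
2. **Block filters** — detection fraction ≥ 2/3 of retained samples and
   score SD ≥ 0.02, both inclusive ("no less than"), SD with the n−1
   denominator.
3. **Per-block test** — paired Wilcoxon signed-rank for tumor versus
   matched normal (only complete `pair_id` pairs enter; unpaired tumors
   are excluded from this stage), unpaired rank-sum for MVI+ versus
   MVI−. Tests come from `stats::wilcox.test`: exact p-values for small
   untied samples, normal approximation with tie and continuity
   corrections otherwise; the suite checks them against full
   permutation / sign-flip enumeration for n ≤ 8.
4. **FDR** — Benjamini–Hochberg (the field default where the procedure
   is unnamed; pluggable in principle via `benjamini_hochberg()`),
   applied within each score kind and, for one-sided testing, within
   each direction.

One design point deserves emphasis: choosing the one-sided direction
per marker from the observed median shift would be double-dipping. The
`alternative = "both"` default instead runs the one-sided test in both
directions, adjusts within each direction, and concatenates — markers
are tagged `hyper` or `hypo`, and a hypo-methylated block can never be
selected by the hyper direction. Missing values are dropped pairwise /
listwise per test, never imputed: a missing score means "block not
measured", and imputing it would manufacture evidence.

## Classification

Features are marker scores (columns tagged `kind:id` so MHL- and
UMHL-quantified markers of the same block stay distinct). The default
model is a 500-tree random forest (`randomForest`); a radial-kernel SVM
(`kernlab`, cost 1, sigma tuned over `2^(-4..4)` times the median
heuristic on training folds only) is one flag away. Evaluation is
stratified 3-fold cross-validation repeated 10 times: stratification is
necessary at these sample sizes (a random 3-fold split of 35 samples
can easily lose a class from a training fold), and each repeat yields
one AUC from pooled out-of-fold probabilities. The 95% interval over
repeats is the normal approximation `mean ± 1.96·sd/√R`, truncated to
[0, 1]; the repeat count is small, so this is a summary of fold-split
variability, not an inferential interval on generalisation error.
Missing feature values are imputed with training-fold medians — computed
inside each fold, so no information leaks from held-out samples; a
feature entirely missing in training falls back to 0.5, the midpoint of
the score range. AUC is the tie-aware rank statistic (probability a
random positive outranks a random negative, ties counting one half),
which the trapezoidal integral of `roc_curve()` matches exactly.

Plasma evaluation applies the tissue-trained model unchanged to the
plasma score matrix (`transfer_predict()`); retraining on plasma is also
possible by calling `cross_validate()` on the plasma matrix, but the
transfer path is the default because it answers the clinically relevant
question — whether a tissue-derived signature survives dilution into
cfDNA. MVI hard calls threshold the mean out-of-fold probability at 0.5
(unstated in the conventions this package follows; 0.5 is the neutral
choice for a probability-calibrated binary call), and feed the survival
comparison.

## Survival validation

Kaplan–Meier estimation and the two-group log-rank test are delegated
to the `survival` package behind a thin surface (`kaplan_meier()`,
`logrank_test()`), with the standard censored-after-events tie
convention, and verified in the suite against direct risk-set and O−E/V
recomputation. Survival closes the loop on synthetic truth: if the MVI
classifier works and MVI carries a hazard ratio, the *predicted* groups
must separate. Multivariable (Cox) modelling of clinical covariates is
deliberately out of scope — it is routine and cohort-specific.

## The synthetic cohort generator

The generator is a first-class, tested module, not a fixture. Each
block × group is a two-state Markov chain: a read starts methylated
with probability `theta` and toggles with probability `switch_rate` per
step. This is the minimal generator with independently tunable marginal
methylation (`theta`) and consecutiveness (`switch_rate`) — exactly the
two axes MHL measures; adjacent-site r² under the chain is approximately
`(1 − 2·switch_rate)²` near a 0.5 marginal, so the default
`switch_rate = 0.1` yields within-block linkage ≈ 0.64, comfortably
above the 0.5 discovery threshold, while `switch_rate = 0.5` destroys
linkage entirely. Read counts per pattern are drawn as independent
Poissons at rate `depth × P(pattern)` — by Poisson thinning this is
exactly a Poisson read total with i.i.d. chain reads, but it vectorises
over all patterns and blocks.

Defaults define the emulated study: 25 matched normal tissues, 35
tumors (17 MVI−, 18 MVI+), 24 healthy and 35 patient plasma samples;
2,000 blocks of 5 CpGs at mean depth 30 with per-sample detection
probability 0.9 — a desk-scale stand-in for a ~225,000-region genome
catalog chosen so the full pipeline runs in under a minute. Twenty
tumor-differential blocks shift `theta` by 0.4 (half up, half down) in
all tumors; eight MVI-differential blocks shift by 0.3 in MVI+ tumors
only. Patient plasma draws each read from the matched tumor's
distribution with probability `tumor_fraction` (default 0.3), else from
the normal distribution — a per-read mixture, matching the physical
picture of tumor and background *molecules* mixing in plasma, rather
than a per-sample average. Survival is exponential with hazards 0.02
and 0.08 per month (ratio 4) for predicted-relevant contrast, light
exponential censoring (0.01/month) and a 60-month administrative
cutoff. Where the emulated study reports no value, these are one-time
choices of plausible magnitudes, stated here and not revisited.

What the generator does *not* emulate — and therefore what passing
benchmarks cannot show: real CpG spacing and density, bisulfite
conversion error, fragment-length and coverage biases, batch effects,
between-patient heterogeneity of marker effect sizes, and any
correlation between blocks beyond group structure. Synthetic benchmarks
demonstrate that the machinery is correct and well-calibrated under its
own assumptions; they say nothing about clinical performance.

## Reproducibility

Every stochastic stage takes a seed. The pipeline fans one master seed
out to per-stage seeds by a fixed affine map
(`(seed·1009 + stage·9973) mod 2³¹−1`), so any stage can be re-run in
isolation. Two runs from one configuration are byte-identical, and
`manifest.json` records parameters, stage seeds, headline results and
md5 checksums of every artifact.

## Verification scales

The test suite verifies the scoring oracle on 10,000 random blocks (≤ 6
CpGs, ≤ 50 reads, missing calls included) at 1e-12; linkage and
partitioning against exhaustive oracles up to 100 sites; rank tests
against full enumeration up to n = 8; marker recovery and realized
false-discovery proportion over 20 simulated cohorts of 2,000 blocks
with 20 spiked markers (shift 0.4, 20 paired samples per group, depth
30); classification benchmarks on a strong-signal preset (shift 0.5,
depth 50) including plasma transfer across tumor fractions
{0, 0.1, 0.3, 1}; log-rank type-I error over 2,000 null simulations;
and end-to-end byte determinism. These sizes are the package's chosen
verification conditions and are stated in the corresponding tests.

## Known limitations

* Block discovery estimates r² from pooled reads; strong between-sample
  heterogeneity (e.g. copy-number differences) can bias pooled linkage.
* The marker cascade tests blocks independently; correlated blocks make
  BH conservative in principle but the realized FDP is only verified
  under the generator's independence.
* The repeat-AUC interval understates uncertainty for tiny cohorts; at
  n ≈ 35 treat it as fold-split variability.
* `wilcox.test` switches to the normal approximation under ties;
  heavily tied score matrices (e.g. many exact zeros) get approximate,
  not exact, p-values.
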