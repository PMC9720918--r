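# mhbkit

Read-level DNA methylation haplotype analysis in R: discovery of
methylation haplotype blocks (MHBs), methylated / un-methylated haplotype
load (MHL / UMHL) scoring, differential marker selection, classification
with repeated cross-validation, tissue-to-plasma model transfer, and
survival validation of predicted groups.

## Who this is for

Bisulfite (or enzymatic) methylation sequencing preserves the *joint*
methylation state of neighbouring CpGs on each DNA molecule. Single-CpG
beta values discard that co-methylation structure, yet it is exactly what
makes circulating-tumor-DNA signals detectable at low tumor fractions:
tumor-derived fragments carry long *consecutive* runs of (un)methylated
CpGs. `mhbkit` is for analysts who start from read-level methylation
haplotype calls and want a tested, reproducible path to: blocks →
haplotype-load scores → differential markers → tumor/normal and
subgroup classifiers → survival validation. The package was built around
a hepatocellular-carcinoma use case (tumor vs matched peritumoral normal
tissue, patient vs healthy plasma, microvascular-invasion (MVI) status),
but every stage is generic.

## The statistics at the core

**Blocks.** Two adjacent CpG sites belong to the same MHB when the
squared Pearson correlation (linkage disequilibrium) of their binary
methylation calls across reads exceeds a threshold: `r² > 0.5`. Blocks
are maximal runs of linked adjacent pairs with at least two CpGs.

**Haplotype load.** For a block of `l` CpGs, let `P(MH_i)` be the
fraction of contiguous length-`i` call windows (over all reads, split at
missing calls) that are fully methylated. Then

    MHL = Σᵢ wᵢ · P(MH_i) / Σᵢ wᵢ ,   wᵢ = i³ ,  i = 1…l

UMHL is the mirror statistic on fully *un*-methylated windows. The cubic
weights reward long consecutive runs; the exponent is a parameter
(`weight_exponent = 1` gives linear weighting).

**Marker cascade.** Samples need a minimum number of detected blocks;
candidate blocks must be detected in ≥ 2/3 of samples with score SD
≥ 0.02; surviving blocks are tested per block (paired Wilcoxon
signed-rank for tumor vs matched normal, rank-sum for MVI+ vs MVI−;
one-sided tests run in both directions) and selected by
Benjamini–Hochberg FDR.

**Models.** Random forest (500 trees; `randomForest`) or RBF-SVM
(cost 1, sigma tuned; `kernlab`) with stratified 3-fold cross-validation
repeated 10 times; AUC per repeat with a normal-approximation 95% CI.
The tissue-trained model transfers to plasma score matrices. Predicted
MVI groups are compared by Kaplan–Meier curves and the log-rank test.

**Synthetic cohorts.** Reads are two-state Markov chains over
{methylated, unmethylated}: initial state methylated with probability
`theta` (per group), toggling with probability `switch_rate` per step —
the minimal generator with tunable consecutiveness. Plasma is a per-read
tumor/background mixture at a set tumor fraction; blocks drop out per
sample with `1 − detect_prob`; survival is exponential with an
MVI-dependent hazard.

## Worked example

```r
library(mhbkit)

cfg <- pipeline_config(
  cohort = cohort_spec(n_normal = 16, n_mvi_neg = 8, n_mvi_pos = 8,
                       n_healthy_plasma = 10, n_blocks = 300,
                       n_diff_tumor = 12, n_diff_mvi = 6),
  model = model_config(n_repeats = 3),
  seed = 7)
res <- run_pipeline(cfg, "run1")
```

which prints (numbers from this exact configuration and seed):

```
[mhbkit] simulating cohort (seed 17036)
[mhbkit] discovering blocks from pooled tissue reads
[mhbkit] 300 blocks in use
[mhbkit] scoring MHL and UMHL
[mhbkit] selecting tumor-vs-normal markers (paired signed_rank, FDR < 0.05)
[mhbkit] 13 tumor-vs-normal markers
[mhbkit] cross-validating tissue classifier (random_forest)
[mhbkit] tissue mean AUC 1.000
[mhbkit] plasma transfer AUC 0.969
[mhbkit] selecting MVI markers (rank_sum, FDR < 0.05)
[mhbkit] 3 MVI markers
[mhbkit] MVI mean AUC 1.000
[mhbkit] log-rank chisq 6.73, p 0.009489
```

Reading the output: 300 true blocks were rediscovered from pooled tissue
reads by adjacent-pair LD; 13 of them pass the paired signed-rank FDR
cascade as tumor-vs-normal markers (12 were spiked); the random forest
separates tumor from normal tissue perfectly in repeated 3-fold CV; the
tissue model applied unchanged to plasma reaches AUC 0.969 despite the
70% background dilution; 3 MVI markers survive the unpaired rank-sum
cascade; and patients called MVI-positive by the classifier relapse
significantly earlier (log-rank p = 0.0095), closing the loop against the
simulated hazard ratio. `run1/` holds every intermediate (regions BED,
MHL/UMHL matrices, marker tables, predictions, survival JSON) plus
`manifest.json` with parameters, per-stage seeds and file checksums —
rerunning the same config reproduces it byte for byte.

Individual stages are plain functions (`partition_blocks`,
`score_cohort`, `select_markers`, `cross_validate`, `transfer_predict`,
`predict_mvi`, `kaplan_meier`, `logrank_test`) operating on the TSV/BED
formats documented in `?read_haplotypes`, `?read_regions`,
`?read_matrix`, `?read_metadata`. A thin CLI wrapper lives at
`inst/scripts/run_pipeline.R`.

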