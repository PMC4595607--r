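---
title: "Methods: quantitative procedures for alternative cap-binding complex studies"
author: "altcbc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative procedures for alternative cap-binding complex studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altcbc)
```

# Scope

The nuclear cap-binding complex (CBC) binds the m7G cap of polymerase-II
transcripts; besides the canonical NCBP1+NCBP2 heterodimer, an alternative
complex uses NCBP3, an RRM-containing protein that contacts capped RNA
directly. Characterising such a complex rests on four quantitative
procedures, which this package implements as reusable, seeded, testable
pipelines:

1. **AP-MS interactor scoring** — which proteins co-purify specifically with
   a GFP-tagged bait, from label-free intensity tables;
2. **poly(A) FISH quantification** — whether depleting a factor retains
   poly(A) RNA in the nucleus, from two-channel microscopy;
3. **RIP-seq enrichment** — which RNA classes co-precipitate with each cap
   binding protein, from per-gene FPKM/count tables;
4. **MST binding affinity** — how tightly a protein fragment binds capped
   RNA, from thermophoresis titrations.

Every stage has a synthetic-data generator (`gen_apms()`,
`gen_fish_images()`, `gen_ripseq()`, `gen_mst()`) that is a pure function of
its parameters and a seed and ships a ground-truth record, so
pipeline-recovery tests compare only against known truth.

# AP-MS enrichment scoring

## Model and procedure

Protein-level label-free (LFQ) intensities for bait and control
purifications (three replicates each is the typical design) are:

1. **filtered** (`filter_proteins()`): at least 2 identifying peptides and at
   least 3 quantification events in one of the two groups; decoy and
   contaminant entries removed;
2. **log2-transformed and imputed** (`log_transform_impute()`): missing LFQ
   values are left-censored (low-abundance proteins drop out), so missing
   cells are drawn from a per-sample Gaussian downshifted by `shift = 1.8`
   standard deviations and narrowed to `width = 0.3` of the sample spread —
   the standard model for LFQ missingness. Total-proteome analyses use
   `impute = FALSE` and test on observed values only;
3. **scored** (`permutation_fdr()`): per protein, the moderated statistic
   `d = (mean_bait - mean_ctrl) / (se_pooled + s0)`. The constant `s0`
   (default 0.1) damps proteins whose tiny fold change comes with tiny
   variance; `s0 = 0` recovers Student's equal-variance t exactly. The
   volcano y axis carries the classical two-sided t p-value; classification
   uses `d`.

## Permutation FDR: construction and rationale

The null distribution recomputes `|d|` for every protein under relabelings
of the samples (group sizes preserved). All non-trivial relabelings are
enumerated exactly when there are at most `n_permutations` (default 250) of
them — for a 3v3 design that is 18 of the 20 possible assignments —
otherwise `n_permutations` are sampled uniformly.

Two details matter and are deliberate:

* **The identity assignment (and, in balanced designs, its mirror) is
  excluded from the null.** Both reproduce the observed statistics exactly,
  so including them places a hard floor of 2/B on every estimated FDR — for
  a 3v3 design a floor of 0.10, which would make the conventional
  `fdr_q = 0.05` unattainable for *any* data. Excluding them restores the
  usual exchangeability-under-the-null logic.
* **The FDR estimate is add-one regularised**:
  `FDR(c) = (1 + mean null count of |d| >= c) / (observed count >= c)`,
  clipped to [0, 1]. A finite permutation null can never certify an FDR of
  exactly zero; the pseudo-count is the usual guard against that (the same
  reasoning as never reporting a permutation p-value of 0). A consequence
  worth knowing: with k proteins above a cutoff the smallest attainable
  estimate is 1/k, so at `fdr_q = 0.05` a significant set has at least 20
  members. For bait pulldowns with dozens of true interactors this is
  immaterial; for very sparse designs, raise `fdr_q`.

Significant proteins are those at or above the smallest cutoff whose
estimated FDR is at most `fdr_q`; the reported `cutoff` attribute is the
largest non-significant `|d|`, so significance is exactly the strict
inequality `|d| > cutoff` (a protein sitting numerically on the reported
cutoff is not significant). `significance_curve()` returns the hyperbola in
`(delta, -log10 p)` space on which `|d| = cutoff`; its `|delta|` asymptote
as `p -> 0` is `cutoff * s0`, and as `s0 -> 0` it flattens to a constant-p
line.

Even with these choices, exact recovery of a spiked interactor set has a
structural ceiling in a 3v3 design: the ten relabeling pair-classes are
exchangeable under the null, so with probability about 1/10 the observed
labeling holds the pooled maximum background statistic, the null tail count
at that value is zero, and the regularised FDR at "hits + 1" is
(1 + 0)/21 < 0.05. In simulations at the study design (480 background
proteins, 20 interactors spiked at +4 log2, replicate noise 0.3 log2 units)
the significant set equals the spiked set in ~90% of seeds, with the
remaining ~10% admitting exactly one extra background protein — which is
precisely what an FDR of 5% licenses. No count-based permutation FDR can
push this materially higher at q = 0.05.

## What the generator emulates (and not)

`gen_apms()` draws protein baselines uniformly on log2 [23, 33], adds
replicate noise (default sd 0.3 log2 units), shifts spiked interactors in
the bait group, and censors values with a logistic intensity-dependent
dropout. It includes decoy/contaminant/single-peptide rows so the filters
are exercised. It does not emulate correlated replicates, batch effects,
peptide-level roll-up artefacts, or match-between-runs behaviour, so passing
recovery tests demonstrate correctness of the scoring machinery, not
robustness to those real-data pathologies.

# FISH nuclear/cytoplasmic quantification

## The four-mask protocol

From a DAPI + Cy5 (oligo-dT) image pair, with known pixel size:

1. `mask_nuclei()` — DAPI pixels within 13–100% of the full dynamic range
   (13% of 255 for 8-bit data), minimum object size 50 um^2, interior holes
   filled;
2. `mask_total()` — Cy5 pixels within the absolute range 6–255, minimum
   object size 100 um^2, no hole filling;
3. cytoplasm — the exclusive combination (symmetric difference) of (1) and
   (2); when nuclei lie inside the whole-cell mask this is plain
   subtraction;
4. stained nuclei — (2) minus (3).

All threshold bounds are inclusive. The "13–100%" range is interpreted as a
fraction of the dynamic range, not a percentile of the observed histogram
(`threshold_mode = "percentile"` switches). Components are 8-connected, with
the complement labelled 4-connected for hole filling (the standard dual
pairing). Area is pixel count times `pixel_size^2`, with no subpixel
correction. DAPI is used only for masking; all measured intensities are Cy5.

`measure_nc_ratio()` sums Cy5 intensity and area within masks (3) and (4),
normalises intensity by area, and reports the nuclear/cytoplasmic density
ratio — per cell by default (each stained-nucleus component paired with the
cytoplasm of its enclosing whole-cell component; touching cells are split
only by whole-cell connectivity, without watershed — a documented
limitation), or per image. Fewer than 125 cells triggers a warning
(configurable to an error). `anova_tukey()` compares conditions by one-way
fixed-effects ANOVA with Tukey's HSD post-test; the all-values-identical
degenerate case is reported as F = 0, p = 1 with no significant pairs.

## Noise limits of the fixed-threshold protocol

The generator paints noise-free disks whose masks are recovered exactly, so
ground-truth ratios in {0.5, 1, 2, 4} are recovered to well within 5%.
Additive Gaussian noise up to ~2% of the dynamic range changes the recovered
ratio by under 10%. Beyond that the protocol itself gives way: once the
background noise sd approaches the absolute Cy5 threshold of 6 counts
(2.4% of an 8-bit range), background pixels flood across the threshold and
halo onto the whole-cell mask, biasing the ratio upward (+17% at 5%-of-range
noise in our measurements). Real acquisitions satisfy the protocol's
implicit premise — background noise below the threshold — and the generator
should be used in that regime.

# RIP-seq enrichment classification

Per-gene records carry an RNA type (Ensembl biotype vocabulary), and
replicate FPKM and read counts for bait and control libraries. Ribosomal and
mitochondrial genes are removed first (`exclude_contaminant_classes()`).
Enrichment is the pseudocount ratio

`fold = (mean FPKM_bait + 2) / (mean FPKM_control + 2)`

(replicate means taken before pseudocounting), which equals 1 when both
sides are silent and is defined for zero control signal. The per-gene test
(`differential_test()`) is an explicit substitute for the external
isoform-aware caller used upstream of such tables: a two-sided
equal-variance t-test on `log2(FPKM + 2)` across replicates with
Benjamini–Hochberg correction; an exact permutation variant is available
from 4 replicates per side. A gene is enriched
(`classify_enriched()`) when all three thresholds hold strictly:
fold > 2, FDR < 0.01, and every bait replicate carries at least 10 reads
(`count_rule = "sum"` switches to a summed-count rule).
`breakdown_and_preference()` labels genes enriched for both baits or one
only, tabulates RNA-type percentages within each label, and flags per-gene
bait preference when the ratio of fold enrichments exceeds 2 (or falls
below 0.5), strictly.

`gen_ripseq()` draws log-normal baselines (meanlog log 30, sdlog 1), applies
per-type multiplicative enrichment per bait, log-normal replicate noise
(default sdlog 0.2, a realistic replicate CV for RIP-seq), and Poisson
counts at 10 reads per FPKM unit; decoy rRNA/mitochondrial genes feed the
exclusion filter. The default structure has snRNA/lincRNA/antisense classes
bound by one bait and protein-coding genes by both. Note the statistical
honesty trade-off: at the realistic sdlog 0.2, a three-replicate t-test
leaves an occasional true gene just above the strict FDR 0.01 line, so
perfect category recovery is only guaranteed under clearly strong signal
(the recovery tests use sdlog 0.1, where it is seed-robust).

# MST binding-constant estimation

`compute_fnorm()` forms F_hot/F_cold from a fluorescence time trace (hot
34.5 s, cold 5.5 s; nearest sample, optional averaging window).
`make_dilution_series()` builds the instrument grid: a 16-point twofold
protein dilution from 204 uM, mixed in equal volumes with 100 nM labelled
RNA, giving post-mix ligand 102 uM down to ~3 nM and a fixed 50 nM target.
Fitting uses post-mixing concentrations throughout.

`fit_kd()` performs least squares on
`fnorm(L) = f_u + (f_b - f_u) * fraction_bound(L, T, Kd)` with the exact 1:1
quadratic (ligand-depletion) solution for the bound fraction — numerically
safe here since the 50 nM target is far below micromolar Kd values, in
which regime the quadratic collapses onto the hyperbola `L/(L + Kd)` (also
available via `model = "hyperbolic"`). Start values: plateaus from the
extreme points, Kd from the half-transition concentration. Fits that do not
converge, sit at a parameter bound, or see no transition at all are flagged
rather than reported. `combine_replicates()` averages replicate Kd values
and reports sd/sqrt(n) as the standard error, the convention for combining
independent instrument runs.

Identifiability is set by the signal-to-noise of the titration: the
generator's plateaus (1.0 to 0.6) give a 40% fluorescence span, and at 1%
multiplicative noise single-series Kd recovery has median relative error
~3.5% at 1 uM and ~7% at 15.8 uM. A Kd at or above the top post-mix
concentration (102 uM) is fundamentally weakly identified — the bound
plateau is never observed and Kd trades off against it (median error ~20% at
100 uM) — so affinities should sit several-fold below the top of the
dilution series, as the low-micromolar cap-RNA affinity does.

# Orchestration and reproducibility

`run_stage()` drives each analysis and simulator from a validated
configuration (YAML file or list; unknown keys are configuration errors
raised before any computation), writes outputs atomically (temp file +
rename), logs filter input/output counts, and finishes with a JSON manifest
(stage, resolved parameters, seed, package version) from which a rerun
reproduces deterministic outputs bit for bit. One master seed fans out to
per-stage child seeds (`child_seed()`), so stages never share a random
stream. A thin command-line wrapper over these functions ships in
`inst/cli/altcbc.R`.

# Problem sizes used by the test suite

The suite exercises the study-scale designs directly: 3v3 and 4v3
enumeration against brute-force oracles, 200 null datasets of 500 proteins
for FDR control, 100 seeded spiked datasets (480 + 20 proteins) for
recovery, 9–130 cell fields for imaging, ~220-gene tables for RIP-seq, and
100-seed titration sweeps for Kd recovery; everything runs in about a
minute on one CPU.

# Known limitations

* Permutation FDR in a 3v3 design has the exchangeability ceiling described
  above; four replicates per group widen the relabeling space 3.5-fold and
  correspondingly shrink the boundary-error probability.
* The imaging pipeline has no watershed: touching cells merge into one
  whole-cell component and share cytoplasm.
* The RIP-seq differential test is a deliberate, pluggable simplification of
  a count-model caller; with three replicates it is noticeably less powerful
  near the strict FDR line.
* The 1:1 binding model is assumed, not inferred; cooperative or
  multi-site binding requires a different isotherm.
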