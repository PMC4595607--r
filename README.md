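# altcbc

Quantitative analyses for studies of the alternative nuclear cap-binding
complex (CBC). The canonical CBC (NCBP1+NCBP2) binds the m7G cap of
polymerase-II transcripts; an alternative complex uses NCBP3, an
RRM-containing protein that binds capped RNA directly. Establishing such a
complex — and the phenotypes of losing it — rests on four quantitative
procedures, which this package implements as seeded, tested, reusable
pipelines for anyone doing interaction proteomics, RNA-imaging, RIP-seq or
binding-affinity work of the same shape:

* **AP-MS interactor scoring** — bait-versus-control label-free intensity
  tables are filtered (≥2 peptides, ≥3 quantification events in a group),
  log2-transformed, imputed from a downshifted Gaussian
  (shift 1.8 sd, width 0.3 sd), and scored with the moderated statistic
  `d = Δ / (se_pooled + s0)`; significance comes from a permutation FDR
  (non-trivial sample relabelings, enumerated exactly for small designs,
  add-one-regularised tail-count estimate) and is equivalent to lying above
  a hyperbolic curve in the volcano plane.
* **poly(A) FISH quantification** — the four-mask protocol: DAPI nuclei
  (13–100% of dynamic range, ≥50 µm², holes filled), Cy5 whole cells
  (6–255 absolute, ≥100 µm²), cytoplasm as their exclusive combination,
  stained nuclei as the remainder; the readout is the nuclear/cytoplasmic
  Cy5 density ratio (N/C > 1 indicates nuclear poly(A) retention), compared
  across conditions by one-way ANOVA with Tukey's post-test.
* **RIP-seq enrichment** — per-gene pseudocount enrichment
  `(FPKM_bait + 2)/(FPKM_control + 2)`, a replicate t-test with BH
  correction, strict thresholds (fold > 2, FDR < 0.01, ≥10 reads in every
  bait replicate), and an RNA-type breakdown of genes bound by one bait,
  the other, or both.
* **MST binding affinity** — normalized fluorescence `F_hot/F_cold`
  (34.5 s / 5.5 s) over a 16-point twofold dilution from 204 µM (mixed 1:1
  with 100 nM labelled RNA), fitted with the exact 1:1 ligand-depletion
  isotherm; replicate Kd values combine as mean ± s.e.

Every stage has a generator (`gen_apms()`, `gen_fish_images()`,
`gen_ripseq()`, `gen_mst()`) that produces synthetic data with a serialised
ground truth, and `run_stage()` orchestrates analyses and simulators from
validated YAML configs with atomic outputs and reproducible JSON manifests
(a thin CLI wrapper ships in `inst/cli/altcbc.R`). The methods vignette
(`vignettes/altcbc-methods.Rmd`) documents the models, parameter choices
and known limitations.

## Worked example

```r
library(altcbc)

# 1. AP-MS: simulate a pulldown with 20 true interactors, then score it
sim <- gen_apms(n_background = 480, n_spiked = 20, effect_log2 = 4, seed = 42)
tab <- log_transform_impute(filter_proteins(sim$table), seed = 42)
volcano <- permutation_fdr(tab, s0 = 0.1, fdr_q = 0.05, seed = 42)
sum(volcano$significant)                       # 21
attr(volcano, "cutoff")                        # |d| cutoff 3.29
sum(volcano$protein_id[volcano$significant] %in%
    sim$ground_truth$spiked_ids)               # 20 of 20 recovered

# 2. FISH: nuclear/cytoplasmic poly(A) ratio from a synthetic field
fish <- gen_fish_images(n_cells = 130, nc_ratio = 2, seed = 1)
measure_nc_ratio(fish$image)
#> N/C ratio (sim): 2.000 +/- 0.000 sd, n = 130 cells

# 3. RIP-seq: enrichment calls and the two-bait category breakdown
rip <- gen_ripseq(dispersion = 0.1, seed = 7)
cls <- function(df)
  classify_enriched(differential_test(exclude_contaminant_classes(df)))
breakdown_and_preference(cls(rip$NCBP2), cls(rip$NCBP3))$counts
#>       both NCBP2-only
#>         50        150

# 4. MST: Kd of the cap-binding RRM fragment
mst <- gen_mst(kd = 15.8, noise_frac = 0.01, n_replicates = 3, seed = 1)
fit_binding_series(mst$series)$combined
#> Kd = 16.37 +/- 0.8219 uM (s.e., n = 3)
```

What the numbers mean: the AP-MS run recovers all 20 spiked interactors and
admits one background protein — exactly what a 5% FDR licenses on a
21-protein significant set. The FISH field was painted with a ground-truth
N/C density ratio of 2 and the mask pipeline returns it exactly. The RIP-seq
breakdown reproduces the generated structure (150 snRNA/lincRNA/antisense
genes bound by NCBP2 only, 50 protein-coding genes by both baits). The MST
fit recovers the generating low-micromolar affinity within its standard
error.

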