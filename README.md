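# dhsreg

Integrated open-chromatin and expression analysis of BMP4 response in
breast cancer cell lines, packaged as a reusable, fully tested R workflow
over synthetic data with known ground truth.

## The problem

BMP4, a TGF-β-superfamily ligand signaling through SMAD transcription
factors, drives opposite phenotypes in different breast cancer cell
lines — increased migration in one, reduced proliferation in another.
Dissecting that divergence requires joining several analyses over paired
RNA-seq and DNase-seq experiments (BMP4- vs vehicle-treated):
differential expression, differential chromatin hypersensitivity,
promoter openness, transcription-factor binding-site enrichment in open
promoter chromatin, SMAD-motif co-localization, and survival association
of the target genes. `dhsreg` implements each of those components and a
synthetic-data module that generates all inputs with recorded truth, so
the whole workflow can be exercised, benchmarked, and extended without
raw sequencing data.

## The statistics at its core

* **DEG calling** after median-of-ratios normalization:
  gene is a DEG iff |log₂((t+1)/(v+1))| ≥ 0.75 **and** |t − v| ≥ 50
  (normalized condition values t, v).
* **Differential hypersensitivity** over a unified set of m DHSs:
  Δᵢ = √(nᵢᵗʳ/(Σᵗʳ/m)) − √(nᵢᵛᵉʰ/(Σᵛᵉʰ/m)); sites with Δ ≥ 0.20 are
  selected.
* **TSS openness**: expression-weighted coverage of ±1000 bp TSS
  windows; first-quintile genes classified closed.
* **PWM scanning**: S_{b,i} = ln((x_{b,i} + a·q_b)/((W + a)·q_b)) with
  pseudocount a = ln W; match thresholds calibrated at tail p ≤ 0.001
  from the exact score distribution (dynamic programming, verified
  against 4^w enumeration).
* **Enrichment**: observed sites over expected sites, expected =
  background site density × foreground scanned length; SMAD-element
  co-localization within 200 bp tested by a one-sided binomial test.
* **Survival screen**: median-expression split, log-rank test
  ((Σ(O−E))²/ΣV), Benjamini-Hochberg correction.

See `vignettes/methods.Rmd` for the full model, parameter table, and
design rationale.

## Worked example

```r
library(dhsreg)

# deltaDHS on a 4-peak unified set: one peak opens 4x, the rest are flat
delta_dhs(c(400, 0, 0, 0), c(100, 100, 100, 100))
#> [1]  1 -1 -1 -1

# log-rank test, two groups of two patients each
lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#> chisq = 2.882353, p = 0.089555

# the full workflow on synthetic inputs
res <- run_pipeline(pipeline_config(seed = 11), "demo_run")
#> (run_log.txt)
#> simulate: 60 genes, 300 peaks, 8 planted DEGs, 30 planted diff DHSs
#> expression: 8 DEGs (8 up) of 60 genes
#> chromatin: 230 merged DHSs, 29 selected at deltaDHS >= 0.20
#> tss_openness: 60 genes, 48.3% open in vehicle
#> enrichment: 7 fg / 34 bg fragments, ratio 2.281
#> survival: 8 DEGs screened, 8 with adjusted p < 0.05
```

The first result is the deltaDHS worked example: the opening peak scores
exactly 1 (its scaled treated signal is 4× the mean, √4 = 2, minus the
flat vehicle term √1). The log-rank χ² of 2.88 reflects all deaths in
group A preceding all of group B at n = 4. The pipeline run recovers all
8 planted DEGs with no false calls, selects 29 differential DHSs of 30
planted, and finds the planted GGCGCC motif enriched (ratio 2.28) in the
promoter DHSs of upregulated genes. Reruns with the same seed are
byte-identical.

The same stages are available as numbered drivers: run
`Rscript analysis/01_simulate.R` … `analysis/07_report.R` from the
repository root; each writes self-describing TSVs under `results/`.

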