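# tamsig

Derivation, scoring and validation of tumor-associated macrophage (TAM)
subtype gene signatures for bulk RNA-seq, plus the cohort-stratification
metrics used alongside them in immuno-oncology studies.

Single-cell studies of solid tumors resolve (at least) two TAM states — a
complement-high, phagocytosis-associated subset (**C1QC TAMs**) and an
osteopontin-high, angiogenesis-associated subset (**SPP1 TAMs**) — whose
balance carries prognostic information. Estimating their abundance from bulk
RNA-seq requires markers that are expressed by the subset and essentially
nowhere else in the tissue. `tamsig` implements that whole workflow:

* **Marker derivation** — per-gene Wilcoxon rank-sum differential expression
  of the target subset against all other cells (BH-adjusted, fold-change
  ranked), followed by a **specificity filter** against any number of
  per-cell-type reference profiles: candidates must be minimally expressed in
  non-macrophage types (default ≤ 0.1 × the target-subset mean) and at most
  modestly expressed in other macrophages (default ≤ 0.5 ×), in every
  reference.
* **Scoring** — the mean z-score statistic: per-gene standardization across
  samples (on `log2(x+1)` by default), averaged over signature genes; plus
  limma-backed quantile normalization. Five signatures ship built in
  (C1QC-8, macrophage-specific SPP1-5: PLAUR, SLC11A1, BRI3, FBP1, C15orf48,
  the 8-gene literature SPP1 set, CD8-3, Trm-3).
* **Pseudo-bulk spike-in validation** — mixtures of exactly N cells with
  0–2.5% of a macrophage type spiked into a fixed tumor-rich background;
  per-arm Spearman rho and score-per-percentage-point slopes quantify
  sensitivity and specificity.
* **Cohort metrics** — IHC H-score (0–300), prevalence at strict
  percent-positive cutoffs, paired tumor-vs-stroma contrasts, median splits,
  and the four C1QC × SPP1 TAM bins (pooled or per indication).
* **Synthetic data** — a gamma-Poisson single-cell generator with planted
  marker structure and a synthetic IHC score-table generator, so the full
  pipeline is testable end to end without any external download.

## Worked example

```r
library(tamsig)

sim <- generate_single_cell(synthetic_sc_config(seed = 1,
                                                use_real_symbols = TRUE))

mk <- differential_markers(sim$matrix, sim$annotation, "Mac_SPP1")
fl <- specificity_filter(
  mk, list(discovery = reference_profile(sim$matrix, sim$annotation)),
  target = "Mac_SPP1")
head(fl$gene, 5)
#> [1] "C15orf48" "BRI3"     "FBP1"     "PLAUR"    "SLC11A1"

val <- run_validation(sim$matrix, sim$annotation,
                      builtin_signatures()["SPP1_new"],
                      pseudobulk_design(seed = 1))
val$report
#>   signature spiked_type        rho slope_per_pct specific
#> 1  SPP1_new  Background -0.2571429  -0.006165039    FALSE
#> 2  SPP1_new    Mac_C1QC  0.9428571   0.222418518    FALSE
#> 3  SPP1_new Mac_general  1.0000000   0.199034289    FALSE
#> 4  SPP1_new    Mac_SPP1  1.0000000   1.340518946     TRUE
```

The five planted SPP1 TAM markers are recovered exactly, and the signature
score climbs ~6× faster per percentage point of SPP1 TAMs than of C1QC TAMs
(which it detects weakly, through their modest shared expression), with no
trend under the background-only control — the sensitivity/specificity
pattern a usable bulk signature must show.

The full pipeline (simulate → derive markers → spike-in validation → TAM
bins → IHC summaries) runs from one config:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "tamsig"))
run_pipeline(cfg, "demo_out")   # writes TSVs + manifest.json, bitwise reproducible
```

A command-line wrapper with subcommands (`simulate-sc`, `select-markers`,
`pseudobulk`, `score`, `ihc-summarize`, `bins`, `run`) is installed at
`system.file("cli", "tamsig.R", package = "tamsig")`.

## Package layout

| Path | Contents |
| --- | --- |
| `R/synthetic.R` | single-cell + IHC generators, fixture bundles |
| `R/normalize.R` | quantile normalization, z-scores, signature scoring |
| `R/markers.R` | differential markers, specificity filter, cross-validation |
| `R/pseudobulk.R` | spike-in design, pseudo-bulk construction, evaluation |
| `R/cohort.R` | H-score, prevalence, contrasts, median splits, TAM bins |
| `R/io.R`, `R/pipeline.R` | TSV/MTX/GMT/CSV readers-writers, config, pipeline |
| `vignettes/tam-signature-workflow.Rmd` | methods and design rationale |
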