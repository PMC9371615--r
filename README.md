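# phosphopipe

Differential analysis of label-free phosphoproteomic screens with
missing-not-at-random (MNAR) imputation, permutation-based FDR testing, and
detection-pattern enrichment — the statistical workflow used for small
two-group designs such as drug- vs vehicle-treated primary cells (the
motivating design: neutrophils, 4 DMSO vs 5 neratinib samples after quality
control).

## What it computes

Phosphosite intensities from a MaxQuant-style `Phospho (STY)Sites` table
are log2-transformed and median-centered per sample. Missingness in such
data is left-censored: sites drop out because they sit near the detection
limit. The pipeline therefore handles three channels of evidence:

1. **Intensity differences.** Sites with ≥ 3 valid values in at least one
   group are kept; remaining missing cells in column *j* are imputed from a
   downshifted Gaussian
   *N*(μ<sub>j</sub> − 1.8 σ<sub>j</sub>, (0.3 σ<sub>j</sub>)²) built from
   the column's observed mean and SD. Each site is tested with a pooled
   two-sample *t* (optional SAM-style fudge factor *s₀*), and significance
   is decided by a permutation estimate of the false discovery rate: at the
   threshold set by each site's |t|,
   FDR = mean<sub>perms</sub> #{|t*| ≥ thr} / #{|t| ≥ thr}, clipped,
   monotonized by a tail cumulative minimum, and called at q ≤ 0.05. All
   C(9,4) = 126 labelings are enumerated for the 4 vs 5 design.
2. **Presence/absence patterns.** A site detected in ≥ (group size − 1)
   samples of one group and ≤ 1 of the other is classified as enriched in
   the first group — the "3–4 of 4 vs 0–1" / "4–5 of 5 vs 0–1" rule —
   before imputation, on the raw detection matrix. Enriched site sets
   collapse to deduplicated protein sets.
3. **Annotation terms.** Selected protein sets are tested against a
   background (default: all proteins passing the validity filter) with the
   upper-tail hypergeometric probability P(X ≥ k), Benjamini–Hochberg
   adjusted.

A synthetic-data generator (`simulate_phospho_dataset()`) produces
study-shaped matrices — log-normal abundances, logistic
intensity-dependent detection, group-shifted and group-exclusive sites —
with full ground truth, so the whole chain is testable and its FDR
calibration measurable without external data.

## Worked example

```r
library(phosphopipe)

sim  <- simulate_phospho_dataset(n_sites = 500, seed = 42, n_terms = 20)
logm <- median_normalize(log2_transform(sim$matrix))

classify_sites(detection_matrix(logm))
#> presence/absence classification:
#>   DMSO-enriched: 13 sites -> 12 proteins
#>   neratinib-enriched: 9 sites -> 9 proteins
#>   neither: 478 sites

filt <- filter_min_valid(logm, min_valid = 3)
imp  <- impute_downshift(filt$matrix, seed = 7)
perm_fdr(imp$matrix, q = 0.05, seed = 8)
#> permutation-FDR two-sample test: 448 sites, groups DMSO vs neratinib
#>   exhaustive mode, 126 labelings; q = 0.05, s0 = 0
#>   significant: 24 (11 higher in DMSO, 13 higher in neratinib)
```

Of 500 simulated sites, 448 pass the 3-valid-values filter; the
detection-pattern rule finds 22 group-exclusive sites, and the permutation
test calls 24 sites at q ≤ 0.05. Scoring against the generator's truth:

```r
d <- perm_fdr(imp$matrix, q = 0.05, seed = 8)
cl <- classify_sites(detection_matrix(logm))
evaluate_calls(d, cl, sim)
#> $power          0.146   # shifted sites recovered by the t channel
#> $fdp            0       # no truly-null site among the 24 calls
#> $n_called       24
#> $pa_sensitivity 0.76    # group-exclusive sites labeled correctly
#> $pa_specificity 0.994
```

An end-to-end run with provenance (QC report, imputation mask, manifest,
TSV result tables) is one call:

```r
run <- run_pipeline(pipeline_config(site_table = "sites.tsv",
                                    sample_map = sample_map,
                                    annotations = "annotations.tsv",
                                    out_dir = "results", seed = 1))
```

A thin CLI wrapper with `simulate` / `qc` / `run` / `classify` / `enrich`
subcommands ships in `inst/cli/phosphopipe`.

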