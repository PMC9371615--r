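---
title: "Differential phosphoproteomics with MNAR imputation and permutation FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential phosphoproteomics with MNAR imputation and permutation FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphopipe)
```

## The problem

Label-free phosphoproteomic screens of small designs — here, neutrophils
from healthy donors treated ex vivo with a drug versus vehicle (DMSO),
four versus five samples after quality control — produce a site-by-sample
intensity matrix with two awkward properties. First, intensities are
log-normal-ish and need per-sample centering before any comparison.
Second, missing values are *not at random*: a phosphosite drops out of a
run mostly because its abundance is near or below the detection limit, so
missingness itself carries signal. The analysis convention this package
implements, familiar from the Perseus ecosystem, deals with both and adds
a third channel of evidence that intensity tests cannot see: sites
consistently *detected* in one group and *absent* in the other.

The pipeline is: read the MaxQuant-style site table → log2 transform →
per-sample median normalization → sample QC by mean pairwise correlation →
detection-pattern (presence/absence) classification → valid-value filter →
downshifted-Gaussian imputation → two-sample testing with permutation FDR →
protein collapsing → hypergeometric term enrichment. Presence
classification deliberately runs *before* imputation, because imputation
destroys the detection pattern it needs.

## The statistical pieces

**Normalization.** Each sample column is centered by the median of its
*present* log2 values. Under left-censored missingness the observed median
is a biased but consistent-across-samples location summary; using only
present values keeps the censoring from leaking into the centering.
The operation is idempotent.

**Valid-value filter.** A site is kept iff at least one group has at least
`min_valid = 3` present values. Three points are the minimum from which a
within-group variance is at all estimable, and the threshold is also what
makes downstream imputation defensible: every tested site has one group
that is mostly real data.

**Sample QC.** For each sample, the mean of its pairwise product-moment
correlations with the other samples, on pairwise-complete log2 values
(pairs sharing fewer than 3 sites are recorded as incomputable). Samples
below a configurable threshold (default 0.7) are *flagged only*;
exclusion is an explicit action (`exclude_samples()`), so the analyst — not
a heuristic — decides, mirroring how a poorly correlating sample would be
dropped in practice. Neither the metric's input scale nor a universal
cutoff is standardized in the field, so both are exposed as configuration.

**Imputation.** Missing cells in column $j$ are drawn independently from

$$\mathcal N\!\left(\mu_j - 1.8\,\sigma_j,\ (0.3\,\sigma_j)^2\right)$$

where $\mu_j, \sigma_j$ are the mean and SD of the column's present
values. The downshift (1.8 observed SDs) places imputed values where
left-censored measurements plausibly live; the width (0.3) keeps them from
adding spurious variance. Both are the standard defaults of this
workflow and are exposed (`width`, `downshift`); statistics can instead be
computed matrix-wide (`mode = "global"`). Column streams are derived
deterministically from `(seed, sample_id)`, so results do not depend on
column processing order, and a column with fewer than two present values
falls back to global statistics with a logged note.

**Differential testing.** Per site, the pooled-variance two-sample $t$;
optionally SAM-style regularisation $t = \bar x_A - \bar x_B \,/\,
(\mathrm{se} + s_0)$ with $s_0 = 0$ by default. Two-sided reference
p-values come from the $t_{n_A+n_B-2}$ distribution, but significance is
decided purely by a permutation estimate of the false discovery rate: group
labels are permuted (all $\binom{9}{4} = 126$ distinct labelings are
enumerated when the count is at most `exhaustive_below = 1000`, otherwise
250 random labelings excluding the identity), and at the threshold set by
each site's $|t|$,

$$\widehat{\mathrm{FDR}} =
\frac{\text{mean over permutations of } \#\{|t^\ast| \ge \text{thr}\}}
     {\#\{|t| \ge \text{thr}\}},$$

clipped to $[0,1]$ and made monotone non-decreasing down the ranking by a
tail cumulative minimum, so significant sites form a prefix of the $|t|$
ranking. Sites are called at $q \le 0.05$. Ties in $|t|$ keep input (site
key) order. The permutation count, $s_0$, and the monotonization are the
common SAM/Perseus construction; none of them is standardized enough to
hard-code, so all are configuration.

**Presence/absence classification.** With groups of 4 and 5, a site is
group-enriched when detected in at least `group size − 1` samples of that
group and at most 1 of the other — literally "3–4 of 4 vs 0–1" and "4–5 of
5 vs 0–1". The generalization `min_in = n − 1`, `max_out = 1` scales to
other designs and is overridable; configurations where a site could satisfy
both directions (`min_in ≤ max_out`) are rejected. Classification uses
only the detection pattern, never magnitudes, and runs independent of the
valid-value filter (its own thresholds already imply three valid values in
the enriched group). Enriched site sets collapse to deduplicated protein
sets.

**Term enrichment.** For a selected protein set against a background
(default: all proteins with a site passing the validity filter), each
term's overlap is tested with the upper-tail hypergeometric probability
$P(X \ge k)$, adjusted by Benjamini–Hochberg across all tested terms and
called at $q \le 0.05$. Over-representation only — the one-sided question
"more frequent than expected" — and annotations are taken as given, with
no ontology-graph propagation.

## The synthetic-data generator

`simulate_phospho_dataset()` emulates the study-shaped data the pipeline
consumes, with ground truth for every site:

* site-level log2 baselines $\mathcal N(23, 2^2)$ — the scale and spread
  of typical label-free MS intensities — with residual measurement noise
  of SD 0.5;
* a fraction (default 0.10) of *shifted* sites, magnitude 1 log2 unit
  (2 residual SDs) with random sign;
* a fraction (default 0.05, about the rate the motivating study observed)
  of *presence/absence* sites whose "off" group sits 8 detection scales
  below the midpoint — effectively undetectable;
* logistic MNAR detection, $P(\text{detect}\mid x) = 1/(1+e^{-(x-m)/s})$
  with midpoint $m = 20.5$ and scale $s = 0.5$, giving ~10% missingness
  concentrated at low abundance;
* groups of 4 and 5 samples, so the literal published thresholds are
  exercised;
* optionally a protein–term annotation model in which non-null sites land
  preferentially on proteins carrying designated "enriched" terms.

The generator writes the same file dialect the reader consumes, so
end-to-end tests exercise I/O. What it does *not* emulate: correlated
peptide co-isolation, batch or run-order drift, multiplicity-linked
intensities, heavy-tailed noise, or annotation bias. Passing tests
therefore validate the statistical machinery under a clean MNAR
log-normal model, not robustness to every artifact of real instruments.

## Calibration behavior, honestly

On the generator's default-style data (1000 sites, 4 vs 5, 10% shifted at
2 residual SDs, MNAR missingness, 20 replicates), the realized
false-discovery proportion of the full filter→impute→test chain averages
close to, and in most runs below, the $q = 0.05$ target — the acceptance
test asserts the mean does not exceed $q$ beyond twice its Monte-Carlo
standard error. Two structural caveats, both properties of this workflow
rather than of the implementation:

* **Imputation can fabricate differences.** A *null* site near the
  detection limit can, by chance, be detected in one group and not the
  other; downshifted imputation then manufactures a large, low-variance
  group difference. Such sites occasionally reach the top of the ranking,
  and they are the dominant source of false calls. Real analyses should
  read the presence/absence channel (which handles these patterns
  honestly) alongside the t-test channel.
* **Power at this design is low.** With 4 vs 5 samples and a pooled
  permutation null that is contaminated by the shifted sites themselves,
  only extreme statistics clear $q = 0.05$ — single-digit calls out of 100
  true shifts are typical, consistent with the handful of regulated
  peptides the motivating study reported from ~4000 quantified sites.
  The permutation FDR estimate is conservative by construction here, so
  low power is the price of its validity.

## Numerical and design choices

* Zero and blank intensity cells both mean "not detected" (MaxQuant writes
  0 for unquantified sites); raw values are never negative, and a
  write/read round trip preserves keys, values and the missing pattern.
* Each site × multiplicity state is an independent row, approximating the
  "phosphopeptide" granularity used for the published counts; reverse-decoy
  and contaminant flags are honored when present and treated as all-false
  otherwise.
* Groups are reported in alphabetical order; `diff` is first minus second.
  Renaming groups flips signs and nothing else.
* Zero pooled variance: $t = 0$ when the mean difference is 0, signed
  infinity otherwise (such sites rank first).
* In exhaustive mode the identity labeling is included (it is one of the
  distinct labelings); in random mode it is excluded to avoid bias at
  small permutation counts, and a random request covering all labelings
  falls back to exhaustive enumeration.
* All randomness (simulation, imputation, permutations) flows from
  explicit integer seeds; imputation derives one stream per sample id so
  results are order-invariant. Identical config + seed gives byte-identical
  output tables.
* Problem sizes in the test suite (hundreds to a few thousand sites,
  $10^5$-value imputation columns, 20-replicate calibration loops) are
  chosen so the full suite runs in seconds while keeping Monte-Carlo error
  well inside the asserted tolerances.

## Worked example

```{r example}
sim <- simulate_phospho_dataset(n_sites = 500, seed = 42, n_terms = 20)
logm <- median_normalize(log2_transform(sim$matrix))
sample_qc(logm)$table

cl <- classify_sites(detection_matrix(logm))
cl

filt <- filter_min_valid(logm, min_valid = 3)
imp  <- impute_downshift(filt$matrix, seed = 7)
d    <- perm_fdr(imp$matrix, q = 0.05, seed = 8)
d

evaluate_calls(d, cl, sim)
```

Or, end to end with provenance:

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(site_table = "sites.tsv",
                       sample_map = sample_map,
                       annotations = "annotations.tsv",
                       out_dir = "results", seed = 1)
run <- run_pipeline(cfg)
```

## Limitations

Two groups only; no paired designs, no moderated-variance (limma-style)
testing, no batch correction, no multiple-imputation uncertainty
propagation. Reproducing the motivating study's exact significant-site
count requires its unpublished imputation seed and permutation settings;
the statistical stage is therefore validated by simulation calibration,
and the presence/absence counts are the exactly reproducible quantity
given the study's processed site table.
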