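---
title: "Metabotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabotyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models behind `metabotyper`, the
parameters a user may want to move, what the synthetic-cohort generator
does and does not emulate, and the numerical decisions that were genuinely
open when the package was designed.

## 1. The two-step model

The package treats patient subtyping as a two-step problem. Step one is
purely clinical: k-means on ten z-scaled routine variables, with the number
of clusters chosen by a validity-index panel and the partition defended
against a column-permutation null. Step two asks whether the resulting
metabotypes differ metabolically: per-feature ANOVA across metabotypes on
preprocessed LC-MS feature tables, pathway-level aggregation of the
significant features, per-metabotype clinical–metabolite association
networks, and a fibrosis-stage correlation screen.

The underlying assumptions are worth stating plainly. K-means assumes
roughly spherical clusters in the scaled space, which is why the ten
variables are z-scaled first and why VLDL (an exact linear function of TG,
VLDL = TG/5) effectively double-weights triglycerides — a property of the
clinical panel itself, retained deliberately. The permutation null keeps
every variable's marginal distribution but destroys the joint structure;
it therefore tests "is there multivariate cluster structure beyond the
marginals", not "is k correct". The ANOVA treats the log2 feature
intensities as approximately normal within groups, which quantile
normalization plus log2 makes reasonable in practice.

## 2. Parameters that matter

| Parameter | Default | Units | Why this default |
|---|---|---|---|
| `k_grid` | 2–10 | clusters | plausible clinical subtype range |
| `n_start` / `max_iter` | 25 / 1000 | restarts / iterations | standard k-means practice; WSS is monotone over Lloyd iterations, so only restarts matter for quality |
| `perm_B` | 100 | permutations | add-one-smoothed p floor of 1/101 |
| `ppm_tol` / `rt_tol` | 5 / 30 | ppm / seconds | high-resolution Orbitrap mass accuracy; chromatographic drift between runs |
| `cv_max` | 0.75 | fraction | technical-replicate CV filter, strict `<` |
| `rep_r_min` | 0.7 | Pearson r | replicate agreement floor, strict `>` |
| `n_pcs` / `conf` | 5 / 0.99 | components / level | Hotelling T² screen over the leading PCs |
| `fdr` | 0.05 | — | Benjamini–Hochberg threshold gating Tukey and enrichment |
| `r_min` / `alpha` | 0.3 / 0.05 | score / p | network edge thresholds, both strict |
| `n_comp` | 3 | components | two-block PLS depth; results change little beyond 2–3 on cohort-scale data |
| `delta` | 0.025 | centrality | Δ-centrality selection, inclusive `>=` |
| `min_overlap` | 3 | compounds | pathway reporting floor |

Boundary semantics are pinned and tested: the CV filter and the network
thresholds are strict, the ppm/RT matching tolerances and the Δ-centrality
threshold are inclusive, and the 5-SD clinical screen is strict and
computed once (a single pass, not iterated, and on raw rather than scaled
variables — the latter was an open choice; raw was selected because the
screen precedes scaling in the workflow).

## 3. What the synthetic generator emulates

`sim_config()` defaults encode the study conditions the package is tested
under: a cohort of 514 children in three latent metabotypes (proportions
0.494/0.368/0.138), per-cluster clinical marginals with published medians
and IQR-derived spreads (log-normal for positive skewed labs so the median
is exactly `exp(mu)`; normal for age, SBP, BMI z-score), VLDL emitted as
TG/5 before rounding, 0.34 % missing clinical cells,
cluster-conditional ordinal histology scores, two ionization modes acquired
in triplicate across three study batches with location/scale shifts,
ppm-scale mass noise, a 4.7 % multivariate-outlier sample rate, and
pathway-structured intensity effects (default log2 effect sizes 0.6–1.0 on
the six packaged pathways). An optional mechanism plants within-cluster
correlations between a clinical variable and a pathway's features, which is
what makes the network Δ-centrality machinery testable.

Cluster labels are drawn i.i.d. categorical by default (`fixed_counts =
TRUE` gives exact sizes); this models cohort sampling rather than a fixed
design. Intensities are generated on the raw scale and never pre-logged —
normalization and transformation belong to the preprocessing module.
Replicate noise is log-normal with sigma chosen so the replicate CV is
exactly the configured value.

What it does **not** emulate: raw spectra, peak shapes, isotope envelopes,
and — by design — the real cohort's joint covariance beyond the configured
marginals and planted effects. Within a cluster the clinical variables are
independent by default (an optional correlation is the planted-association
mechanism only). This matters for interpreting tests: passing recovery
tests show the machinery works under known structure, not that real
cohorts carry that much signal.

### The recovery ceiling

One consequence deserves emphasis. The generator's per-cluster IQRs
describe the *marginals* of real, disjoint k-means partitions; resampling
them as overlapping independent distributions creates strictly more class
overlap than the partition that produced them. Under the default
conditions the Bayes-optimal classifier on the true generative model
reaches an adjusted Rand index of about 0.83 against the latent labels
(accuracy ≈ 0.95, measured at n = 2000), and k-means attains roughly
0.75–0.80 at n = 500. A recovery target of ARI ≥ 0.90 is therefore not
attainable under these conditions — not because of an implementation
defect but because the generative design deliberately refuses to invent
joint structure the published marginals do not constrain. The acceptance
suite keeps the 0.90 assertion as written and it stays red; the
validity-index panel recommending k = 3 under the same conditions does
hold.

## 4. Numerical choices

* **k-means determinism.** k-means++ seeding; ties in nearest-centroid
  assignment break toward the lowest cluster index; empty clusters are
  repaired by reseeding from the farthest point; the best of `n_start`
  restarts by WSS is kept. All randomness flows through `with_seed()` /
  `derive_seed()`, so a single root seed reproduces a full run.
* **Gap statistic.** 50 uniform reference sets over the data's bounding
  box; the first-local rule (gap(k) ≥ gap(k+1) − se(k+1)) with a
  maximum-gap fallback; reference fits use fewer restarts (5) since only
  the reference *distribution* matters. Panel ties go to the smallest tied
  k and are flagged.
* **Batch adjustment.** Location/scale empirical Bayes with
  method-of-moments hyperparameters (normal prior on per-batch locations,
  inverse-gamma on scales), applied on the log2 scale, with each feature's
  grand mean restored exactly afterwards. `shrink = FALSE` gives the
  no-shrinkage limit, where per-feature batch means are removed exactly —
  that limit is the oracle the tests compare against, and the shrunk
  estimate agrees with the reference ComBat implementation to r > 0.999 on
  constructed data. Because each synthetic study arrives as its own table,
  the pre-merge adjustment only acts on tables carrying ≥ 2 batch labels;
  the cross-study standardization step is realized as the same adjustment
  across study labels after matching — the workflow's ordering here was
  ambiguous and this resolution is recorded in the run report.
* **Feature matching.** ppm is computed against the mean of the two
  masses, making the matcher exactly symmetric; greedy acceptance by
  ascending ppm with RT as tie-break; one-to-one.
* **Eigenvector centrality.** The clinical–metabolite networks are
  bipartite, and plain power iteration on a bipartite adjacency matrix
  oscillates with period 2. Centrality therefore uses an ARPACK
  eigensolver on the |r|-weighted adjacency (verified against a dense
  eigendecomposition to 1e-8) and is max-normalized. On disconnected
  graphs mass concentrates on the dominant component; the result carries a
  `disconnected` flag.
* **Association scores.** With z_h the average of the two block variates
  of component h, r_ij = Σ_h cor(X_i, z_h)·cor(Y_j, z_h), clipped to
  [−1, 1], with a two-sided t test on n − 2 df. The formula is pinned by
  this package's own tests (planted-pair recovery, clipping, symmetry);
  sign conventions cancel because z → −z leaves the product invariant.
* **Degenerate inputs.** Constant columns: error in scaling, dropped with
  a warning in PLS. Zero within- and between-group variance: F = 0,
  p = 1; zero within- with real between-group differences: p = 0.
  All-zero features are dropped before log2; zeros are replaced by half
  the feature's smallest positive value. Singleton silhouette clusters
  score 0. Empirical p-values are add-one smoothed, so p = 0 never
  occurs.
* **Natural log.** The six skewed clinical variables entering the network
  block are natural-log transformed; any base gives identical correlations
  after z-scaling, so downstream results are base-invariant — recorded
  only for reproducibility.
* **Small-sample tests in profiling.** Mann–Whitney uses exact enumeration
  for tie-free groups of ≤ 8, the tie/continuity-corrected normal
  approximation otherwise; r×c tables with any expected count < 5 fall
  back to a seeded Monte-Carlo Fisher test (10,000 tableaux). Pairwise
  profiling p-values are reported unadjusted and flagged as such in the
  report metadata.
* **Enrichment.** Compound hits require a primary-adduct match (M+H
  positive, M−H negative — the registry is configurable since primary-ion
  sets are tool-version dependent); overlap counts distinct compounds, not
  features, to avoid double-counting adducts; the permutation p (add-one
  smoothed) replaces a parametric Gamma fit — on one-to-one references it
  converges to the hypergeometric tail, which the tests check at
  B = 20,000.
* **Permutation stability reporting.** Whether the observed-vs-permuted
  comparison should be made at the chosen k only or across the whole grid
  is genuinely open; the report therefore carries the full grid and the
  per-k empirical p, and callers read off whichever they need.

## 5. Problem sizes in the shipped tests

The test-suite and acceptance-script sizes are chosen as the smallest
cohorts at which each property is comfortably identifiable: n = 500
synthetic subjects (20 seeds) for recovery and k selection, n = 200 for
the planted stability check, B = 20 permutations where only the p floor of
1/21 matters, 150 subjects / ~200 features / 20 replicates for end-to-end
planted-pathway recovery, and B = 20,000 permutations only for the one
hypergeometric-convergence oracle. The synthetic defaults (514 subjects,
triplicates, two modes) remain the generator's reference conditions.

## 6. Known limitations

* Feature extraction from raw spectra is out of scope; the pipeline starts
  at feature tables.
* Annotation is adduct mass matching only (confidence level 5), with an
  optional caller-supplied confirmed list for level 1; no MS/MS or
  retention-time library evidence.
* The packaged pathway reference is a small fixed six-pathway set meant
  for testing and demonstration; real analyses should supply a fuller
  reference via `read_pathway_reference()`.
* HOMA2-IR and BMI percentiles are consumed as inputs, never computed.
* The fibrosis screen reports unadjusted Spearman p-values by design
  (mirroring exploratory practice); multiplicity is the caller's
  responsibility.
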