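# metabotyper

Data-driven subtyping ("metabotyping") of pediatric metabolic
dysfunction-associated steatotic liver disease (MASLD) cohorts, combining
unsupervised clinical clustering with untargeted LC-MS metabolomics. The
package is aimed at clinical metabolomics analysts who have (a) a table of
routine clinical variables per subject and (b) per-study, per-mode LC-MS
feature tables, and who want reproducible metabotypes plus the metabolic
pathways and clinical-metabolite networks that distinguish them. Because
cohort data of this kind are usually controlled-access, the package ships a
first-class synthetic-cohort generator with known ground truth, so the whole
pipeline is testable end to end.

## The method

**Step 1 — clinical metabotyping.** Ten routine variables (age, ALT, AST,
waist circumference, VLDL = TG/5, LDL, TG, HOMA2-IR, uric acid, SBP) are
median-imputed, screened for subjects with any value more than 5 SD from the
mean, and z-scaled. K-means (k-means++ seeding, 25 restarts, Lloyd
iterations) partitions the cohort; the number of clusters is chosen by
majority vote of a validity-index panel (mean silhouette width s(i) =
(b(i) − a(i)) / max(a(i), b(i)), Calinski–Harabasz, Davies–Bouldin, gap
statistic, WSS elbow). Cluster stability is tested against a permutation
null: each variable's values are independently permuted B times, k-means is
refit over k = 2..10, and the add-one-smoothed empirical p compares the
observed mean silhouette with the permuted distribution. Clusters are
profiled Table-1-style (median/IQR, counts/percents, Kruskal–Wallis,
Mann–Whitney U, chi-squared / Fisher).

**Step 2 — metabolomics.** Feature tables (m/z, RT, intensity per
injection) are median-summarized over technical triplicates (pairwise
Pearson r > 0.7 check), CV-filtered (median technical CV < 75 %), adjusted
for batch effects by empirical-Bayes location/scale shrinkage, matched
across studies (5 ppm, 30 s, greedy one-to-one), quantile-normalized,
log2-transformed, and screened for multivariate outliers with Hotelling's
T² over the first five principal components at the 99 % control limit.
Per-feature one-way ANOVA across metabotypes with Benjamini–Hochberg FDR
and Tukey HSD post-hoc tests identifies differential features; these feed a
mummichog-style pathway enrichment (adduct mass matching at ±5 ppm, primary
ions enforced, permutation null over the quality-filtered background,
pathways reported at overlap ≥ 3). Per metabotype, a two-block PLS
(canonical mode) links the clinical block to the differential features; the
association score r_ij = Σ_h cor(X_i, z_h)·cor(Y_j, z_h) with
z_h = (t_h + u_h)/2 defines a network at |r| > 0.3 and p < 0.05, with
Louvain communities and eigenvector centrality. Features whose centrality
differs by ≥ 0.025 between two metabotype networks enter pairwise pathway
enrichment. Finally every feature is screened against the square-root
transformed histologic fibrosis stage with Spearman correlation.

## Worked example

```r
library(metabotyper)

cfg <- sim_config(n_subjects = 200, seed = 42,
                  modes = list(hilic_pos = list(n_background = 60),
                               c18_neg  = list(n_background = 60)))
run <- run_pipeline(pipeline_config(synthetic = cfg, k = "auto",
                                    k_grid = 2:6, perm_B = 20,
                                    enrich_B = 199, seed = 42))
run
#> <metabotype_run> k = 3 | 198 subjects | 2 mode(s) | 3 network(s)
run$k_selection
#> <k_selection> recommended k = 3
#> votes: silhouette=3  calinski_harabasz=3  davies_bouldin=4  gap=4  elbow=3
run$stability
#> <stability_report> B = 20
#>  k observed      p
#>  2   0.1988 0.0476
#>  3   0.2289 0.0476
#>  ...
head(as.data.frame(run$enrichment$hilic_pos), 4)
#>                                 pathway n_significant_hits n_detected_in_pathway ratio empirical_p   B
#> 1                 tryptophan metabolism                  9                     9   9/9       0.005 199
#> 2     pantothenate and CoA biosynthesis                  8                     8   8/8       0.010 199
#> 3                     purine metabolism                  9                    10  9/10       0.010 199
#> 4 branched-chain amino acid degradation                  7                     7   7/7       0.020 199
```

Reading the output: the panel votes k = 3, matching the three latent
metabotypes the generator planted; the stability p of 0.0476 (= 1/21 at
B = 20) says the observed silhouette beat every permuted dataset; the
enrichment table recovers the planted pathway effects — e.g. tryptophan
metabolism with 9 of its 9 detected compounds significant at empirical
p = 0.005 (the floor for B = 199). `run$networks` holds the per-metabotype
association networks (exportable with `export_graphml()`),
`run$centrality_comparisons` the pairwise Δ-centrality feature selections,
and `run$fibrosis` the per-mode Spearman screen against fibrosis stage.

2 of 200 subjects were dropped by the 5-SD screen and ~5 % of samples by
the Hotelling screen (the generator's planted multivariate-outlier rate),
visible in `run$report$stages`.

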