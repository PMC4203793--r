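# micropart

Two-part differential abundance analysis for microbiome count data.

## What it is for

Treatment-group amplicon surveys — e.g. a mouse study asking which gut
bacteria expand or collapse under a dietary or clinical intervention —
yield, per animal, read counts over taxa.  These counts are zero-inflated
(a taxon is absent from some animals and abundant in others) and
compositional (only relative abundances are meaningful).  `micropart`
provides the analysis chain for such studies:

- **Read QC**: sliding-window quality trimming (window 5, mean Phred ≥ 20),
  ambiguity (> 1 N) and length (< 200 nt) filters, OTU tabulation by exact
  taxonomy-string identity.
- **Two-part test**: per taxon, a presence z-statistic and a Wilcoxon
  rank-sum z on the non-zero relative abundances combine as
  *X² = Zp² + Zw² ~ χ²₂* (with χ²₁ fallbacks when one part is
  degenerate), after a ≥ 50 % prevalence filter, with Benjamini–Hochberg
  FDR across the tested taxa.
- **Effect views**: Manhattan data (−log₁₀ p with 0.05/0.01 lines) and the
  Δmedian-abundance / Δproportion-positive quadrant view.
- **Kruskal–Wallis screen** across all groups, tie-corrected.
- **CLR–PCA ordination**: centered log-ratio transform with a per-sample
  pseudocount of 1/(sample total), covariance PCA by SVD, biplots with
  loading vectors.
- **Random-forest ranking** of taxa by mean decrease in Gini impurity
  (10,000 trees by default).
- **Simulator**: a zero-inflated Dirichlet-multinomial community generator
  with known ground truth (group sizes 5–14, depths ~1,000 in [388, 3,065],
  46 taxa with a dominant ~50 % constituent), used to validate every stage.

See the vignette in `vignettes/two-part-analysis.Rmd` for the model,
its assumptions and the design choices.

## Worked example

Simulate the bundled bloom scenario — a taxon at 0.5 % baseline enriched
30-fold in the treatment group of a 14 + 14 animal study — and test it:

```r
library(micropart)
sim <- simulate_counts(sim_config_pnali(), seed = 42)
sim$table
#> taxon_table: 28 samples x 46 taxa
#> read depth: 649-2271 (median 981)
#> groups: control (n=14), treatment (n=14)

fit <- two_part(sim$table, "control", "treatment")
fit
#> Two-part differential abundance: control vs treatment
#> 21 taxa tested (25 removed by the 50% prevalence filter)
#> 2 taxa at p < 0.05, 1 at p < 0.01; 1 at FDR < 0.05

head(summary(fit)[, c("taxon", "prop_A", "prop_B", "median_A", "median_B",
                      "statistic", "df", "p_raw", "p_adj")], 3)
#>         taxon    prop_A    prop_B    median_A    median_B statistic df        p_raw        p_adj
#> 1 bloom_taxon 0.2142857 1.0000000 0.000000000 0.155530691 25.117647  2 3.513761e-06 7.378899e-05
#> 2  S24-7_like 1.0000000 1.0000000 0.133916315 0.084581078  4.087262  1 4.320757e-02 4.536795e-01
#> 3    taxon_18 1.0000000 0.7142857 0.008868102 0.005820145  4.752381  2 9.290382e-02 5.659406e-01
```

The injected bloom is recovered at the top: present in 21 % of controls
at median relative abundance 0, in 100 % of treated animals at median
15.6 %, combined statistic 25.1 on 2 df, FDR-adjusted p = 7.4 × 10⁻⁵.
The dominant taxon shows a raw-p 0.04 fluctuation that the FDR
adjustment correctly discounts (adjusted p = 0.45).  `plot(fit,
type = "manhattan")` and `plot(fit, type = "effects")` draw the two
diagnostic views; the bloom lands in the "higher in treatment" quadrant.

Ordination and forest ranking on the same study:

```r
clr_pca(clr_transform(sim$table))
#> CLR-PCA: 28 samples, 27 components
#> explained variance: PC1 15.6%, PC2 13.6%, PC3 13.4%, PC4 8.6%, PC5 7.1%

head(rf_importance(sim$table, n_trees = 2000, seed = 1)$ranking, 3)
#>         taxon importance rank
#> 1 bloom_taxon  3.4479250    1
#> 2  S24-7_like  0.7866933    2
#> 3    taxon_05  0.6393540    3
```

`run_pipeline(pipeline_config(...))` chains every stage (QC or
count-table input → summaries → pairwise two-part comparisons →
Kruskal–Wallis when > 2 groups → effect views → CLR-PCA → random forest)
and writes TSV outputs plus a JSON manifest with input hashes.

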