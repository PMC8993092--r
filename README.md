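# panelmiR

Circulating miRNAs are stable in serum and attractive as non-invasive
disease biomarkers, particularly for rare disorders such as the muscular
dystrophies, where cohorts are small (a handful of patients against a larger
pool of matched healthy controls) and single-marker statistics are fragile.
panelmiR implements the full analysis such a study runs once a small-RNA
count matrix is in hand:

1. **Differential expression** — TMM normalization and the negative-binomial
   quasi-likelihood F-test. Counts are modelled as
   `y ~ NB(mu, phi)` with `Var(y) = mu + phi * mu^2` and
   `log mu = x'beta + log(effective library size)`; each miRNA is reported
   with `log2FC`, `logCPM`, `F`, `p-value` and Benjamini–Hochberg `FDR`.
2. **Panel classification** — a nested leave-one-out cross-validation: in
   every fold, feature selection (the full DE pipeline) and normalization
   are recomputed on the training samples only, an SVM (radial basis, cost
   1) is trained on standardized `log2(CPM + 1)` expression, and the
   held-out sample is scored. Panel size grows from six miRNAs until
   accuracy saturates; results include accuracy, sensitivity, specificity,
   Matthews correlation coefficient and the Mann–Whitney AUC, plus the
   pooled unique panel across folds.
3. **Target aggregation** — per-database miRNA→gene edge lists are
   thresholded on their kappa-like scores, merged, ranked by cross-database
   support, capped at 50 genes per miRNA, and partitioned across diseases
   (Venn cells, disease-term joins).
4. **Enrichment** — two-sided hypergeometric term enrichment with step-down
   (Holm) adjustment, fold-enrichment reporting and ontology-level
   filtering (levels 4–16 by default).
5. **Synthetic cohorts** — a seeded generator of NB count matrices
   (default: 8 patients vs 22 controls, library sizes 1–5M), target edge
   lists and annotation tables, so every stage is testable without any
   external data.

See `vignettes/serum-mirna-panels.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

Simulate a cohort with ten truly differential miRNAs planted among 800,
test for differential expression, and search for the optimal panel:

```r
library(panelmiR)

sim <- simulate_counts(sim_config(n_mirnas = 800, frac_de = 10/800,
                                  lfc_magnitude = 2, dispersion = 0.1,
                                  seed = 21))
de <- de_analysis(sim$counts, sim$samples)
summarize_de(de)
#> 10 of 800 features significant (1.3%) [6 over, 4 under; 11 at FDR < 0.05]

head(de[order(de$p_value), ], 3)
#>  mirna_id   log2fc   logcpm        f      p_value          fdr
#>  mir-0065 2.356341 13.57185 177.6086 2.298151e-40 1.838521e-37
#>  mir-0699 2.228661 11.21097 160.8953 9.648802e-37 3.859521e-34
#>  mir-0613 2.161302 11.39228 150.8033 1.494778e-34 3.986074e-32

sw <- sweep_panel_sizes(sim$counts, sim$samples)
sw
#> Panel sweep: optimal size 6 (accuracy 1.000, AUC 1.000); 7 pooled unique features
#>  panel_size accuracy sensitivity specificity mcc auc
#>           6        1           1           1   1   1
#>           7        1           1           1   1   1
#>           8        1           1           1   1   1
#>           9        1           1           1   1   1
```

Reading the output: all ten planted miRNAs are the ten significant calls
(`p < 0.05`, `|log2FC| > 1`), and their fitted fold changes sit near the
planted `±2`. The cross-validated sweep saturates immediately — a 6-miRNA
panel classifies every held-out sample correctly (accuracy, MCC and AUC all
1.0) — and the pooled unique panel across the 30 folds contains 7 distinct
miRNAs, every one of them a planted marker:

```r
sw$pooled_unique_mirnas
#> "mir-0011" "mir-0065" "mir-0141" "mir-0605" "mir-0613" "mir-0699" "mir-0730"
```

The whole pipeline (with the target and enrichment stages on synthetic edge
lists and annotations) can also be driven from a YAML/JSON config via
`run_pipeline()`, which writes every stage table plus a manifest with seeds
and checksums.

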