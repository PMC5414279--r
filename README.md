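# habvar

Phylogenetic comparative analysis of climatic niche breadth and gene
functional categories.

## The problem

Why can some mammal species occupy climatically variable habitats while
close relatives cannot? Candidate explanations range from primary genomic
measures (genome size *G*, total gene count *N*<sub>g</sub>, duplicated
genes *N*<sub>d</sub>) to physiology (body mass *M*, mass-specific
metabolic rate *B*<sub>c</sub>) to the gene complement of specific
functional categories. Testing a specific category against these
confounders requires (i) a quantitative niche-breadth score, (ii) per-
category gene counts, and (iii) a regression framework that removes
phylogenetic autocorrelation and survives having far more candidate
categories (~384) than species (~32).

`habvar` implements that full chain for R users:

- **Climate envelope** — the number of occupied cells in a 981 × 15 grid
  (14 715 cells, axes weighted by explained variance) over the first two
  principal components of the 19 bioclim variables sampled across a
  species' range; analysed on the square-root scale.
- **Habitat diversity** — the Brillouin index
  H = (ln N! − Σ ln n<sub>i</sub>!)/N over categorical climate classes.
- **Duplicated genes** — genes with at least one same-species, non-self
  homology hit at E < 10⁻⁵ and query coverage > 30% (strict).
- **NOGF** — number of distinct genes per functional category.
- **Inference** — Felsenstein's independent contrasts; cross-validated
  L1 screening of all categories; phylogenetic GLS under Brownian
  covariance (β̂ = (XᵀC⁻¹X)⁻¹XᵀC⁻¹y); all-subsets AICc selection; model
  averaging over the 95% Akaike-weight confidence set; strict p < 0.01
  acceptance gate.

A synthetic-study generator (`simulate_study()`) emulates the complete
data bundle — Yule tree, Brownian traits, per-species climate sample
clouds, homology hit tables with threshold-boundary decoys, gene-to-
category maps — with one category causally planted, so the entire
pipeline can be exercised and validated without any external downloads.

## Worked example

```r
library(habvar)

study  <- simulate_study(sim_config(seed = 7))
report <- run_pipeline(study$tree, study$traits,
                       climate      = study$climate,
                       hits         = study$hits,
                       gene_map     = study$gene_map,
                       catalogue    = study$catalogue,
                       class_counts = study$class_counts)
print(report)
```

```
Habitat-variability analysis report (32 species)
screened categories: Exosome-like
AICc: full 166.4, best 152.8
      variable estimate_full  se_full   p_full estimate_best se_best   p_best estimate_avg   se_avg    p_avg
1  (Intercept)      1.09e+01 1.90e+01 0.572612         9.745  4.6798 4.59e-02     9.50e+00 9.65e+00 3.25e-01
2 Exosome-like      4.37e-01 9.50e-02 0.000104         0.435  0.0834 1.25e-05     4.35e-01 8.53e-02 3.51e-07
3            G      9.60e-10 6.68e-09 0.886761            NA      NA       NA     3.43e-10 2.60e-09 8.95e-01
4          N_g     -2.60e-04 6.46e-04 0.690963            NA      NA       NA    -4.82e-05 2.85e-04 8.66e-01
5          N_d      1.75e-03 1.90e-02 0.927233            NA      NA       NA     2.17e-04 7.49e-03 9.77e-01
6            M      6.04e-05 2.24e-04 0.789415            NA      NA       NA    -3.50e-06 8.47e-05 9.67e-01
7          B_c      2.84e+02 2.87e+02 0.332324            NA      NA       NA     8.49e+01 1.82e+02 6.41e-01
gated at p < 0.01: Exosome-like
```

Reading the output: the lasso screen over all 384 category contrasts plus
the five covariates forwarded a single candidate, the planted
"Exosome-like" category. In the model-averaged fit its coefficient on the
√envelope scale is ≈ 0.44 with p ≈ 3.5 × 10⁻⁷ — the only term passing the
strict 0.01 gate, so the pipeline accepts exactly the category that the
generator made causal, while genome size, gene counts, body mass and
metabolic rate are all (correctly) dismissed. The best model's AICc is
lower than the full model's, as it must be, since the best model
minimizes AICc over all coefficient subsets.

The Figure-1-style single-predictor summary:

```r
nogf <- setNames(study$traits[["Exosome-like"]], study$traits$species)
resp <- setNames(report$scores$response,        report$scores$species)
str(pic_correlation_report(nogf, resp, study$tree))
#> List of 4
#>  $ slope      : num 0.435
#>  $ r_squared  : num 0.476
#>  $ p_value    : num 1.25e-05
#>  $ n_contrasts: int 31
```

A contrast-level R² near one half is the signal strength the generator is
calibrated to plant (the regime of the motivating study's headline
correlation).

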