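# splicestem

An R package implementing an integrative transcriptomic screen that
prioritizes long non-coding RNAs (lncRNAs) linking aberrant alternative
splicing to tumor stemness in tumor/normal cohorts — and the downstream
analyses such a screen feeds: survival stratification, clinical
association, junction-count differential splicing, and drug-sensitivity
association. It is aimed at computational biologists who have a TPM
matrix, clinical annotations, splice-event junction counts and (optionally)
per-sample drug-response predictions, and want a reproducible, tested
implementation of this screen rather than a pile of one-off scripts.

## The method

All stages work on `log2(TPM + 1.01)` expression. Two per-sample axis
scores anchor the screen:

* **Splicing score** — the mean log2 expression over a curated set of
  splicing regulatory factors;
* **Stemness index (mRNAsi-style)** — the Spearman correlation between a
  one-class stemness signature's weights and the sample's expression over
  the signature genes, rescaled cohort-wide to [0, 1].

Candidate lncRNAs must be concordant across three views. With moderated
t-statistics from empirical-Bayes variance shrinkage
(s̃²ᵍ = (d₀s₀² + d s²ᵍ)/(d₀ + d), hyperparameters fit by method of
moments on log variances) and per-gene Pearson correlations r against
each axis score:

```
up:   log2FC >  0.6  ∧  BH p < 0.001  ∧  r_stem >  0.25  ∧  r_splice >  0.45  (corr p < 0.05)
down: log2FC < −0.6  ∧  BH p < 0.001  ∧  r_stem < −0.25  ∧  r_splice < −0.25  (corr p < 0.05)
```

Selected candidates are stratified at their mean expression and tested
with both the log-rank test and a two-stage procedure whose second stage
is a maximally-selected two-piece weighted log-rank statistic with a
permutation null — retaining power when survival curves cross. Direction
(`Poor`/`Better`) comes from restricted mean survival.

Differential splicing uses PSI = (I/lᵢ)/(I/lᵢ + S/lₛ) from inclusion/
skipping junction counts and a beta-binomial likelihood-ratio test with
event-level shared dispersion, a parametric-bootstrap Bartlett
calibration of the chi-square reference, and the five-rule filter chain
(group counts ≥ 10, mean PSI in [0.05, 0.95], FDR ≤ 0.01, |ΔPSI| ≥ 0.05,
TPM ≥ 1). Drug calls require the stratified IC50 comparison and the
IC50–score correlation to agree in sign.

A seeded synthetic-cohort generator (`sim_config()`, `generate_cohort()`,
`generate_events()`, `generate_ic50()`, `write_bundle()`) emulates the
assumed data structure — a latent malignancy factor loading on splicing
factors, signature genes and planted lncRNAs, hazard-linked survival,
planted ΔPSI events, axis-correlated drugs — with a truth table for
recovery testing. See `vignettes/methods.Rmd` for the full model
descriptions, parameter meanings and design decisions.

## Worked example

```r
library(splicestem)

cfg <- sim_config(seed = 1)            # frozen strong-effect reference cohort
co  <- generate_cohort(cfg)            # 60 tumors + 30 normals, truth table
expr <- normalize_expression(co$expr)  # log2(TPM + 1.01)

ss <- splicing_score(expr, co$factors)
si <- stemness_index(expr, co$weights)
roc_auc(ss, co$samples$tissue == "tumor")
#> [1] 0.8766667

de  <- moderated_de(expr, co$samples$tissue)
tum <- co$samples$sample_id[co$samples$tissue == "tumor"]
cs  <- correlate_with_score(expr, si, restrict_to = tum)
cp  <- correlate_with_score(expr, ss, restrict_to = tum)
uni <- co$truth$id[grepl("^lncRNA", co$truth$role)]   # the lncRNA universe
cand <- select_candidates(de[de$gene_id %in% uni, ],
                          cs[cs$gene_id %in% uni, ],
                          cp[cp$gene_id %in% uni, ])
c(attr(cand, "n_up"), attr(cand, "n_down"))
#> [1] 23  5

head(cand[order(-cand$log2fc),
          c("gene_id", "direction", "log2fc", "adj_p", "r_stem", "r_splice")], 3)
#>   gene_id     direction log2fc    adj_p r_stem r_splice
#>  LNCUP020 up_concordant   5.45 5.64e-18  0.618    0.870
#>  LNCUP004 up_concordant   5.31 2.49e-17  0.651    0.899
#>  LNCUP022 up_concordant   5.29 3.66e-17  0.595    0.873

prognostic_call(expr$values["LNCUP001", ], co$samples, seed = 1)$call
#> [1] "Poor"
```

The screen recovers all 23 planted up- and 5 planted down-lncRNAs with no
false positives on this cohort (the tumor/normal AUC of the splicing
score is 0.877), and the survival-linked lncRNA is called `Poor`
(log-rank p ≈ 2e-7). `run_pipeline()` drives the same stages — plus
clinical tests, the splice-event pipeline and drug calls — from a YAML
config over the TSV bundle written by `write_bundle()`.

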