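# ucbranch

Multi-omic analysis of the two developmental branches of urothelial bladder
cancer — papillary urothelial cancer (PUC) and carcinoma in situ (CIS) — and
of the origin of invasive tumors.

Invasive bladder cancer can arise from either precursor, but the two routes
carry different prognoses and no routine marker distinguishes them.
`ucbranch` is a reusable, tested R implementation of an analysis chain that
addresses this from proteogenomic data:

* **Label-free quantification** — iBAQ (summed peptide intensity over the
  count of theoretically observable tryptic peptides, 7–30 aa, no missed
  cleavages), fraction-of-total normalization (FOT × 1e5, floored at 1e-5),
  match-between-runs retention-time transfer (linear/quadratic model chosen
  by adjusted R²), a strict >30% detection filter, floor imputation, and
  log2 transform.
* **Single-sample enrichment** — ssGSEA with weight 0.75, rank
  normalization, area-under-running-score statistic, minimum overlap 5, and
  permutation-normalized scores (NES, 1000 permutations); DNA damage
  response scores (mean of across-sample-standardized phospho markers);
  regulon/transcription-factor activity with a minimum set size of 10.
* **Mutational signatures** — 96-context SBS catalogs on the pyrimidine
  strand, de-novo extraction by KL-divergence NMF, and NNLS refitting
  against a reference set with the 0.08 weight filter and
  dominant-signature grouping.
* **Copy number** — length-weighted arm/band burden from SEG-style
  segments, amplification/deletion calls at |log2| ≥ 1, Fisher
  frequency tests between groups, and a Spearman cis-effect screen
  (copy number vs the same gene's protein).
* **Origin classifier** — Wilcoxon/BH/fold-change differential panels
  (adjusted p < 0.05, fold > 2 or < 0.5), an L2-regularized logistic
  model (mean logistic loss + (λ/2)‖β‖², Newton-Raphson, λ = 1/n by
  default), stratified 80/20 split and 10-fold cross-validation without
  scaling leakage, confusion-matrix metrics with Mann-Whitney AUC, and
  PUC-derived/CIS-derived assignment of invasive samples at the 0.5
  threshold.
* **Survival** — Kaplan-Meier, log-rank, univariate Cox (Breslow ties),
  and maximally selected cutpoints with permutation-corrected p-values.
* **Synthetic cohorts** — a seeded generator producing peptide evidence,
  protein/phospho matrices with abundance-dependent dropout, mutation
  tables with class-dependent signature mixtures and HRAS hotspots,
  segment tables with an 8p12 deletion coupled to a protein cis effect,
  and proportional-hazards survival, plus the ground truth needed for
  recovery testing.

The methods vignette (`vignettes/ucbranch-methods.Rmd`) documents every
model, parameter, and numerical choice.

## Worked example

Generate a study-scale synthetic cohort (40 LGPC+HGPC papillary tumors,
40 CIS, 86 invasive) and run the full pipeline:

```r
library(ucbranch)

cfg <- pipeline_config(
  cohort = cohort_config(
    n_per_class = c(LGPC = 20, HGPC = 20, CIS = 40, Invasive = 86),
    classes    = c("LGPC", "HGPC", "CIS", "Invasive"),
    n_proteins = 120, n_phospho = 60, mutation_rate = 50),
  seed = 42)
rep <- run_pipeline(cfg)

rep$panel
#> differential panel: 10 up in PUC, 10 up in CIS (q < 0.05, FC > 2 or < 0.5)
rep$cv          # pooled 10-fold CV on the 80% training split
#> eval_report: acc 0.984, sens 0.969, spec 1.000, AUC 0.972
rep$test_eval   # held-out 20%
#> eval_report: acc 0.938, sens 1.000, spec 0.875, AUC 0.953
table(rep$origin_calls$label)
#> CIS-derived PUC-derived
#>          34          52
rep$derived_comparison$cox
#> cox_fit: HR 3.619 (95% CI 2.104-6.222), Wald p 3.31e-06
rep$derived_comparison$logrank$p_value
#> 9.06e-07
```

Reading the output: the differential panel found 20 proteins separating
PUC from CIS at the stated thresholds; cross-validated sensitivity/
specificity describe how well the panel classifier re-identifies the two
precursors; 34 of 86 invasive tumors are called CIS-derived; and the
CIS-derived group shows worse overall survival (hazard ratio 3.6, log-rank
p ≈ 1e-6) and more metastasis (Fisher p = 0.039) — the synthetic cohort is
generated with a true CIS-derived hazard ratio of 2 and metastasis coupled
to the CIS branch, and `rep$recovery` compares every estimate against that
generator truth (here: panel recall 1.0, origin-label accuracy 0.953,
signature-exposure mean absolute error 0.047).

Every stage is also callable on its own (`quantify_evidence()`,
`filter_and_impute()`, `score_matrix()`, `ddr_score()`, `build_catalog()`,
`refit_signatures()`, `nmf_extract()`, `arm_burden()`, `cis_effect()`,
`differential_panel()`, `fit_margin_logistic()`, `cross_validate()`,
`assign_origin()`, `km_estimate()`, `logrank_test()`, `cox_univariate()`,
`optimal_cutpoint()`), and `write_cohort_bundle()` /
`pipeline_config(mode = "files")` exchange all inputs as plain TSV/GMT/JSON.

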