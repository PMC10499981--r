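---
title: "Models and methods behind ucbranch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ucbranch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucbranch)
```

# Scope

`ucbranch` implements a multi-omic analysis of urothelial bladder cancer
progression along its two developmental branches: papillary urothelial
cancer (PUC) and carcinoma in situ (CIS), the flat high-grade lesion. The
package covers label-free proteomic quantification, single-sample pathway
and phospho-signature scoring, single-base-substitution (SBS) mutational
signatures, arm-level copy-number burden, a protein-panel classifier that
assigns invasive tumors a PUC-derived or CIS-derived origin, and survival
analysis of the resulting groups. A seeded synthetic cohort generator
reproduces the latent structure these analyses assume, so the entire chain
is testable without patient data.

# Label-free quantification

Peptide evidence (area under the extracted-ion chromatogram per peptide and
run) is aggregated to protein level by iBAQ: summed peptide intensity
divided by the count of theoretically observable tryptic peptides. We define
observable peptides as fully tryptic fragments — cleavage C-terminal to K/R,
suppressed before proline, zero missed cleavages — of length 7 to 30
residues. The lower bound matches the common ≥7-residue identification
filter; the upper bound is the usual iBAQ convention for peptides that
ionize and elute reproducibly.

Per run, iBAQ values are normalized to the fraction of total (FOT): each
protein's iBAQ over the run's summed iBAQ, scaled by 1e5. Values below 1e-5
are floored at 1e-5 *after* normalization, so conservation (pre-floor FOT
sums to 1e5) is exact and is asserted in the tests at 1e-6 relative
tolerance.

Match-between-runs transfers identifications from a reference run into a
target run through a retention-time map fitted on shared peptides. Both a
linear and a quadratic least-squares map are fitted; the one with the higher
adjusted R² wins, with ties going to the linear model. We require at least
six anchors so the quadratic retains three residual degrees of freedom.
Transferred records are flagged (`observed = FALSE`) and can be excluded
downstream.

Matrices are filtered to features detected in strictly more than 30% of
samples (a feature seen in exactly 30% is dropped), missing entries are
imputed with the 1e-5 floor, and values are log2-transformed. The floor
imputation is deliberately crude — it encodes "below detection" — and its
−16.6 log2 value is an outlier by construction; downstream rank-based
statistics are robust to it, which is one reason the analysis leans on
Wilcoxon/Spearman machinery.

# Single-sample enrichment

Pathway, kinase-substrate, and regulon scores all use one primitive:
single-sample gene-set enrichment with the parameterization weight = 0.75,
rank sample normalization, area-under-running-score statistic, minimum
overlap 5, and 1000 permutations for normalized scores. Features are sorted
by rank-normalized value, descending; the running score gains
$|r|^{0.75}/\sum_{hits}|r|^{0.75}$ at set members and loses $1/(N-n_{set})$
elsewhere; the enrichment score (ES) is the mean of the running score over
positions (the signed area). The normalized score (NES) divides the ES by
the mean |ES| of size-matched random sets, preserving sign.

Two numerical choices matter. Ties in the rank ordering are broken by a
seeded random ordering of the sorted feature names, which makes results
deterministic, unbiased, and invariant to the storage order of features.
And because the rank weights and the area kernel are co-monotone, the area
statistic has a small *positive* expectation for random sets; the NES
rescales but does not recenter it. Null calibration therefore has to be
read from the permutation rank of a set's ES (which is uniform under
exchangeability, and tested as such), not from the raw NES sign.

The DNA damage response (DDR) score standardizes each marker
phosphoprotein (SQ/TQ substrates of ATM/ATR/DNA-PK) to mean 0, SD 1 across
samples (n−1 denominator) and averages the standardized values per sample.
Zero-variance markers are dropped with a warning. Regulon (e.g. AP-1)
activity is the same ssGSEA machinery applied to transcription-factor
target sets with a minimum set size of 10.

# Mutational signatures

Catalogs count substitutions in the 96 trinucleotide contexts on the
pyrimidine strand (purine-reference records are reverse-complemented,
flanks swapping and complementing accordingly) in the fixed order C>A, C>G,
C>T, T>A, T>C, T>G by 5' then 3' flank. De-novo extraction is non-negative
matrix factorization with multiplicative updates minimizing generalized
Kullback-Leibler divergence — the count-appropriate objective — with the
best of 10 random restarts kept and signature columns normalized to sum 1.
The objective is non-increasing across iterations, which the tests assert
directly.

Refitting against a reference signature set solves a non-negative least
squares problem on the count-normalized catalog, normalizes weights to sum
1, removes signatures below the 0.08 weight threshold, and re-fits the
retained set until stable. This is the same constrained objective as the
iterative refitting tools in common use, but solved directly by NNLS, which
is deterministic; on noise-free catalogs inside the reference's convex hull
the residual is zero to 1e-9. Samples whose weights all fall below the
threshold are flagged unassigned rather than erroring. Dominant-signature
labels use the argmax weight, ties going to the lexicographically smaller
id with a flag. Trinucleotide-opportunity correction is not applied: no
genome is in scope, and the synthetic reference is already expressed in
catalog space.

# Copy number

Arm-level burden aggregates segment log2 copy ratios over an arm with
overlap length as weight. We report the length-weighted *mean* by default so
values stay on the log2-ratio scale and can be compared to the ±1
amplification/deletion cutoff; the literal length-weighted sum is available
as an option. Cutoff comparisons are inclusive: a value of exactly ±1
qualifies. Coordinates are 0-based half-open internally; conventional
1-based SEG input is converted on read. Group alteration frequencies are
compared with Fisher's exact test, BH-adjusted across arms. A cis effect is
declared when a gene's copy-number value and its own protein abundance
correlate positively (Spearman) at BH-adjusted p < 0.05.

# Statistical primitives

The rank statistics are self-contained so their conventions are explicit:

* Wilcoxon rank-sum: exact two-sided p by enumeration of all
  $\binom{n_1+n_2}{n_1}$ assignments when $n_1+n_2 \le 14$, otherwise a
  normal approximation with tie and continuity correction.
* Kruskal-Wallis with tie correction; Fisher's 2×2 by the two-sided
  probability-mass convention (zero margins give p = 1); BH step-up;
  Spearman with average-tie ranks, t approximation for n ≥ 10 and exact
  permutation below.
* Differential panels require BH-adjusted Wilcoxon p < 0.05 *and* a group
  mean FOT ratio above 2 (or below 0.5). Testing happens on the log2 scale;
  fold changes on the raw FOT scale with imputed floor values included,
  which is the reading of "ratio > 2" consistent with FOT units. Mean
  rather than median fold change is used; the choice is visible in one
  place should a user prefer otherwise.

The base-R equivalents (`wilcox.test`, `kruskal.test`, `fisher.test`,
`p.adjust`, `cor.test`) are used as independent cross-checks in the test
suite, never as the implementation.

# The origin classifier

Candidate features come from the PUC-vs-CIS differential panel ranked by
adjusted p; the default panel size is 18. The model is L2-regularized
logistic regression minimizing mean logistic loss plus
$(\lambda/2)\lVert\beta\rVert^2$ with an unpenalized intercept, solved by
damped Newton-Raphson to a gradient max-norm below 1e-8 — a deterministic
stand-in for the "fast large margin" logistic operator of point-and-click
pipelines. The default regularization is $\lambda = 1/n$: large-margin
solvers fix the penalty at $\tfrac12\lVert w\rVert^2$ against a *summed*
loss with C = 1, which equals $1/n$ on our mean-loss scale. A fixed
$\lambda = 1$ on the mean-loss scale is roughly n times stronger, shrinks
probabilities toward the majority class, and visibly depresses sensitivity
at a fixed 0.5 threshold even when the ranking (AUC ≈ 0.98) is excellent —
which is why the scaled default was chosen.

Features are z-scaled with *training* statistics (population SD, so
duplicating the sample set is a no-op); cross-validation re-estimates the
scaling inside every fold, and the suite includes an explicit leakage test
that reproduces each fold's model from scratch. The 80/20 split and the
stratified 10-fold assignment preserve class proportions to within one
sample. Evaluation reports the 0.5-threshold confusion matrix, sensitivity,
specificity, accuracy, and the Mann-Whitney AUC (ties counted 0.5).
Invasive samples with CIS-class probability above 0.5 are called
CIS-derived; exactly 0.5 falls to PUC-derived and is flagged.

# Survival

Kaplan-Meier, log-rank, and univariate Cox (Breslow ties, Wald intervals)
are computed through the `survival` package behind the module's interface;
an independent Newton solver for the partial likelihood lives in the test
suite as the oracle. On tie-free data the Cox score test at $\beta = 0$
equals the log-rank chi-square to 1e-9, which is asserted.

Optimal biomarker cutpoints maximize the standardized log-rank-score
statistic over all dichotomizations leaving at least `minprop` (default
0.1) of samples on each side — the maximally selected rank statistic with
log-rank scores. Significance is selection-adjusted by permuting the marker
and re-maximizing (default 1000 permutations), which controls the scan's
multiplicity exactly at finite samples; the reported cutpoint is the
midpoint of the selected gap so it never coincides with an observed value.

# The synthetic cohort generator

The generator emulates the latent structure of an FFPE multi-omic bladder
cohort; it is the package's test bed and defines the conditions under which
recovery is asserted:

* Eight histology classes (Normal, Hyperplasia, UPUMP, Papilloma, LGPC,
  HGPC, CIS, Invasive), 12 per class by default. Papilloma/LGPC/HGPC sit on
  the papillary branch, CIS on the CIS branch; invasive samples draw a
  latent branch (40% CIS-derived) that downstream classification must
  recover.
* Proteome: per-protein log2 baselines ~ N(5, 2); a panel (default 20
  proteins) shifted ±1.5/2 log2 between branches (half up in PUC, half up
  in CIS); residual log2 noise SD 1.0. Peptide evidence is generated from
  tryptic protein sequences built so digestion recovers the generating
  peptides exactly, with per-run retention-time distortion for the
  match-between-runs path.
* Missingness is logistic in log2 abundance (midpoint 1.0, slope 1.0),
  emulating abundance-dependent dropout of label-free FFPE data.
* Phosphoproteome with 10 DDR markers shifted +1 log2 in CIS and invasive
  classes.
* Mutations: Poisson counts (mean 50) from class-specific mixtures of four
  synthetic, well-separated SBS signatures (an aging-like CpG C>T pattern
  dominating early lesions, a flat clock-like component, an APOBEC-like
  TpC C>G pattern and a C>T-outside-CpG pattern rising in late lesions).
  Papilloma samples carry an HRAS hotspot with probability 0.83, of which
  80% are Q61R. These synthetic signatures are stand-ins constructed for
  testing, not the COSMIC catalogs.
* Copy number: per-arm segments with log2 noise SD 0.15; carriers (80% of
  metastatic invasive, 10% of non-metastatic invasive, 2% otherwise) bear a
  −1.2 log2 deletion spanning the 8p12 band, coupled to a −1.2 log2 shift
  of one designated protein. That protein's baseline is pinned at a
  well-quantified abundance so the cis-effect screen is not confounded by
  detection filtering.
* Survival: exponential event times (baseline hazard 0.005/month for
  non-invasive, 0.02/month for PUC-derived invasive, hazard ratio 2.0 for
  CIS-derived) with independent exponential censoring at 0.01/month.
  Metastasis is coupled to the CIS branch (55% vs 20%, odds ratio ≈ 4.9).

What the generator does *not* emulate: spectra or chromatograms, genome
sequence, batch effects, correlated protein co-expression modules,
non-proportional hazards, or informative censoring. Tests passing on these
cohorts demonstrate that the algorithms recover the structure they claim to
recover under their stated assumptions; they are not evidence about messier
real data.

# Problem sizes and determinism

The default pipeline cohort (96 samples, 300 proteins) runs in seconds and
is byte-identical across runs with the same seed: one top-level seed
deterministically derives independent per-stage streams for cohort
generation, splitting, fold assignment, and permutation normalization.
Recovery checks run at the sizes the properties demand — e.g. 60 PUC + 40
CIS over 20 seeds for classifier sensitivity/specificity, 86 invasive
samples for the cis-effect screen (the Spearman screen is underpowered for
a −1.2 log2 shift at unit noise below roughly half that size), 2000
samples per arm for hazard-ratio recovery within a [0.85, 1.18] factor,
and ≥500 null replicates for type-I-error calibration of every reported
test.

# Known limitations

* The ssGSEA ES is reported on the area scale; implementations differing in
  the area normalization give proportionally different ES, identical NES.
* The refit step inherits NNLS's tendency to sparse solutions; highly
  collinear reference signatures (unlike the synthetic set) would make
  individual weights unstable even when the fit is good.
* The classifier is strictly binary (PUC vs CIS); samples from neither
  branch are still forced into one of the two classes.
* `optimal_cutpoint` prices in the selection over cutpoints, but not any
  upstream selection over markers; screening many markers still requires
  adjustment across markers.
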