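---
title: "Methods: construction and evaluation of the astrocytoma progression score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: construction and evaluation of the astrocytoma progression score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apscore)
```

## The problem and the model

Astrocytomas span a progression continuum from lower-grade (II–III) tumours
to glioblastoma (grade IV), and transcriptome-wide expression carries a
strong prognostic signal along that axis. This package builds a per-sample
**astrocytoma progression (AP) score** in two stages:

1. **Signature selection.** From a log2 gene-by-sample matrix containing
   normal tissue (NT), lower-grade glioma (LGG) and glioblastoma (GBM)
   samples, a gene enters the signature only if it passes all five of:
   (i) differential expression tumour vs NT (BH q < `fdr_max`),
   (ii) differential expression GBM vs LGG (BH q < `fdr_max`),
   (iii) high variability across tumours (scaled MAD > `mad_min`),
   (iv) concordant direction of change in (i) and (ii), and
   (v) per-gene prognostic value (median-split log-rank p < `km_p_max`).
   Genes up with progression form POS_AP, genes down form NEG_AP.

2. **Scoring.** Each sample's expression is rank-transformed
   (ties averaged) and each set S scored with the single-sample enrichment
   statistic
   $$ES = \sum_{i=1}^{N}\Big[P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i)\Big],
   \qquad
   P_{\mathrm{in}}(i)=\frac{\sum_{k\le i,\,k\in S} r_k^{\alpha}}
   {\sum_{k\in S} r_k^{\alpha}},\quad
   P_{\mathrm{out}}(i)=\frac{\#\{k\le i,\,k\notin S\}}{N-|S|},$$
   walking the genes in decreasing-rank order. Then
   **AP = POS score − NEG score** per sample. A higher AP score means a
   more progressed, worse-prognosis transcriptional state.

The evaluation layer reproduces the statistics such a score is judged by:
Kaplan–Meier curves with median survival, the two-group log-rank test with
the Mantel–Haenszel hazard ratio, Cox proportional-hazards regression
(Efron ties), outcome ROC/AUC, ANOVA / chi-square / Fisher / Pearson /
paired-t association tests, and mutation and copy-number group comparisons.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fdr_max` | 0.01 | BH q ceiling for criteria i–ii |
| `lfc_min` | 0 | optional \|log2 FC\| floor for i–ii (the published screen used FDR only; the 1.5 value seen in AP-group DEG analyses belongs to that separate analysis) |
| `mad_min`, `mad_constant` | 1.0, 1.4826 | variability floor; the 1.4826 normal-consistency scaling is conventional and configurable because the source method states only "MAD > 1.0" |
| `km_p_max` | 0.05 | per-gene log-rank ceiling for criterion v |
| `alpha` | 0.25 | ssGSEA rank-weight exponent, the customary single-sample default; 0 weights set genes equally |
| `normalize` | TRUE | divide all enrichment scores by the global (max − min) range of the score matrix |

POS and NEG are always scored **jointly**, sharing one normalization range:
their difference is only meaningful on a common scale. Whether scores should
be normalized per cohort or across merged cohorts is not prescribed by the
source method; this package normalizes per input matrix.

Tie and direction conventions, fixed once and reused everywhere:
median splits send ties to the "low" group; the high-score group is always
listed first in two-group survival contrasts, so HR > 1 reads "high score,
worse survival"; within-sample rank ties receive average ranks and the
walk order among tied ranks is alphabetical by gene symbol, making the
enrichment score independent of input gene order.

## The synthetic cohort: what it emulates, what it does not

`generate_cohort()` emulates the *statistical structure* of a TCGA-style
training cohort — 5 NT, 160 LGG and 80 GBM samples, 2000 genes of which
12 + 6 are planted progression genes shifting ±1.0 log2 per grade step
(σ = 0.7 residual noise). The latent progression axis of a tumour is the
standardized planted-POS minus planted-NEG mean — exactly the quantity the
AP score estimates — and it drives everything downstream: exponential
survival with hazard $h_0 e^{\beta\,\mathrm{latent}}$ (β = 1 per SD,
$h_0 = 10^{-3}$/day, uniform administrative censoring at 10 years),
logistic couplings for IDH/MGMT/grade/subtype, a named mutation panel
(IDH1/TP53/ATRX rates falling with progression; PTEN/EGFR/NF1/RB1/PIK3CA
rising) and copy-number shifts (EGFR/CDK4/PDGFRA up, CDKN2A/CDKN2B/PTEN
down, 0.2 SD noise). All draws come from one seeded stream in a documented
order, so cohorts are bit-reproducible.

It does **not** model read-count distributions, platform or batch effects,
annotation drift between platforms, or non-proportional hazards. A green
test therefore establishes internal statistical correctness and directional
behaviour, not performance on real cross-platform cohorts.

`generate_paired_recurrence()` builds primary lower-grade tumours and
recurrences in which 6 of 7 pairs progress (the planted genes shift one
further grade step), mirroring the longitudinal design of primary–recurrent
cohorts; the left-out pair recurs without progression.

## Power limits of the default world (why one acceptance check is red)

Two of the screen's criteria are *not satisfiable* at the generator's
default settings, and the acceptance suite says so rather than quietly
relaxing anything:

* **MAD.** A planted gene across tumours is a 2:1 mixture of N(+1, 0.7²)
  and N(+2, 0.7²); its scaled MAD concentrates near 0.85 — below the 1.0
  threshold (background genes sit near 0.70). Real log2 RNA-seq data has
  much heavier per-gene dispersion, which is what the 1.0 threshold was
  written against.
* **FDR with 5 normals.** The tumour-vs-NT contrast is limited by the NT
  mean's standard error (0.7/√5 ≈ 0.31), capping per-gene evidence near
  z ≈ 4.2, while BH q < 0.01 among 2000 genes requires roughly z ≳ 3.9 —
  per-gene pass probability ≈ 0.3 with the exact rank-sum test, far from
  the ≈ 0.97 needed to recover 17 of 18 genes jointly.

Consequently the cascade correctly raises its empty-signature error (with a
full per-criterion audit table attached) on the default synthetic cohort.
The recovery acceptance check is left failing by design; the identical
cascade recovers ≥ 16/18 planted genes with ≤ 2 false positives in a
powered configuration (20 NTs, 1.5 log2 shifts, σ = 0.9), which the unit
suite exercises. Downstream direction checks (grade gradient, survival,
mutation/CNV enrichment, 6/7 recurrence) score with the planted truth
signature through the documented precomputed-signature path.

## Numerical and design choices

* **DE test.** Wilcoxon rank-sum on normalized log values (exact null when
  the group-size product ≤ 10⁴ and there are no ties, else the corrected
  normal approximation) — distribution-free, consistent with applying one
  signature across platforms. BH is computed over all genes tested.
* **Survival.** KM, log-rank and Cox are implemented from their defining
  formulas. Cox uses Efron's tie correction (day-granularity data produce
  heavy ties), Newton–Raphson with step-halving, convergence at
  max |score| < 1e-8, SEs from the inverse observed information;
  diverging coefficients (|β| > 20) are flagged as monotone likelihood.
  `survival::coxph`/`survdiff` are used in the test suite as independent
  oracles only.
* **Fisher vs chi-square.** 2×2 tables with any expected cell < 5 use the
  exact two-sided hypergeometric rule (sum of table probabilities ≤ the
  observed, with a 1e-7 relative tolerance for floating-point ties);
  otherwise Pearson chi-square without continuity correction.
* **ROC labelling.** Mean OS is averaged over deceased patients; positive =
  died before mean OS, negative = survived past it, censored-before-mean-OS
  patients are excluded as indeterminate (the only reading under which
  every retained label is well defined). AUC is the tie-corrected
  Mann–Whitney statistic.
* **Degenerate inputs.** Constant genes are dropped from median splits and
  correlations with warnings; a gene mutated in every sample compares as
  p = 1; zero-range normalization and empty set–universe overlaps are hard
  errors.

## Known limitations

Selection power depends strongly on the number of normal samples; with very
few normals, criteria i and iii dominate the false-negative rate (see the
power notes above). The Mantel–Haenszel HR and the Cox HR answer slightly
different questions and are both reported rather than reconciled. No GO or
pathway enrichment is included, and transcriptional subtype is treated as a
given covariate, not called from expression.
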