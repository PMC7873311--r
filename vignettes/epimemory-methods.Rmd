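---
title: "Methods: GA-related methylation, transcription, and epigenetic memory"
author: "epimemory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-related methylation, transcription, and epigenetic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Gestational age (GA) at birth is the strongest prognostic factor for preterm
infants, and cord-blood DNA methylation carries broad GA-associated
alterations. Two questions follow: do these methylation changes relate to
transcription in the fetal state, and do any of them persist into postnatal
blood — i.e., act as *epigenetic memory* of the intrauterine period?
`epimemory` implements the complete analysis path for a paired
cord/postnatal methylome study with a cord-blood expression subset, plus a
synthetic-data generator that plants every signal the pipeline is supposed
to detect, so each stage can be validated against ground truth.

## The statistical model

### Per-CpG EWAS

For each CpG, methylation (percent scale, $\beta \times 100$) is regressed
by OLS on GA and the birth-weight SD score jointly:

$$Y_{meth} = \beta_0 + \beta_{GA} X_{GA} + \beta_{SD} X_{SD}
  + \textstyle\sum_i \beta_i X_{COV,i} + \varepsilon$$

Two adjustment sets are fitted. **Model 1**: infant sex, batch
(treatment-coded indicators), and estimated cell-type fractions.
**Model 2**: Model 1 plus six prenatal covariates (chorioamnionitis,
idiopathic PROM, preeclampsia, maternal smoking before pregnancy, maternal
pre-pregnancy BMI, cesarean section). Benjamini–Hochberg q-values are
computed over all tested probes, *separately* for the GA and SD-score
coefficient families (the two predictors answer different questions and are
reported separately). A CpG is called GA-related (or SD-related) when it is
FDR-significant (q < 0.05) in *both* models *with the same coefficient
sign* — the dual-model direction-consistent intersection. Single-covariate
sensitivity fits (Model 1 + one prenatal covariate at a time) report the
fraction of consensus CpGs robust to every added covariate.

Cell fractions nearly sum to a constant, so K−1 of the K = 7 types enter
the design (granulocytes dropped by default); entering all seven would make
the design rank-deficient in the renormalized case and near-singular
otherwise. Batch enters as indicators against the first batch label.

### Covariate screen

Prenatal covariates are screened one at a time against GA and the SD score.
Continuous covariates are standardized to SD 0.5 (division by two standard
deviations), so a "+1" change spans 2 SD and estimates are directly
comparable with binary category switches; binary covariates are never
scaled. CIs use exact t quantiles. Covariates passing p < 0.05 (optionally
a suggestive threshold, e.g. 0.060) enter a multivariate model together
with infant sex.

### Cell-type deconvolution

Reference-based constrained projection: for each sample, the beta vector
over reference CpGs is projected onto the reference profile matrix
(CpGs × 7 cord-blood cell types: CD4T, CD8T, NK, B, Gran, Mono, nRBC) by
solving $\min_f \|y - Rf\|^2$ subject to $f \ge 0$, $\sum f \le 1$
(quadratic program, solved with `quadprog`). The inequality sum constraint
permits an unexplained remainder; a renormalize-to-1 switch exists for
downstream use. Whether the original analyses constrained the sum to
exactly 1 is not documented, so both behaviors are exposed.

### Integration with transcription

CpGs are matched to expression probes on the same chromosome within
±250 kb, **boundary inclusive** (the source wording — "within 250 kb
upstream or downstream" — does not specify the boundary; inclusive is
chosen and boundary-tested at 250,000 vs 250,001 bp). Matched transcripts
are tested for GA/SD association (log2 expression, same adjustment engine);
q-values are scoped to the matched probe set only. For pairs involving
GA-related transcripts, Pearson correlation between methylation and log2
expression is computed over the shared samples, with p from the t transform
on n−2 df. Promoter CpGs (TSS200, TSS1500, 5′UTR, 1st exon) are classified
**concordant** (r < 0: transcription falls as methylation rises) or
**discordant** (r > 0); the labels are not defined outside promoters.

### Memory scoring and chromatin state

For each GA-related CpG, the Pearson correlation between cord and postnatal
methylation across paired subjects is computed; CpGs with r ≥ 0.7
(inclusive) are memory candidates. A draw-interval confounding check splits
paired subjects into bottom/top halves by the cord-to-postnatal interval
(the median subject dropped when the count is odd so halves are equal,
configurable) and paired-t-tests the per-CpG difference in within-half
correlations. Chromatin-state statistics over the 25-state vocabulary use
2×2 Fisher exact tests of set vs background-minus-set (a flag switches to
set-vs-full-background, since "reference proportion based on all CpGs" is
ambiguous); odds-ratio CIs use the normal approximation on the log scale
with the Haldane–Anscombe +0.5 correction applied *and flagged* when a cell
is zero, rather than suppressed. Significance requires p < 0.05/25 and
OR ≥ 1. The decile trend orders the GA-related universe by cord-post r
(ties broken by CpG id so bins are deterministic), partitions into 10 bins
differing in size by at most one, and traces each requested state's OR per
bin.

### Gene lists and set enrichment

Promoter CpGs with a gene annotation are mapped to genes per direction
category (GA±, SD±); genes need ≥ 2 supporting promoter CpGs. Enrichment
against a GMT collection uses a plain one-sided hypergeometric test with BH
correction at FDR ≤ 0.1. This is a deliberate substitution for the DAVID
web service's modified-Fisher EASE score: the published enrichment
statistics are therefore not reproduction targets. The default universe is
the genes carried by post-filter array probes, not the genome, mirroring
the array-constrained background (the original's universe is unstated).

## The synthetic world

The generator emulates the target study at miniature scale: 110 cord
samples, 47 paired postnatal samples, a 55-sample expression subset, GA
from a truncated normal (mean 34, SD 4.9, range 23–41 weeks), postnatal
draw intervals of 2–18 weeks with median near 7, and binary prenatal
covariates with logistic GA dependence in the canonical directions (male,
cesarean, smoking before pregnancy, chorioamnionitis, idiopathic PROM and
higher maternal BMI more frequent at earlier GA; SD score rising with GA
and lowered by preeclampsia). Defaults chosen once:

* `n_cpgs = 5000`, `frac_ga_cpgs = 0.2`. Each single model detects ~11% of
  array probes at FDR 0.05 in the real cohort at the same n; with imperfect
  power the true prevalence is plausibly about twice the both-model rate,
  so 0.2 is used as the planted prevalence.
* `ga_effect_logit_per_week = NULL` (auto): the planted effect is 4× its
  *true* standard error under the fully adjusted design — computed from the
  realized design matrix (including the SE inflation from GA-correlated
  covariates and cell composition, about 2.9× here) and the full residual
  SD (noise plus subject intercepts), solved jointly by fixed point.
* Methylation noise is logit-normal (`noise_sd_logit = 0.3`): keeps betas
  in (0,1) and yields the heteroscedastic, boundary-compressed behavior of
  array betas. The per-sample baseline is a reference-profile × true-cell-
  fraction mixture whose composition drifts with (postmenstrual) age —
  nRBC falling steeply with maturity — creating the confounding that the
  cell-adjusted model must neutralize (this is tested directionally).
* Persistence: a subject-level intercept shared between tissues is the
  mechanism for *baseline* cord-post correlation (mean `nonmemory_icc`
  = 0.2). For memory CpGs the GA-stamped change itself persists: the GA
  term appears identically in cord and postnatal values, sized so the
  expected cross-subject correlation is `memory_icc` (mean 0.85). A shared
  intercept alone cannot reach 0.85 once the cord-only GA variance is
  planted at 4×SE (the correlation is bounded near 0.67), and an intercept
  large enough to approach it would swamp the EWAS residual and make
  memory CpGs undetectable — persistence *of the GA effect* is also what
  the term epigenetic memory denotes. Per-CpG target correlations are
  drawn from Beta distributions (concentration 20 for memory CpGs, 10
  otherwise): real paired-correlation histograms are continuous, and a
  two-point world makes the decile-trend criterion unidentifiable.
* `frac_memory = 0.08` (≈ the observed 2093/27619), `frac_linked = 0.15`,
  `frac_discordant_promoter = 0.34` (≈ 84/(84+165)); expression links are
  linear on log2 expression vs logit methylation (`link_scale_log2 = 1`,
  noise SD 0.5, giving absolute correlations around 0.5–0.7 at n = 55).
* Manifests: toy genome, one chromosome per ~1000 CpGs, strictly
  increasing positions; GA CpGs mildly Shore-enriched (~1.4-fold);
  ReprPC/PromBiv annotation odds scale as
  `1 + (knob − 1) × persistence`, so the knob at 1 is an exact null;
  a fraction of unlinked expression probes is placed just outside the cis
  window to exercise the matcher boundary.

What a green test does *not* establish: the generator has no probe-type
chemistry, no dye bias, no genomic autocorrelation beyond shared gene
labels, a single categorical batch shift, complete data (no missingness),
and Gaussian logit noise. Passing recovery tests validates the pipeline's
statistics, not its robustness to artifacts the generator does not emit.

## Numerical choices

* RNG: base Mersenne–Twister; stage seeds are design seed + fixed offsets
  (cohort +0, methylation +1, expression +2, manifests +3), making each
  stage independently reproducible and the dataset byte-identical per seed.
* The multi-probe OLS uses one QR decomposition of the shared design and
  matrix products for all probes; coefficients match `lm()` to 1e-10 and
  rank deficiency aborts naming the collinear columns.
* BH is the step-up rule computed by cumulative minima; ties are resolved
  by stable sort (no effect on values).
* Degenerate interval-check inputs (zero-variance differences) report
  p = 1 with a flag instead of erroring.
* Beta validity is `[0, 1)`: the +100 offset in M/(U+M+100) makes 1.0
  unreachable, so a stored value of exactly 1 is treated as corrupt.
* Tiny cohorts can make the full Model-2 pilot design singular; the
  generator then falls back to the unadjusted-slope SE for effect sizing.

## Known limitations

Postnatal-blood EWAS is not a distinct operation (run `fit_ewas` on
postnatal rows). The probe-filtering stage consumes normalized betas;
background correction, BMIQ and array QC belong upstream. DAVID/EASE and
the birth-weight SD-score reference program are out of scope (SD scores are
consumed as given). Cross-cohort CpG-list comparisons are not implemented.
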