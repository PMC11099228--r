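---
title: "Methods: two-sample MR mediation along the gut-lung axis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR mediation along the gut-lung axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axismr)
```

## The problem

Gut microbiota composition is associated with lung-cancer risk, plausibly
through immune mechanisms (the "gut-lung axis"). Observational associations
are confounded; Mendelian randomization (MR) uses genetic variants as
instrumental variables to estimate causal effects from GWAS summary
statistics alone. `axismr` implements a complete two-sample MR *mediation*
workflow: it first estimates the total effect of an exposure (a microbial
taxon abundance) on a disease outcome, then asks how much of that effect is
transmitted through a candidate mediator (an immune-cell phenotype).

Throughout, per-SNP quantities are the exposure association
$\hat\gamma_j$ (SE $\sigma_{\gamma j}$) and the outcome association
$\hat\Gamma_j$ (SE $\sigma_{\Gamma j}$), aligned to the same effect allele.

## Instrument selection

`select_instruments()` composes the standard cascade:

1. **Thresholding** at `iv_p_threshold` (default 1e-5 for microbiota and
   immune-cell exposures; 5e-8 when a disease outcome serves as the
   exposure in reverse MR).
2. **Greedy LD clumping** against a user-supplied r² matrix: candidates are
   scanned by ascending p-value and accepted only if r² < `clump_r2`
   (default 0.001) with every accepted SNP within `clump_window_kb`
   (default 10,000 kb) on the same chromosome. SNP pairs absent from the
   matrix are treated as independent, which matches the generator's
   post-clumping world; real analyses should supply a reference-panel
   matrix.
3. **Outcome-association exclusion**: instruments with outcome p <
   `outcome_assoc_p` (default 5e-5) are removed, as are instruments absent
   from the outcome dataset (counted separately).
4. **Weak/rare filters**: per-SNP F = (β/se)², the squared Wald z, must
   exceed `f_min` = 10 strictly; minor allele frequency must be at least
   `maf_min` = 0.01.
5. **Harmonization**: outcome effects are aligned to the exposure's effect
   allele (sign flip for swapped alleles, strand complement resolved
   first); palindromic A/T and C/G SNPs are dropped unconditionally — no
   frequency-based rescue is attempted, because allele frequencies near 0.5
   make such rescues unreliable.

The per-stage survivor counts are attached to the result so that no SNP
disappears silently.

## Estimators

* **IVW** — weighted zero-intercept regression of $\hat\Gamma$ on
  $\hat\gamma$ with weights $1/\sigma_\Gamma^2$. The default variance model
  is multiplicative random effects: the fixed-effect SE is scaled by
  $\max(1, \sqrt{Q/(k-1)})$, which equals the fixed model when Cochran's
  $Q \le k-1$ and never undershoots it. P-values use the normal reference.
* **MR-Egger** — the same regression with a free intercept after orienting
  all $\hat\gamma_j \ge 0$; the intercept estimates directional pleiotropy.
  SEs carry the same overdispersion floor; slope and intercept p-values use
  the t distribution with $k-2$ df. With the floor in place a zero-residual
  fit retains the fixed-weights SE, so exact 3-point fixtures recover the
  intercept exactly but do not produce a zero p-value.
* **Weighted median** — the ratio interpolated at cumulative normalized
  inverse-variance weight 1/2 (ratio variance
  $\sigma_{\Gamma}^2/\hat\gamma^2$, the first-order delta approximation;
  the second-order term is omitted). SE by seeded parametric bootstrap.
* **Mode-based** (weighted and simple) — argmax of a Gaussian-kernel
  weighted density of the ratios with bandwidth `bandwidth_factor` times
  the modified-Silverman scale $0.9\,\min(\mathrm{sd},\mathrm{mad})\,
  k^{-1/5}$; SE by seeded bootstrap. The "simple" mode uses uniform
  weights; we read the occasionally-seen label "sample mode" as this
  estimator.
* **MV-IVW** — weighted least squares of $\hat\Gamma$ on the matrix of
  exposure effects, no intercept, with the same overdispersion floor and
  t-based p-values ($k-m$ df). Instruments are the union of the
  per-exposure selections, jointly re-clumped by best p-value, and every
  retained SNP must be observed in all datasets.

All estimators are equivariant under joint per-SNP sign flips, so the
harmonization orientation cannot change an estimate.

## The four-step mediator screen

For exposure X, mediator M, outcome Y, with total effect $\beta$ (UVMR IVW
of X on Y):

1. $\beta_1$: UVMR of X on M; keep if p < 0.05 and no pleiotropy flag.
2. $\alpha$: UVMR of M on Y; same rule.
3. Sign consistency: keep iff $\mathrm{sign}(\beta_1\alpha) =
   \mathrm{sign}(\beta)$.
4. $\beta_2$: MV-IVW of M on Y adjusted for X; keep if its p < 0.05.

The mediated effect is $\beta_1\beta_2$ and the mediation proportion
$(\beta_1\beta_2)/\beta$, on the log-odds scale (never on ORs). The
reported mediation p-value is the multivariable p of $\beta_2$; a
delta-method p for the product ($\mathrm{var} \approx \beta_2^2
s_{\beta_1}^2 + \beta_1^2 s_{\beta_2}^2$) is computed as a labeled
extension. Candidates with a proportion outside [0, 1] are retained but
flagged `inconsistent_mediation` rather than dropped — a negative or
super-unity proportion is a finding about the pathway, not a reason to
hide it. Benjamini-Hochberg q-values are appended to primary IVW results;
the FDR family is the outcome by default and is configurable, since "all
IVW results" is ambiguous once several outcome subtypes are analyzed.

Pleiotropy gating follows the usual decision rule: heterogeneity is flagged
when Cochran's Q has p < 0.05; pleiotropy when the Egger intercept p or the
MR-PRESSO global p falls below 0.05, and pleiotropy invalidates the causal
claim for that pair. Inside the high-throughput screens the Egger intercept
test always runs; MR-PRESSO participates when `use_presso` is set (it
dominates runtime in simulation studies, and its global test targets the
same violation as the intercept test).

## MR-PRESSO

The global test compares the observed leave-one-out residual sum
$\sum_j w_j(\hat\Gamma_j - \hat\beta_{(-j)}\hat\gamma_j)^2$ with its
distribution under `n_sim` parametric draws
$\gamma^*_j \sim N(\hat\gamma_j, \sigma_{\gamma j})$,
$\Gamma^*_j \sim N(\hat\beta_{(-j)}\hat\gamma_j, \sigma_{\Gamma j})$
(defaults: 1,000 draws). Per-SNP outlier p-values rank each observed
weighted residual against its simulated counterparts, Bonferroni-compared
to 0.05 across SNPs. When no simulated sum reaches the observed one the
global p is reported as a bound (below 1/`n_sim`). The distortion test in
the original algorithm is underdescribed in secondary sources; this package
implements a transparent variant — the percentage shift between all-SNP and
outlier-removed IVW estimates is compared with the shifts induced by
removing 1,000 random same-size subsets — and labels it as such. All three
stages are seeded and bit-reproducible.

## The synthetic study generator

`generate_study()` draws per-SNP instrument effects
$\gamma_j \sim N(0, \texttt{effect\_sd}^2)$ for exposure SNPs and
$\delta_j$ for mediator SNPs, propagates them structurally
($\beta_1\gamma_j$ to the mediator; $(\texttt{direct} +
\beta_1\beta_2)\gamma_j$ + pleiotropy to the outcome; $\beta_2\delta_j$
for mediator SNPs), and adds sampling noise with
$se = 1/\sqrt{2n\,\mathrm{eaf}(1-\mathrm{eaf})}$. Binary outcomes are
simulated directly on the log-odds scale with an *effective* sample size —
two-sample MR consumes only summary statistics, so individual-level
logistic sampling would add cost without changing what the estimators see.

Default conditions, chosen once as the emulated study design:

* exposure GWAS n = 7,738 (a shotgun-metagenomics microbiome cohort);
* mediator GWAS n = 3,757 (an immune-phenotype cohort);
* outcome effective n = 2,861, i.e. a small-cell lung-cancer case-control
  study of 717 cases / 313,476 controls collapsed by
  $n_\mathrm{eff} = 4/(1/\mathrm{cases} + 1/\mathrm{controls})$;
* `effect_sd` = 0.15 and eaf in (0.05, 0.5), which after the 1e-5 selection
  leaves ~40-60 instruments per trait, all with F well above 15;
* decoys: 5% palindromic SNPs and 2% low-MAF SNPs, which exercise the
  harmonization and MAF filters;
* directional pleiotropy, when enabled, acts along the exposure-increasing
  allele (a constant applied in arbitrary allele orientation would cancel
  under Egger's reorientation and be undetectable by construction);
* LD is not simulated — instruments emulate post-clumping data; a
  block-diagonal injector exists solely to test the clumping code.

The outcome size deserves a note. When the outcome GWAS is much larger
(effective n near 10,000 or above) and the true total effect is
substantial, valid instruments become genuinely outcome-associated at the
5e-5 exclusion threshold: the filter then removes the strongest instruments
and, worse, retains borderline SNPs preferentially when their outcome noise
opposes the true effect, attenuating IVW toward zero — increasingly so as
the outcome GWAS grows. The small outcome default keeps the filter in the
regime where it behaves as intended; the residual attenuation at that
default is quantified by the recovery tests, which run the full cascade on
200 seeded replicates.

What the generator does *not* emulate: realistic allele-frequency spectra,
LD between instruments, sample overlap between the two samples, and
population stratification. Passing tests therefore validate the estimators
and the decision logic, not robustness to those real-data complications.

## Numerical and design choices

* Confidence intervals are $\hat\beta \pm 1.959964\,se$ with the constant
  fixed, so output is digit-stable across platforms; odds ratios are
  $\exp(\hat\beta)$.
* All bootstraps and simulations take explicit seeds, and the internal RNG
  scope is isolated so library calls never perturb the caller's RNG state.
* Summary tables are written with 17 significant digits; a write/read round
  trip reproduces every double exactly.
* Wald ratios with $\hat\gamma = 0$ are estimation errors rather than
  infinities; estimators state their minimum instrument counts (2 for IVW,
  3 for Egger/median/mode, 4 for MR-PRESSO, m+1 for MV-IVW).
* The exclusion step runs after clumping and before harmonization; the
  original workflow's ordering is not documented, and this choice is
  recorded as ours.
* In reverse MR (outcome as exposure), disease-associated SNPs that act on
  the disease *through* the studied exposure are usually eliminated by the
  outcome-association filter, which is what prevents a one-directional
  causal pair from being spuriously flagged bidirectional in the pipeline
  tests.

## Known limitations

* The recovery simulations show a persistent downward attenuation, on the
  order of several percent, of all effect estimates under the full
  selection cascade (winner's curse from same-sample instrument selection
  plus the exclusion-filter truncation described above); the recovery test
  documents its size at the default conditions. The mediation *proportion*
  is more robust because numerator and denominator attenuate together.
  Shrinking the instrument-effect scale does not remove the attenuation:
  smaller effects trade exclusion truncation for more winner's curse. This
  is a property of the screening design, not of the estimator
  implementations, which recover truth to well under 1% in the
  Monte-Carlo tests that bypass selection.
* Instrument counts per trait (tens) match microbiome/immune GWAS practice;
  the estimators are not tuned for the thousands-of-instruments regime of
  highly polygenic exposures.
* No proxy-SNP lookup, Steiger directionality filtering, or radial MR; the
  screen is deliberately the classical five-estimator battery plus
  MV-IVW.

## Problem sizes used in the test suite

Simulation-based tests run at 100+100 instrument SNPs per study, with
200 replicates for recovery properties, 2,000 for null calibration of the
IVW/Q/Egger tests, and 200 seeded MR-PRESSO runs at 1,000 simulations
each; oracle-equivalence suites cover 1,000 random instrument sets
(weighted median), all 1,024 sign patterns of a 10-element p-vector
(Benjamini-Hochberg), and all 0/0.5-grid LD matrices up to 5 SNPs plus
1,500 random larger ones (clumping). These sizes are the package's chosen
balance between statistical resolution and a test suite that runs in
about a minute.
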