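---
title: "Identifying genetically unrelated comorbidities with equivalence testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying genetically unrelated comorbidities with equivalence testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equicomorb)
library(data.table)
```

## The scientific problem

Patients with a severe index disorder such as schizophrenia accumulate many
comorbid diagnoses. Most comorbidity reflects shared genetic liability, but
some of it is a *consequence* of the disorder or its treatment — adverse drug
effects, behavioral sequelae, environmental exposure. Those consequence-driven
comorbidities are the clinically actionable ones: they can, in principle, be
modified regardless of a patient's genetic risk.

`equicomorb` implements a pipeline that separates the two kinds of
comorbidity using only routinely collected data:

1. **Phenome-wide comorbidity.** In each health system, every phenotype
   (phecode) is regressed on index-disorder case status (and vice versa) by
   logistic regression with demographic and utilization covariates. The two
   directional Wald Z statistics are combined into one site-level Z, and site
   Zs are combined across systems by a shared-case-weighted average
   $Z_C = (\sum_s Z_s N_s)/(\sum_s N_s)$, converted to two-sided normal
   p-values and Bonferroni-corrected over the tests performed.
2. **Polygenic-score PheWAS.** For every phecode, case status is regressed on
   a standardized polygenic risk score (PRS) for the index disorder, with
   index cases removed so that associations reflect genetics rather than
   diagnosis. Site results are combined by fixed-effect inverse-variance
   weighting.
3. **Equivalence testing.** For each significant comorbidity, the TOST (two
   one-sided tests) procedure asks whether the PRS distributions of cases and
   controls are *significantly equivalent* within Cohen's d bounds of
   ±0.2. Per-site TOST p-values are combined with Fisher's method
   ($\chi^2 = -2\sum\ln p$, df $=2k$) and Bonferroni-corrected over the
   phecodes tested at all sites.
4. **Classification.** Phenotypes are tiered: significantly comorbid and
   significantly equivalent; additionally non-significant PRS association
   after correction; additionally PRS p > 0.05 (the headline set — comorbid,
   well-powered, and with no discernible genetic signal); and separately,
   PRS-associated phenotypes that are not comorbid.

## Case, control and missing status

Status assignment follows standard phecode practice. A patient is a **case**
for a phecode with occurrences on at least two distinct calendar dates
("2 or more" is read as two *independent instances*: same-day repeats of
codes mapping to one phecode collapse). A single instance makes the patient
**missing** — present once is too little evidence for caseness but too much
for clean controlhood. A patient with no occurrence is a **control** unless
any phecode in the phecode's exclusion range occurred at least once, in
which case the would-be control is removed. Exclusion removal never demotes
a case. ICD-9 and ICD-10 codes map through their own vocabulary's entries
only; no cross-mapping is attempted.

Covariates derived per patient: current age, EHR age (age at last visit),
coded sex and race as factors with the modal category as reference
("unknown" is always a retained level), record length (days between first
and last code), and the natural log of the number of unique phecodes plus
one. The unique-phecode count includes single-instance codes — the count is
about utilization, not diagnostic certainty — and the +1 offset tolerates
zero-code patients; both choices are configurable.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `minCases` | 20 | logistic Wald statistics destabilize below ~20 cases; fits under the floor are skipped with a reason code |
| direction rule | `"mean"` | the per-site combination of the two directional Zs; `outcome_direction_only` and `stouffer` are available |
| shared-patient weight $N_{A,B}$ | joint-case count | configurable to joint-analyzable count |
| TOST bounds | d = ±0.2 | the smallest effect size of interest for "no PRS difference" |
| bound scale | `sqrt((sd1^2+sd2^2)/2)` | root-mean-square conversion of d to the raw scale; df-pooled form available |
| TOST variant | Welch | unequal-variance one-sided t tests with Satterthwaite df; pooled-variance variant available |
| `alpha` | 0.05 | family-wise rate for every Bonferroni family |
| `excludeIndexCases` | TRUE | PRS effects measured independent of the index diagnosis |

Bonferroni denominators are always the number of tests actually performed
and are recorded in output metadata, never hard-coded. Boundary p-values
are not flagged (strict inequality). Variance explained is reported as the
Nagelkerke pseudo-R² difference between the full and covariate-only
models, in percent — the convention of the PheWAS ecosystem; it is an
assumption, and a liability-scale alternative could be substituted.

Separation and non-convergence are detected (|log-odds| ≥ 15, SE ≥ 100, or
IRLS non-convergence at tolerance 1e-12) and flagged rather than silently
reported; no Firth fallback is applied by default so that reported effects
are plain maximum-likelihood estimates. Both current age and EHR age enter
jointly despite their collinearity; aliased covariate columns are tolerated
as long as the term of interest is estimable. p-values are never truncated
below the smallest positive double, and exact zeros entering Fisher's
method are clamped there and flagged.

## The synthetic two-site study

All raw EHR/biobank data of this kind are access-restricted, so the package
ships a generator whose defaults define the study conditions used by the
test suite and the acceptance script:

* two sites × 20,000 patients; a standard-normal polygenic score;
* a liability-threshold index disorder: liability $=\sqrt{h^2_s}\,\text{score}
  + \sqrt{1-h^2_s}\,\varepsilon$ with $h^2_s = 0.2$ and a threshold giving a
  coded prevalence of 2% — a typical coded schizophrenia rate in
  health-system samples;
* 40 labeled phenotypes, ten per class: **genetic** (score loading
  g = 0.15 on the phenotype logit), **consequence** (log-odds increment
  c = 1.0 per index-case status, no genetic loading), **mixed** (both),
  **null** (neither); prevalences cycle over {0.05, 0.08, 0.12, 0.15};
* a 100-code **background phenome** (prevalence 0.08, log-odds 1.2 per SD of
  log-utilization). A real phenome holds on the order of a thousand codes,
  so any single pair contributes negligibly to a patient's unique-phecode
  burden. Without the background, the burden covariate would condition on a
  sum dominated by the tested pair itself — a collider that manufactures
  negative comorbidity between independent phenotypes. The background
  restores the real-data regime and gives the covariate its intended
  confounder (utilization) to absorb;
* every phenotype carries a utilization loading b = 0.2 and a small age
  effect; site 2 receives a +0.1 intercept shift;
* cases emit ≥ 2 code events on distinct dates (guaranteed by spaced
  sampling); non-cases emit exactly one event with probability 0.03,
  exercising the missing rule; four decoy phecodes fall in exclusion ranges
  of the first four phenotypes, exercising control removal;
* each site draws from its own random stream derived from (seed, site), so
  regeneration is byte-identical and sites are independent given the
  parameters.

What the generator does **not** emulate: realistic ICD vocabularies and
phecode hierarchies (the toy map is flat), visit-level temporal dynamics,
genotype-level structure (scores are drawn directly), ancestry structure
(PCs are pure noise), and care fragmentation across systems. Passing the
benchmark therefore demonstrates that the statistical machinery recovers
the designed causal contrast under faithful-but-idealized conditions; it is
not evidence about coding behavior or population structure in real EHR
data.

```{r benchmark-small}
cfg <- defaultSimConfig(seed = 1, nPatients = 2000, nPerClass = 2,
                        nBackground = 20)
study <- simulateStudy(cfg)
res <- runStudyAnalysis(study$sites, study$map, indexPhecode = "295.1",
                        minCases = 10)
res$verdicts[!is.na(comorbidP)][1:5,
  .(phecode, comorbidP = signif(comorbidP, 2),
    prsMetaP = signif(prsMetaP, 2), equivalent, tier)]
```

(The chunk above runs a deliberately small configuration so the vignette
builds quickly; the benchmark proper uses the defaults.)

## Problem sizes used by the shipped checks

The package's own validation runs at sizes chosen to make the Monte Carlo
error small relative to the properties being asserted: null calibration of
the directional Z over 200 replicates of n = 5000; a 200-pair
Kolmogorov–Smirnov check of the site-Z null distribution at n = 5000;
PRS type-I error over 1000 replicates; TOST size at the equivalence bound
over 2000 replicates of 500 per arm; and one full default benchmark run
(2 × 20,000 patients) for end-to-end tier recovery, where sensitivity and
specificity for the consequence class are both required to reach 0.8.

## Design choices on genuinely open points

* **Direction combination.** The per-site "combined Z" of the two
  directional regressions defaults to their arithmetic mean: both
  directions carry information, the statistic stays on the Z scale, and for
  exchangeable phenotypes the two directions agree closely (a property the
  tests assert). A one-direction rule and a Stouffer rule are selectable.
* **Shared patients.** $N_{A,B}$ is the joint-*case* count — the patients
  who actually carry both diagnoses are the ones a comorbidity estimate is
  about — with the joint-analyzable count available.
* **TOST inputs.** Equivalence is tested on raw standardized scores of the
  PheWAS case/control sets (index cases excluded), not on covariate
  residuals; the module runs from group summary statistics so
  pre-summarized data are equally usable.
* **Equivalence Bonferroni denominator.** Taken from the number of phecodes
  actually entering the cross-site equivalence meta-analysis, reported in
  the output, never hard-coded.
* **Single-site pairs.** Pairs testable at only one site retain that site's
  Z, flagged `singleSite`, rather than being dropped.

## Known limitations

Logistic comorbidity Zs between overlapping patient sets are not fully
independent across pairs; the Bonferroni control is conservative. The
liability/logit generator cannot probe miscoding, diagnostic substitution,
or ancestry confounding. TOST equivalence is relative to the chosen bounds:
d = ±0.2 declares "no difference of clinical interest", not "no difference".
Fisher's method assumes independent per-site p-values, which holds across
health systems but would not within one. The tier classification inherits
every upstream threshold; phecodes missing from any input land in `OTHER`
with an explicit flag rather than being silently dropped.
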