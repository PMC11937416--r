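---
title: "Deriving and analysing drug-response phenotypes from longitudinal EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and analysing drug-response phenotypes from longitudinal EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxehr)
```

## The problem

Randomised trials measure drug response directly; biobank-linked
electronic health records (EHRs) do not. What they offer instead is a
prescription history and a sparse, irregular series of biomarker
measurements per participant. `pgxehr` turns such records into
drug-response phenotypes — the change in a biomarker (LDL-C, HbA1c,
systolic blood pressure, heart rate) between a window before and a
window after the first prescription of a drug — and provides the
statistical machinery to analyse their genetics: per-variant and
rare-variant burden association, a drug-naive negative-control scan,
power transfer across ancestries, and polygenic-score analyses.

Because the real data these designs target (UK Biobank primary care,
All of Us OMOP extracts) are access-controlled, the package ships a
synthetic-EHR generator that reproduces the statistical structure the
analyses assume. All tests run against it; what that does and does not
demonstrate is discussed at the end.

## The longitudinal biomarker model

The generator and the bias theory share one model. A biomarker level at
time $t$ is

$$Y_t = \beta_0 G_0 + \beta_E E_t + \gamma_E G_E E_t +
        \beta_D D_t + \gamma_D G_D D_t + \epsilon_t$$

with $G$ the allele dosage (one variant plays all three genetic roles,
$G_0 = G_E = G_D$, unless configured otherwise), $E_t$ a standard-normal
environment with inter-visit correlation $\mathrm{corr}(E_{t_1}, E_{t_0})
= corr_E$, $D_t$ the drug indicator, and $\epsilon_t$ measurement noise
with SD $\sigma_\epsilon$. Treated participants have $D = 0$ at baseline
and $D = 1$ post-treatment; drug-naive controls have $D = 0$ at both
visits.

Differencing the two visits removes every time-constant term:

$$\Delta Y = Y_{t_1} - Y_{t_0} = \beta_D + \gamma_D G_D + \delta_{01},
\qquad
\mathrm{var}(\delta_{01}) = 2\sigma_\epsilon^2 +
  (\beta_E^2 + \gamma_E^2)\, 2 (1 - corr_E).$$

Regressing $\Delta Y$ on dosage therefore estimates the pharmacogenetic
effect $\gamma_D$ without any contribution from the baseline genetic
effect $\beta_0$ — this is why the association functions default to
**no baseline adjustment**.

### The variance budget

The trait variance at baseline is normalised to 1 by solving
$\sigma_\epsilon$ from

$$\beta_0^2 \cdot 2\,maf(1-maf) + \beta_E^2 + \gamma_E^2 +
  \sigma_\epsilon^2 = 1.$$

This standardisation is what makes the bias coefficient below
interpretable; `longitudinal_model_params()` enforces it to 1e-9 and
refuses parameter sets that overspend the budget. The environment
distribution behind the bias formula is not uniquely pinned down by the
formula itself; the standard-normal, unit-variance convention is adopted
here and verified empirically by the Monte-Carlo machinery rather than
asserted as an algebraic identity.

## Baseline-adjustment bias

Adjusting a change score for the baseline level re-introduces the
baseline genetics. Under the standardised model the spurious component
added to the genotype slope is approximately

$$C \cdot \beta_0, \qquad
  C = 1 - (\beta_E^2 + \gamma_E^2)\,\mathrm{corr}(E_t, E_0).$$

`bias_coefficient()` evaluates the closed form; `verify_bias()` /
`verify_bias_grid()` check it by simulation: drug-naive data are
generated, the change score is regressed on genotype with and without
the baseline covariate, and the mean adjusted-slope excess is compared
with $C\beta_0$ within 3 Monte-Carlo standard errors.

Two numerical points matter. First, the closed form is an
approximation: the exact population slope under this model is
$\beta_0\,(1 - (\beta_E^2+\gamma_E^2)\,corr_E /(1 - \beta_0^2
\mathrm{var}(G)))$, which differs from $C\beta_0$ by a term of order
$\beta_0^3 \mathrm{var}(G)$. The verification grid therefore uses
moderate baseline effects ($\beta_0 \le 0.35$ SD per allele, the regime
the formula is meant for), where the approximation error is well below
the Monte-Carlo resolution. Second, `corr(E_t, E_0)` is taken as the raw
environmental correlation, not an error-attenuated version; the
empirical agreement across the test grid supports that reading.

The default verification grid is 6 parameter points at $n = 2000$
participants and 120 replicates each — chosen as the smallest design
whose Monte-Carlo SE (~0.003 in slope units) still cleanly separates the
theoretical biases (0.07–0.19) from zero.

## Cohort extraction

`build_cohort()` applies the QC cascade in a fixed order, counting
removals per step in an exclusion ledger that must reconcile exactly
(initial n − removals = final cohort):

1. baseline and post-treatment measures available in their windows;
2. an unrelated primary-care record at least 2 years before the start
   (a provider switch would otherwise masquerade as a first
   prescription);
3. a related-class prescription after the post measure (continued
   treatment);
4. no treatment change between start and post measure — same-class
   non-allowed medication, a combination product (always), or a dose
   change when the scenario forbids it;
5. prescription completeness at or above threshold;
6. baseline at or above the biomarker minimum (e.g. LDL-C ≥ 2 mmol/L);

then same-class medication within a year of initiation, the add-on
policy, and a minimum per-drug group size of 20.

Key tunables (defaults encode the two scenarios):

| parameter | stringent | lenient |
|---|---|---|
| baseline window (days) | [-100, +7] | [-365, +7] |
| post window (days) | [100, 365] | [100, 730] |
| completeness threshold | 0.60 | 0.30 |
| dose change | excluded | allowed, post-window doses averaged |
| concomitant related drugs | monotherapy only | allowed add-ons flagged as covariates |

The post-window start of 100 days suits drugs with delayed biomarker
effect (statins, metformin); 60 days is the conventional choice for
antihypertensives and beta blockers. Aggregation over multiple
measures in a window is the default (`average_all`), with
`closest_single` available.

Choices the data sources leave open, fixed here and configurable:

- **Completeness bins** are anchored at the first prescription with a
  61-day width; the final partial bin counts iff at least half a bin
  long; the denominator runs to the post-measure date (not the window
  end), so completeness reflects the actually-observed follow-up.
- **Tie at equal |offset|** in `closest_single`: the earlier
  (pre-treatment) measure wins — the reading that cannot be
  contaminated by the drug.
- **Baseline window start** of 100 days (not "three months"), since
  that is the operative analysis description.
- **HbA1c units** are harmonised with the NGSP↔IFCC master equation
  (`hba1c_ifcc_to_ngsp()`), applied before plausible-range filtering.
- **Plausible ranges** are plain configuration; the synthetic default
  for an LDL-C-like trait is [0.5, 20] mmol/L.
- **Dose covariate**: drug type enters as a categorical covariate and
  dose as numeric mg (parsed from the description string; per-drug
  median imputation is a separate, flagged step).

## Association analysis

Two response scales are first-class: absolute ($Y_{t_1} - Y_{t_0}$) and
log-relative ($\log Y_{t_1} - \log Y_{t_0}$); which one a variant acts
on linearly is a priori unknown, so both are scanned.
`associate_variant()` fits OLS of the response on dosage plus
covariates (sex, age at start, time to post measure, drug type/dose,
optional PCs supplied as columns — never computed internally), with
Wald normal p-values (GWAS convention; exact-t offered for small n).
The minimum analysable cohort defaults to 500 in pipeline use;
functions accept a lower floor for small designed experiments.
Bonferroni thresholds (5e-8 genome-wide, 0.05/#genes for burden) are
the only multiplicity layer.

Rare-variant burdens sum qualifying minor-allele dosages (MAF < 1%)
per gene and are fitted on the inverse-normal-transformed outcome
(ranks to normal quantiles at $(r - 0.5)/n$, average ranks for ties).
Whole-genome mixed-model machinery (LOCO, LD clumping, SKATO) is
deliberately out of scope: those are existing external tools, not part
of the method defined here.

The drug-naive control scan (`control_change_scan()`) reruns the
identical machinery on untreated participants with two measures spaced
6 months to 3 years apart. It is the negative control: pharmacogenetic
signals must vanish there, and any signal appearing only under baseline
adjustment is the bias at work.

## Power analysis

Power at two-sided level $\alpha$ with non-centrality $\lambda$ is

$$\mathrm{power}(\alpha, \lambda) =
 \Phi(\sqrt{\lambda} - c) + \Phi(-\sqrt{\lambda} - c), \qquad
 c = \Phi^{-1}(1 - \alpha/2),$$

and $\lambda$ transfers a discovery result to a target sample size and
allele frequency:

$$\lambda = \frac{N}{n_{obs}} \cdot
  \frac{\beta_{obs}^2}{se_{obs}^2} \cdot
  \frac{MAF(1-MAF)}{MAF_{obs}(1-MAF_{obs})}.$$

When a published table prints beta and p but not se, `se_from_summary()`
recovers it as $|\beta|/\Phi^{-1}(1-p/2)$ (evaluated on the upper tail
so extreme p-values do not underflow). `required_n()` searches sample
sizes on a 500-grid (the convention in published transfer analyses;
offset grids of the form 501, 1001, … are supported via a grid-origin
parameter) and also reports the continuous root. Reproducing published
required-N values from printed summary statistics is exact when the
printed beta/p pair determines the se the authors used; where it does
not (rounded p-values), the derived values can differ by a grid step or
two, which is why the package reports the un-gridded root alongside.

```{r power}
inp <- power_inputs(alpha = 5e-8, n_obs = 18753, beta_obs = 0.232,
                    p_obs = 1.11e-28, maf_obs = 0.059,
                    maf_target = 0.105)
required_n(inp)$n_required
```

## PRS analysis

`compute_prs()` applies per-variant weights (read from a minimal
scoring file, or taken from the simulator's true baseline effects —
externally trained score downloads are out of scope) and standardises
within the analysed cohort. `prs_response_association()` reports the
native-unit and SD-standardised effect per SD of PRS.

The central qualitative phenomenon: when the drug effect is
multiplicative on the raw scale, a baseline-raising PRS produces a
*negative* absolute-scale response effect (higher starting levels drop
more) and a *null* log-scale effect — and adjusting the absolute
response for baseline flips its sign. The package demonstrates the
model-misspecification mechanism only; whether real PRS-response
associations also carry biology is a question the data cannot settle
here. `variance_explained()` provides the nested-R² ledger
(PRS-adjusted baseline, then + PRS), and `stratified_response_grid()`
the quantile-by-quantile mean-response tiles with equal-count bins
(ties broken by stable participant order) and small tiles masked.

## What the synthetic generator does and does not emulate

It does: irregular prescription intervals with skips, dose changes and
add-on classes; sparse baseline/post measures (baseline offsets uniform
on a configurable window; post offsets log-normal with median ≈ 200
days, matching typical follow-up medians); drug-naive controls with two
spaced measures under an identical schema; genotypes in
Hardy-Weinberg proportions; biomarkers from the longitudinal model with
the exact variance budget; a multiplicative (log-link) drug-effect
regime.

It does not: visit processes that depend on health state
(missing-not-at-random), real coding vocabularies (BNF/Read/OMOP are
replaced by a configurable code map), ancestry structure or
relatedness, polypharmacy across medication groups, or secular trends.
Passing tests therefore demonstrate the *statistical* correctness of
the pipeline under the stated model, not robustness to every real-EHR
pathology.

## Problem sizes and determinism

The test suite simulates at n = 1e5 where moments are compared with
analytic values (Monte-Carlo error scales as $n^{-1/2}$), 1000
replicates of n = 400 for type-I calibration, 100 replicates for CI
coverage, and the 6-point bias grid at n = 2000 × 120 replicates —
sizes picked so each check resolves its target quantity comfortably
within Monte-Carlo error. Every stochastic function takes an explicit
seed, derives sub-seeds from a deterministic integer stream, and never
reads the clock; rerunning any pipeline with the same configuration
reproduces outputs byte for byte.

## Known limitations

- The exclusion cascade assigns each participant to the *first* failing
  step, so ledger counts depend on step order (the order is fixed and
  documented above).
- First-prescription dates are taken at face value: someone already on
  the drug before their record window opens is indistinguishable from a
  new user (mitigated, not removed, by the prior-record rule).
- The completeness denominator choice (post-measure date) makes
  completeness incomparable across participants with very different
  follow-up lengths; it is an adherence proxy, not a measure.
- The bias formula's accuracy degrades for large baseline effects
  ($\beta_0 \gtrsim 0.5$ SD/allele) where the neglected
  $\beta_0^3$ term becomes visible; the verifier reports disagreement
  rather than hiding it.
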