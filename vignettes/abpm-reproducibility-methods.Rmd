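---
title: "Methods: within-individual variability of sequential ABPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-individual variability of sequential ABPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abpmvar)
```

## The measurement problem

A 24-h ambulatory blood pressure (ABPM) session yields day, night and 24-h
mean pressures for one occasion. Repeating the session weeks apart gives
values that differ through physiological variation and measurement
technique, even in individuals whose *true average pressure* — the
hypothetical error-free mean — is stable. This package quantifies that
within-individual, between-session variability and its consequences:
uncertain hypertension classification, unstable nocturnal-dipping labels,
and the sample sizes needed to see true change.

## The variability model

All estimators here assume a multiplicative error model: the session value
for individual $i$, session $j$ is

$$y_{ij} = \exp(\mu_i + \sigma_w \varepsilon_{ij}), \qquad
\varepsilon_{ij} \sim N(0, 1) \text{ i.i.d.},$$

so the within-individual SD is proportional to the individual's mean level.
This is why the analysis works on logarithms: $\log y_{ij}$ has constant
within-individual variance $\sigma_w^2$, and the pooled within-subject
variance of the logs,

$$s_w^2 = \frac{\sum_i \sum_j (x_{ij} - \bar x_i)^2}{\sum_i (m_i - 1)},
\qquad x_{ij} = \log y_{ij},$$

estimates it without reference to the mean levels. `cov_within()` maps this
to a percent coefficient of variation by the exact lognormal relation
$\mathrm{CoV} = 100\sqrt{e^{s_w^2} - 1}$. Alternatives in circulation
($100\,s_w$, $100(e^{s_w}-1)$) agree with it to under 0.1 percentage point
at the magnitudes seen in blood pressure work (CoV 4–12%); the exact
mapping was chosen because it is the one the scale-invariance and
simulation round-trip properties hold for exactly. The first-order
agreement $\mathrm{CoV}/100 \approx s_w$ has relative error $\approx
\mathrm{cv}^2/4$, about 0.5% at CoV 14%.

Only individuals with at least two sessions contribute; singletons are
excluded and counted, and excluding them provably never changes the
estimate. Degrees of freedom are $\sum_i (m_i - 1)$, i.e. total retained
sessions minus retained individuals.

**Confidence intervals.** The default is the delta-method standard error of
a pooled SD, $se(s_w) = s_w/\sqrt{2\,df}$, with normal quantiles applied on
the $s_w$ scale and the bounds mapped through the CoV transform. A
chi-square pivot on $df \cdot s_w^2/\sigma^2$ is available
(`ci_method = "chisq"`); at the degrees of freedom of a full cohort
(df > 1000) the two are indistinguishable at reporting precision, and the
test suite verifies 93–97% empirical coverage of the delta interval at
df = 200. When $s_w = 0$ the interval degenerates to (0, 0).

**Group comparison.** No standard test for equality of two
within-individual CoVs is universally agreed; `compare_cov()` therefore
reports two labelled verdicts — non-overlap of the individual confidence
intervals (conservative) and an asymptotic z-test on the $s_w$ values with
the same standard errors. With zero $s_w$ in either group the z-test is
undefined and only the interval verdict is returned. Individuals enter
group estimates by their *baseline* hypertensive status (daytime systolic
mean of the first session ≥ 135 mmHg, ties hypertensive), a fixed
classification that does not migrate with later sessions.

## Session summarization conventions

Raw cuff readings are split into night — timestamps in the half-open
diary interval $[\text{sleep onset}, \text{wake})$, so a reading exactly at
wake time is daytime — and day (everything else in the session span).
Windowing uses absolute datetimes throughout, so night windows spanning
midnight need no special handling, and shifting every timestamp and diary
time by a common offset provably leaves every summary unchanged. There is
deliberately no clock-time fallback when a diary entry is missing: a
missing diary is an error, because silently substituting fixed hours would
blur the day/night contrast the analysis is about.

The 24-h mean is the unweighted mean of **all** valid readings. Since the
device cadence is denser by day (every 30 min from 07:00–22:00, hourly
otherwise; 30 vs 9 scheduled readings), this pools day and night with
roughly 30:9 weights rather than the 16:8 h clock weights; it is the
simplest reading of a "24-h mean" from a device export and is the
convention the simulator mirrors (below).

Validity screening defaults (SBP 60–260 mmHg, DBP 40–150 mmHg, HR 30–200
bpm, SBP > DBP; at least 14 valid day and 7 valid night readings) are an
explicit convention of this package — device-editing criteria for such
trials are rarely published — and every bound is configurable through
`validity_rules()`. Sessions failing the minimums are flagged and excluded
downstream but never deleted.

**Dipping boundaries.** The clinical literature is not internally
consistent about edge cases (a fall of exactly 10%, or between 0 and 1%).
The conventions here are explicit: `dip_pct < 0` reverse, `[0, 10)`
reduced, `[10, 20]` normal, `> 20` extreme; the binary dipper rule is
`dip_pct >= 10`, making the two schemes exactly consistent
(\{normal, extreme\} = dipper). The tests enforce this collapse on $10^5$
random day/night pairs.

## The cohort simulator

The original trial data behind this design are not publicly available, so
the package carries a first-class generator (`simulate_cohort()`)
emulating their structure; it is the substrate for all calibration and
operating-characteristic checks.

Per individual, covariates and the latent true means of six ambulatory
parameters plus PWV are drawn from one joint Gaussian model on the log
scale (a Gaussian copula — equivalently, linear covariate effects on the
log-mean with back-solved coefficients). Defaults:

* **Templates**: CRESSIDA, n = 159, 5 sessions (weeks 0, 3, 7, 11, 15);
  Fruit & Veg, n = 48, 5 sessions (weeks 0, 6, 17, 28, 39); MARINA,
  n = 294, 3 sessions (months 0, 6, 12) — 501 individuals, 1917 sessions.
* **Covariates**: age 53.4 ± 8.0 y; 61% female; 80% white ethnicity; BMI
  26.0 ± 3.9 kg/m²; 2% on antihypertensives.
* **Baseline marginals (mean ± SD)**: SBP day/night/24-h 130 ± 13 /
  110 ± 14 / 125 ± 13 mmHg; DBP 79 ± 8 / 65 ± 8 / 76 ± 7 mmHg; HR
  75 ± 8 / 63 ± 9 bpm; PWV 8.4 ± 1.6 m/s.
* **Within-individual CoV targets (%)**: SBP 5.4 / 7.0 / 4.8
  (day/night/24-h), DBP 6.1 / 8.4 / 5.3, HR 6.3 / 7.9 / 5.9, PWV 10.7.
  $\sigma_w$ is back-solved as $\sqrt{\log(1 + \mathrm{cv}^2)}$, and the
  between-individual log-SD as the remainder of the observed marginal
  dispersion, so baseline sessions reproduce the marginals and repeated
  sessions reproduce the CoV targets simultaneously.
* **Cross-correlations**: PWV–SBP~day~ 0.40, PWV–SBP~night~ 0.41,
  PWV–DBP 0.25/0.30, BMI–BP 0.16–0.29, age–SBP 0.14–0.15. Correlation
  targets are stated on the raw scale; the generator inverts the exact
  lognormal attenuation to set latent correlations, so the raw-scale
  correlations of true means are centred on the targets. Pairs the source
  material does not pin down (day–night 0.70, SBP–DBP 0.70/0.50, age–PWV
  0.35, HR–BP 0.10) are fixed once at physiologically conventional values
  to give realistic dipping spread; they are not fitted to anything.

**24-h construction.** The 24-h true mean is the cadence-weighted blend
$(30\,\text{day} + 9\,\text{night})/39$, perturbed by its own (smallest)
$\sigma_w$. The 16:8 clock-hour blend was considered and rejected: it
contradicts the summarizer's pooled-readings convention and is numerically
inconsistent with the stated 24-h marginals (16:8 gives 123.3/74.3 mmHg
for SBP/DBP against marginal targets of 125/76, while 30:9 gives
125.4/75.8). A consequence to know about: because the blend of two
correlated latents is less dispersed than either, the *between-individual*
SD of the derived 24-h parameters runs ~10% below the printed 13/7 mmHg
even though the means and CoVs are on target; the fidelity tests therefore
check dispersion only for the six directly drawn parameters.

**Reading level.** `generate_readings()` lays the device grid over 24 h of
wear from 10:00, draws each reading as the session's day or night latent
plus Gaussian reading noise (defaults 9/7/5 for SBP/DBP/HR — sized so that
a ~30-reading day mean has an SE near 1.6 mmHg), jitters diary times
(sleep onset 23:00 ± 1 h, wake 07:00 ± 1 h), and drops readings
independently with probability 0.08. Summarizing these readings recovers
the generating session means within reading noise, which the tests verify
both noise-free (< 0.01 mmHg) and at defaults (mean absolute error
< 2 mmHg over 200 sessions).

**What the generator does not emulate**: treatment effects and
pharmacodynamics, seasonal trends, device-specific artifacts,
within-session (reading-to-reading) variability structure beyond white
noise, dip-phenotype mixtures (dipping arises solely from the joint
day/night means — which already makes category changes across sessions the
majority outcome), and, by default, any correlation between parameters'
session errors (a spec hook `session_factor_sd` adds a shared per-session
factor). Passing tests therefore demonstrate estimator correctness and
calibration under this structure, not fidelity to every feature of real
ABPM data.

Two switches are off by default because the evidence for their magnitude
is thin: a device-adaptation effect on night-time DBP (per-session mmHg
offsets, default pattern lowest at baseline then highest at the second
visit) and a small PWV endpoint drift. They exist for power
experiments and signal-recovery tests.

All randomness flows from one root seed through named substreams
(individuals / sessions / readings), so requesting reading-level data
never perturbs the session draws, and identical spec + seed reproduces
every table byte-for-byte.

## Supporting inference machinery

* `rm_anova()` is the textbook one-way within-subject decomposition with
  sphericity-assumed p (no Greenhouse–Geisser correction by default — the
  SPSS-style analysis this mirrors applies none; complete cases only). At
  two timepoints it reduces exactly to the squared paired t.
* `screen_arm_eligibility()` encodes the arm-stability rule: eligible if
  the overall ANOVA p > 0.05, otherwise if the Bonferroni-adjusted
  first-vs-last paired t is ≥ 0.05. The Bonferroni family is ambiguous in
  common practice; the default multiplies by the full pairwise family
  $t(t-1)/2$ (the most plausible reading of "Bonferroni method" for
  pairwise comparisons), with `bonferroni = "single"` for multiplier 1.
  The multiplier is reported in the output.
* `fleiss_kappa()` is the standard Fleiss formulation with the
  large-sample null variance; it requires equal ratings per subject, so
  the pipeline restricts to individuals carrying the full session count —
  the same restriction as the adaptation analysis.
* `ols_std()` standardizes coefficients as $b \cdot sd(x)/sd(y)$, binary
  predictors 0/1-coded and scaled identically; `bpv_regression()` builds
  the four BPV models (outcome: per-individual SD of each BP parameter;
  predictors: age, sex, white ethnicity, BMI, baseline PWV,
  antihypertensive use, and the matching-period mean SBP and DBP), with a
  sleep-duration column appended to the night models when supplied.
  Listwise deletion applies to regression only, never to CoV estimation —
  per-analysis sample sizes legitimately differ.

Degenerate inputs are pinned down rather than left to chance: identical
ANOVA columns give F = 0, p = 1; all-equal pairs give t = 0, p = 1;
constant non-zero differences give p = 0 by convention; zero-variance
correlation input errors; an all-one-category kappa table errors; a
singular regression design errors naming the collinear columns.

## Problem sizes and numerical tolerances

The validation suite runs at sizes chosen to keep Monte-Carlo error well
inside each tolerance: estimator recovery at the full cohort size
(501 × 3 sessions, 100 seeds, ±0.3 pp), CI calibration over 500 cohorts of
100 × 3, screening size over 1000 null replicates of 50 × 5, kappa
calibration over 100 replicates of 500 × 5, and simulator fidelity at
n = 5000 averaged over three cohorts (the SE of a sample SD is ~1% of its
value at n = 5000, against a 2% tolerance). Closed-form implementations
are held to 1e-10 relative agreement with brute-force oracles. Stochastic
round-trip checks average a handful of seeds because a single cohort's
recovered CoV has an SE near 0.15 pp — large enough for occasional
multi-sigma seeds — while the averaged statistic is stable.

## Known limitations

* The delta-method CI treats $s_w$ as approximately normal; at very small
  df (a handful of individuals) prefer `ci_method = "chisq"`.
* The CoV mapping assumes strictly positive measurements; zero or negative
  session means are a domain error, not silently dropped.
* The simulator's covariate effects on *variability* (as opposed to level)
  are off by default; Table-3-style regressions on default simulations
  estimate nulls for everything except the mean-pressure terms.
* `fleiss_kappa()`'s z-test uses the large-sample null variance, which is
  anticonservative for few subjects; with fewer than ~20 complete
  individuals read the p-value with caution.
* The eligibility screen assumes sphericity; with strongly patterned
  session effects its size can drift from nominal.
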