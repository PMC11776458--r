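---
title: "Methods: antibiotic-history instrumental-variable regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibiotic-history instrumental-variable regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`abivr` estimates the causal effect of a one-dimensional gut-microbiome
summary — the log *Prevotella*/*Bacteroides* (P/B) ratio, a proxy for the
enterotype axis of community variation — on incident diseases.  Because
microbiome and disease share many unmeasured confounders (diet, lifestyle,
health behaviour), a naive regression of disease on the microbiome is not
causal.  Instead, the number of antibiotic courses prescribed over a long
pre-baseline window (`hAB`) is used as an instrumental variable: antibiotic
usage has a cumulative, long-lasting effect on the gut community, and for
diseases not themselves treated with antibiotics it is plausible that it
affects disease risk only through the microbiome.

The estimator is a two-sample two-stage procedure (a Wald/ratio estimator).
In a microbiome cohort (sample 2) we fit the linear first stage

$$\mathrm{MB}_i = \alpha_1 + \beta_{MB,hAB}\,\mathrm{hAB}_i + \varepsilon_i,$$

and in a larger, disjoint outcome cohort (sample 1) the logistic reduced form

$$\operatorname{logit} P(D_i = 1) = \alpha_2 + \beta_{D,hAB}\,\mathrm{hAB}_i.$$

The causal effect of the exposure on the outcome's log-odds is the ratio of
coefficients

$$\hat\beta_{D,MB} = \frac{\hat\beta_{D,hAB}}{\hat\beta_{MB,hAB}},
\qquad
\hat\sigma_{D,MB} = \sqrt{\frac{\hat\sigma_{D,hAB}^2 +
  \hat\beta_{D,MB}^2\,\hat\sigma_{MB,hAB}^2}{\hat\beta_{MB,hAB}^2}},$$

the delta-method (first-order) variance for a ratio with independent
numerator and denominator estimates, which the two-sample design guarantees.
Inference is Wald: $z = \hat\beta_{D,MB}/\hat\sigma_{D,MB}$, two-sided
normal p-values, and confidence intervals
$\hat\beta_{D,MB} \pm 1.96\,\hat\sigma_{D,MB}$ (the multiplier is fixed at
1.96 rather than a t quantile; both stages run on thousands of subjects).
Across a disease panel the p-values are Benjamini–Hochberg adjusted; the
default significance threshold is FDR 0.05, with 0.1 available as a looser
reporting convention.

The estimate is causal under the three instrumental-variable assumptions:
(1) relevance — antibiotic history shifts the microbiome; (2) no
instrument–outcome confounding; (3) exclusion — no antibiotic effect on
disease outside the microbiome pathway.  None of these is testable from the
data alone; the sensitivity suite probes them indirectly.

### The estimand's scale

The ratio mixes a log-odds-scale numerator with a linear-scale denominator,
so $\hat\beta_{D,MB}$ is read as a change in disease log-odds per unit of
log P/B.  Because logistic coefficients are non-collapsible, the marginal
reduced-form slope is attenuated relative to the subject-level coefficient
whenever the exposure residual has large variance, and the ratio inherits
that attenuation.  The package therefore treats exact 95% coverage as an
over-claim and its recovery tests assert coverage at or above 90% instead.

## Cohort construction

The instrument counts prescription records with ATC code prefix `J01`
(all systemic antibiotics) in the half-open calendar window
`[index − 10 years, index − 6 months)`.  The last six months are a washout:
any `J01*` prescription there flags the subject ineligible, so that acute,
transient post-antibiotic states do not masquerade as long-term microbiome
differences.  Half-open bounds avoid double counting at the six-month edge;
one record of one drug on one day counts as one course, and same-day
duplicates are deduplicated.  Window arithmetic is exact calendar
arithmetic (month shifts with end-of-month clamping), not 365.25-day
approximations.

Subclass instruments restrict the prefix to `J01CR` (penicillin
combinations), `J01FA` (macrolides) or `J01MA` (fluoroquinolones) — three
classes with strong long-term microbiome effects and essentially
uncorrelated usage, hence quasi-independent instruments.  When a subclass
instrument is selected, the usage cap applies to that subclass count while
washout eligibility still considers all `J01*`.

The default analysis set keeps subjects aged 23–50 (completed years at the
index date, bounds inclusive) with at most 5 courses.  This deliberately
targets the healthier part of the population: frail or chronically ill
subjects both consume more antibiotics and develop more comorbidities,
which would violate assumption (2).  The sensitivity grid widens these to
ages 23–89 and cap 10.

Outcomes are incident diseases: the first diagnosis matching a disease's
ICD-10 prefix set inside `(follow-up start + gap, follow-up end]`
(defaults 2015-01-01 and 2022-12-31).  Subjects diagnosed on or before the
gap boundary are prevalent and excluded from that disease's analysis —
pre-existing disease can itself drive antibiotic usage and perturb the
microbiome (a feedback loop).  The `gap_years = 5` sensitivity treats the
first five follow-up years as prevalent, guarding against disease that was
present but undiagnosed at baseline.  Diagnoses after the follow-up end are
ignored (right censoring).  Diseases with fewer than 50 incident cases in
the analysis set are skipped.

## The microbiome feature

The log P/B ratio is computed from a genus-level relative-abundance table.
Zeros in *Prevotella* or *Bacteroides* are imputed with a pseudocount equal
to half of the minimal non-zero abundance observed anywhere in the table
(all persons, all genera — the global reading of "observed in the data";
a per-genus minimum is a defensible alternative but is not what the rule
says).  The logarithm is natural; the base only rescales estimates but must
be fixed for reproducibility.  The ratio is invariant to percent vs
proportion units; units are auto-detected from row sums and recorded.

Because log P/B is strongly bimodal (the two enterotype components), a
rank-based inverse-normal transform is available as a sensitivity:
$\Phi^{-1}((r_i - 3/8)/(n + 1/4))$ with average ranks for ties (the Blom
offset, the common default).  A fully tied input is degenerate — average
ranks map everything to zero — and is returned as such with a warning
rather than an error, matching the reference implementation's behaviour.
The transform changes the exposure's scale, so transformed and
untransformed estimates are compared by sign and significance, not value.

## The synthetic generator

Real two-sample biobank data of this kind are access-restricted, so the
package ships a generator that emulates the statistical structure the
estimator relies on; its defaults are fixed once and are not tuned to any
test outcome:

* **Cohort sizes** 50,000 (outcome) and 2,500 (microbiome), disjoint ID
  spaces by construction — the sizes of the motivating cohorts.
* **Antibiotic counts**: total 10-year course count
  $\sim \mathrm{NegBin}(\mu = 2, \text{size} = 3)$ truncated at 15 — a
  long-tailed distribution in which 0–5 courses are common and chronic
  users are rare.  Each course is allocated independently to
  J01CR/J01FA/J01MA/other with probabilities 0.20/0.25/0.15/0.40.  With
  mild overdispersion this keeps all pairwise subclass Spearman
  correlations near 0.1, satisfying the quasi-independent-instruments
  condition (below 0.2); heavy overdispersion would violate it, which is
  why size = 3.
* **Baseline log P/B**: two-component Gaussian mixture, weights 0.6/0.4,
  means −2.5/+1.0, SDs 1.0 — a Bacteroides-dominant majority and a
  Prevotella-dominant minority, giving the observed bimodality.
* **Antibiotic effect**: −0.3 log units per course, additive (cumulative),
  shared across classes by default; per-class effects are a knob.
* **Outcomes**: $\operatorname{logit} P(D=1) = \alpha + \beta\,\log PB$
  with $\alpha$ centred so the realised prevalence matches the target.
* **Index dates**: fixed 2015-01-01 in sample 1 (start of follow-up);
  per-person uniform dates over Nov 2017–Jul 2020 in sample 2 (a staggered
  sampling campaign).
* **Violation knobs**, all off by default: a latent standard-normal
  confounder acting on usage rate, log P/B and outcome log-odds; a direct
  instrument→outcome effect; and a feedback loop in which latent
  pre-existing disease adds Poisson-distributed extra courses, shifts
  log P/B, and surfaces as a diagnosis early in follow-up (so the 5-year
  gap rule removes it).
* **Genus table**: Prevotella and Bacteroides constructed from the latent
  log ratio plus 18 filler genera with gamma-distributed abundances,
  renormalised to rows summing to 100 and rounded at a 1e-5% detection
  floor.  Row normalisation preserves the P/B ratio exactly.
* 5% of subjects receive an extra washout-window prescription and are
  excluded by eligibility, exercising the washout path.

What the generator does **not** emulate: real ICD-10 ontologies and
disease-specific coding practice, drug adherence and dosing, within-person
longitudinal microbiome dynamics, compositional correlation structure
between genera, age- and sex-dependent prescription rates, and survival-time
(as opposed to binary) outcomes.  A green test on synthetic data therefore
establishes the estimator's statistical behaviour under its assumptions —
calibration, recovery, robustness of the plumbing — not the validity of
those assumptions in any real cohort.

For the parameter-recovery checks the scenario uses diseases with 12%
baseline prevalence and effects −0.5 / −0.3 / 0: a desk-scale power
analysis at these settings puts the panel z-statistic for the −0.5 effect
near 4, so the stated detect-and-not-flag criterion is achievable with
margin while remaining within realistic 8-year incidence for common
chronic conditions.

## Numerical choices

* Stage 1 is ordinary least squares (`lm`); stage 2 is IRLS (`glm`,
  binomial) with deviance tolerance 1e-8 and at most 100 iterations.
* Separation is flagged when the fit does not converge or the slope or its
  SE diverges (|slope| > 15 or SE > 50); panel runs skip such diseases
  with a warning instead of failing.
* A weak-instrument warning fires when the stage-1 |z| is below 2: near a
  zero denominator the ratio and its delta-method SE are unreliable.  The
  warning threshold mirrors the conditioning used in the package's own
  Monte-Carlo validation — a ratio of normals has no finite variance, so
  the delta SE describes the non-weak bulk of the sampling distribution,
  not moments that do not exist.  At a denominator coefficient of
  variation of 20% the first-order SE is already ~12% below the bulk MC
  spread; the validation therefore runs at CV 10%.
* BH adjustment is the standard step-up with enforced monotonicity,
  implemented directly and cross-checked against `stats::p.adjust` in the
  tests.
* The generator seeds sub-streams per sample (`seed + 1`, `seed + 2`) so
  each table is reproducible independently of the others; all seeds stay
  within 32-bit range.

## Known limitations

* The instrument acts on the whole perturbed subcommunity; effects of
  individual taxa are not identifiable, and a null result does not clear
  taxa the antibiotics never touched.
* Exclusion-restriction violations (direct antibiotic effects on disease)
  are not detectable from a single instrument; the subclass-instrument
  comparison is a consistency check, not a test.
* Estimates mix scales (log-odds per unit log P/B) and inherit logistic
  non-collapsibility; compare signs and z-scores across studies rather
  than raw magnitudes.
* Stage-2 regressions are unadjusted by default, as the estimator
  specifies; age and sex can be added as covariates, and health-behaviour
  confounding beyond that remains the main threat to assumption (2).
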