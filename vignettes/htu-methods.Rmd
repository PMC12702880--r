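---
title: "Harm-threshold allocation: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harm-threshold allocation: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htuAlloc)
```

## The allocation model

`htuAlloc` studies a constrained-utilitarian rule for giving one donor organ
to one of several eligible candidates. Pure benefit maximization
(`select_utilitarian()`) allocates to the largest predicted post-transplant
benefit μ; pure urgency (`select_meld()`) allocates to the highest MELD
score. Harm-threshold utilitarianism (`select_htu()`) sits between them by
making two ethical commitments operational as thresholds.

**Uncertainty model.** Each candidate's benefit is a normal random variable
U ~ N(μ, σ²), where μ is the expected survival over a fixed 5-year horizon
(so μ ∈ [0, 5] years) and σ is the prediction's standard deviation. The
probability that candidate *i* truly beats *j* is
Φ((μᵢ − μⱼ)/√(σᵢ² + σⱼ²)); with both σ's zero the comparison degenerates to
the sign of μᵢ − μⱼ (and to probability ½ at equality, avoiding a 0/0).
Normality is an assumption of convenience — it makes the pairwise
superiority probability closed-form — and nothing in the package supports
non-normal or correlated predictive distributions.

**Stage 1, the epistemic screen**, removes candidate *j* only when some *i*
exceeds it with probability *strictly* greater than 1 − α. We define the
surviving "tie set" as the *undominated set*: every candidate not
confidently beaten by any other. This definition was a genuinely open
design point; we chose it because it is never empty and collapses to a
singleton exactly when one candidate confidently dominates everyone, which
is the case in which the screen alone should settle the decision.
Candidates eliminated by the screen do not re-enter at later stages.

**Stage 2, harm minimization.** Hᵢ is the probability the candidate dies
within 90 days without a transplant; candidates with Hᵢ ≥ H₍crit₎
(inclusive) are in catastrophic danger. Nᵢ counts the *other* pool members
above the threshold, and the rule keeps the tie-set members minimizing Nᵢ
while counting over the whole pool. The closed form
Nᵢ = C − 1{Hᵢ ≥ H₍crit₎}, with C the total catastrophic count, shows what
this stage does: whenever the tie set contains anyone above the threshold,
exactly those candidates survive stage 2. The test suite asserts this
identity on a thousand random pools.

**Stage 3, the benefit tie-break**, maximizes the uncertainty-adjusted
benefit μ − zσ with z = Φ⁻¹(1 − α) — a lower prediction bound, so uncertain
benefit is discounted at the same confidence level the screen uses. A
single α serves both roles; the two-α variant seemed an unmotivated extra
knob. Residual exact ties are broken by pool position, a deterministic and
auditable convention.

Every decision returns a trace object recording the tie set, all Nᵢ and
μ − zσ values, and which stage resolved the choice.

## Tunable parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `alpha` | error tolerance of the screen; also sets z | probability | 0.05 |
| `hcrit` | catastrophic-harm cutoff on 90-day mortality | probability | 0.30 |
| `tau` (metrics) | survival-restriction horizon | years | 5 |
| `urgent_ref` (reporting) | fixed threshold defining an "urgent" selection | probability | 0.30 |

`alpha` is restricted to (0, 0.5]: above 0.5 the "confidence" requirement
would be weaker than a coin flip and z would go negative, *rewarding*
uncertainty in the tie-break. `hcrit = 0.30` matches the upper-quartile
design of the synthetic cohort (below). The horizon of 5 years is the scale
on which μ is defined, so predicted benefit and realized restricted
survival are directly comparable.

A reporting subtlety: when the frontier sweep varies `hcrit`, "fraction of
urgent recipients" is always measured against the *fixed* reference
`urgent_ref = 0.30`, not the swept threshold. Measuring urgency against the
moving cutoff would make the y-axis tautological and incomparable across
grid points; with a fixed reference the frontier shows how loosening the
guardrail trades protection of the same group of patients for benefit.

## The synthetic cohort generator

Real registry extracts with candidate-level (μ, σ, H) are access-restricted,
so the package generates cohorts that reproduce the *statistical structure*
those inputs have, not their values. A single latent severity s ~ N(0, 1)
drives all three clinical channels:

* MELD = round(6 + 34·logistic(1.2·s + ε)), clamped to 6–40 — sicker
  patients score higher;
* H = logistic(−1.6 + 1.0·s + ε) — the intercept is solved so that about a
  quarter of candidates sit at or above H = 0.30, placing the baseline
  threshold at the cohort's upper quartile of short-term risk;
* μ = 5·logistic(−0.8·s + ε) — the sickest candidates gain the least, the
  tension that makes urgency and efficiency conflict at all;
* σ ~ Gamma(4, scale 0.1) (mean 0.4 y), independent of severity;
* blood types O/A/B/AB at 0.45/0.40/0.11/0.04, approximate US frequencies.

Channel noises ε are independent normals (SD 0.6, 0.5, 0.5) so the
correlations are strong but far from deterministic. These defaults were
fixed once, from the design targets above, and are not fitted to anything.

Outcomes are tied to predictions by construction: each candidate's
post-transplant survival time is exponential with the unique rate λ solving
(1 − e^{−5λ})/λ = μ (`solve_rate_from_rmst()`), administratively censored
at 5 years. Under this model the expected value of min(T, 5) *equals* μ, so
"HTU gains restricted survival whenever it selects higher-μ recipients" is
a theorem the simulation can confirm rather than an artifact of a
mis-specified outcome model. The generator therefore emulates: the
MELD–urgency association, the urgency–benefit trade-off, per-candidate
predictive uncertainty, and outcome times consistent with predictions. It
does **not** emulate: disease etiologies, exception points, regional or
center structure, calibration error in μ (predictions are perfectly
calibrated here), correlated prediction errors, or time-varying waitlist
dynamics. Passing tests consequently show the *logic* of the rule behaves
as designed under the stated structure — not that any particular magnitude
would transfer to registry data, where prediction quality, not allocation
logic, may dominate.

## Offer-pool simulation

Pools of 10 candidates are sampled from the cohort with replacement across
pools but without duplicates within a pool (a patient appears at most once
per match run). When ABO matching is on, a donor type is drawn per pool
from the same frequency table and only compatible candidates are sampled.
MELD and HTU pick one recipient each per pool; outcomes are compared as
pooled Kaplan–Meier curves with 5-year RMST per policy, and as the paired
per-pool difference min(T₍HTU₎, 5) − min(T₍MELD₎, 5), summarized by its
mean and plain across-pool standard error (sd/√pools). The per-pool paired
difference was chosen over recipient-level bootstrap because pools are the
independent replication unit here. Sensitivity sweeps rerun only the HTU
selection, on the *same* pools at every (H₍crit₎, α) grid point — common
random numbers make frontier differences low-variance, so the endpoint
orderings checked by the tests are not noise comparisons. The sweep's gain
can alternatively be scored on the predicted-μ scale (`gain_scale =
"predicted_mu"`), which skips survival simulation; with the calibrated
outcome model the two scales agree in expectation.

## Cohort ranking and concordance

At cohort scale the sequential rule is replaced by its lexicographic
surrogate: sort by the harm proxy Nᵢ (equivalently, catastrophic candidates
first) and then by μ − zσ, with the epistemic screen bypassed. A test
verifies this static sort equals sequential removal with recomputed harm
counts — the two formulations coincide exactly. MELD ranks use average
ranks over integer ties. Concordance is reported as Kendall τ-b and
Spearman ρ: τ-b because MELD's integer coarseness produces heavy ties that
the un-corrected τ-a would deflate badly. τ-b is computed by merge-sort
inversion counting (about n log n), since the quadratic pair scan in
`stats::cor` is impractical at 50,000 candidates; both `stats::cor` and an
explicit O(n²) oracle verify it at small n. Note the ranking is driven by
μ − zσ *within* harm groups, which runs against MELD inside each group, so
positive overall concordance is a between-group effect and its magnitude
depends entirely on the generator's correlation structure; the tests assert
its sign only.

## Numerical choices

* Screen boundary strict (>), harm boundary inclusive (≥) — both fixed by
  the rule's definition; tests pin the strict boundary at the exactly
  representable case P = ½, α = 0.5.
* σᵢ = σⱼ = 0 with μᵢ = μⱼ gives P = ½ by convention (no division by zero).
* Kaplan–Meier estimation delegates to `survival::survfit` (deaths before
  censorings at ties); RMST is exact rectangle integration of the step
  function, checked to 1e-12 against an independent `stepfun` oracle.
* `solve_rate_from_rmst` brackets the root by doubling and solves with
  `uniroot` at tolerance 1e-12; round-trips reproduce μ to better than
  1e-8 across (0.1, 4.9).
* μ is clamped to (0 + 1e-9, 5 − 1e-9) in the generator so the outcome rate
  is always finite and positive.
* Result tables serialize doubles with 17 significant digits, so a
  write–read cycle is exactly lossless and seeded runs are byte-identical;
  run manifests carry the resolved configuration and seed.

## Problem sizes

The shipped tests and the acceptance script use a 10,000-candidate cohort
with 2,000 pools of 10 for policy comparison and sweeps, a
50,000-candidate cohort for concordance, 1,000 random pools (size ≤ 6) for
brute-force equivalence of the decision rule, and 10,000 exponential draws
for the RMST calibration check — sizes at which every Monte-Carlo margin
asserted is several standard errors wide while a full run stays
interactive on a single core.

## Limitations

The package evaluates allocation *logic* under an idealized input model. It
does not model how μ, σ, or H would be estimated, their calibration error
or bias, equity across subgroups, organ-offer acceptance behavior,
geographic constraint, or feedback between allocations and the waitlist.
Frontier positions and gain magnitudes reported by the simulation are
properties of the synthetic cohort's correlation structure and should not
be read as predictions for any real allocation system.
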