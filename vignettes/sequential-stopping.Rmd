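---
title: "Sequential stopping rules for sum-scored screeners"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential stopping rules for sum-scored screeners}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curtailr)
library(dplyr)
```

## The problem

Many screening questionnaires classify a respondent by comparing an
unweighted sum of ordinal item scores against an integer cutoff. The
canonical case in this package is the Current Opioid Misuse Measure (COMM):
17 items scored 0–4, summed to a total in 0–68, with a total of 9 or more
read as a positive screen for aberrant drug-related behaviour. Fixed-length
administration wastes items: once the first answers determine — or almost
determine — the final classification, the remaining items change nothing
for that respondent, while the burden of answering them falls hardest on
exactly the compromised subpopulations a clinical screener cares about.

`curtailr` implements the two classical sequential remedies for
computer-based administration, both of which preserve the instrument, its
item order and its cutoff, and only decide *when to stop*:

* **Curtailment** stops deterministically as soon as the classification is
  guaranteed: either the cumulative score has already reached the cutoff
  (minus whatever the remaining items must contribute, when items have
  nonzero floors), or the cutoff is unreachable even if every remaining
  item scored its maximum. The curtailed decision *always* equals the
  full-length decision.
* **Stochastic curtailment (SC-γ)** also stops when the final result is
  merely *probable*: when the estimated probability of one final
  classification, given the cumulative score so far, reaches or exceeds a
  threshold γ (0.90, 0.95 and 0.99 are the conventional choices). Those
  probabilities are estimated once, on a training cohort, and frozen into
  an integer look-up table; no computation happens at administration time.

Both rules reduce to a per-stage pair of integer boundaries — stop negative
at or below `neg_max[k]`, stop positive at or above `pos_min[k]` — which is
the form a testing platform can consume directly, and the form this package
reads, writes, replays and evaluates.

## The boundary algebra

Write $m_k$ and $M_k$ for the attainable minimum and maximum cumulative
score after $k$ of $n$ items, and $T$ for the cutoff. Curtailment's
boundaries are closed-form:

* positive: $\mathrm{pos\_min}[k] = T - \sum_{j>k}\min_j$, stored only when
  it is attainable ($\le M_k$); for instruments with all-zero item floors
  this is simply $T$ from the first stage where $M_k \ge T$;
* negative: $\mathrm{neg\_max}[k] = T - 1 - \sum_{j>k}\max_j$, stored only
  when $\ge m_k$.

For the COMM this yields no negative stopping before stage 15 (a score of 0
after 15 items is the first position from which 9 is unreachable), the
boundaries 0/4/8 at stages 15/16/17, and positive stopping at 9 from stage
3 (the first stage where 9 is attainable) onward. The test suite verifies
the algebra against an independent brute-force oracle that enumerates every
completion of every prefix on all small instruments (up to 4 items, score
widths up to 3, every cutoff), including instruments with nonzero item
floors.

## Stage models and threshold inversion

For SC-γ, the package fits one logistic regression per interim stage
$k = 1..n-1$ on a training cohort: outcome = full-length classification
positive, single predictor = cumulative score after $k$ items. The outcome
is deliberately the instrument's own classification rather than any
external gold standard — the stopping probabilities are statements about
what the *questionnaire* would conclude. A single running-total predictor
is also the only quantity a score-keyed look-up table can condition on.

Boundaries follow by threshold inversion on the attainable scores at each
stage: the positive boundary is the smallest score with estimated positive
probability ≥ γ (ties stop — "reaches or exceeds" is non-strict), the
negative boundary the largest score with negative probability ≥ γ, each
absent when no attainable score qualifies (the "N/A" cells that appear
naturally at early stages for strict γ). Every stage is then unioned with
the deterministic curtailment region: a guaranteed outcome has probability
1 ≥ γ by definition, and a finite-sample fit should never be allowed to
miss it. Because stopping regions shrink as γ grows, SC-0.99 tables nest
inside SC-0.95 inside SC-0.90, all containing curtailment — and mean test
lengths order the same way, a property the suite checks end to end.

### Separation and the empirical fallback

Late stages of a screener are nearly deterministic: given the score after
16 of 17 items, the outcome is fixed unless the score sits exactly at
cutoff − 1. Maximum-likelihood logistic fits on such stages diverge
(perfect or quasi-perfect separation). `fit_stage_models()` flags a stage
as separated when the IWLS fit fails to converge, produces fitted
probabilities of numerically 0/1, or yields a slope beyond
`sep_threshold` (default 10 log-odds per score point — far steeper than
any plausible finite relationship). Flagged stages carry an empirical
fallback instead: the observed conditional proportion positive at each
observed cumulative score, extended to unobserved scores as a
left-continuous step function clamped at the ends. The fallback need not
be monotone in the score; `sc_boundaries()` then takes the extreme
qualifying scores and says so in a warning. In the pathological case where
a non-monotone fallback would push a negative boundary at or above the
stage's positive boundary after the curtailment union, the negative
boundary is truncated to one point below the positive one (with a warning)
rather than aborting the derivation: the positive side is backed by the
deterministic guarantee, so it wins.

### The monotone-constrained variant

Because each stage is fitted independently, a boundary sequence can dip —
a positive requirement of 9 at stage 3 but 8 at stages 4–5, say, which
reads oddly even though nothing in the per-stage estimation forbids it.
`constrain_monotone()` produces the conservative nondecreasing variant:
positive boundaries are raised to their forward running maximum, negative
boundaries lowered to their backward running minimum (each over the stages
where they are present; absent boundaries stay absent and the final-stage
partition is untouched). Raising a positive boundary or lowering a
negative one can only shrink a stopping region, so the constrained rule
never stops a respondent the unconstrained rule would continue. The flag
is set even when the input was already monotone and the values come back
unchanged.

## Evaluation

`apply_rule()` replays complete records through any boundary table
(post-hoc simulation of the sequential administration), and
`evaluate_rule()`/`compare_rules()` report the conventional operating
grid: sensitivity and specificity of the shortened rule's decisions for
predicting the full-length classification and for predicting an external
binary gold label, mean and sample SD of the number of items administered,
and the percentage of respondents stopping before the last item. The
reference classification is always the reference: sensitivity is the
fraction of reference-positives the rule also calls positive. A proportion
whose reference class is empty is reported as `NA`, never coerced to 0 or
1. For a curtailment table, sensitivity and specificity against the
full-length classification are exactly 1 on every dataset — the suite
asserts this with `expect_identical`, not within a tolerance.

## The synthetic cohort generator

No individual-level response data ship with the package, so every
end-to-end test runs on synthetic cohorts from a unidimensional
latent-severity model: respondent trait $z \sim N(0,1)$; item $j$'s latent
response $\lambda_j z + e$, $e \sim N(0,1)$, cut at the item's ordered
thresholds into a 0–4 score; gold label drawn with probability
$\mathrm{logit}^{-1}(a + b z)$. One latent factor reproduces the positive
inter-item dependence a sum-score screener presumes, and routing the gold
label through the trait rather than the items makes screen-versus-gold
discrimination imperfect by construction — the realistic ~0.70
sensitivity/specificity regime rather than a deterministic link.

`calibrate_cohort()` matches the generator to published reference moments
entirely in closed form (normal-ogive item moments plus quadrature over
the trait), so calibration is deterministic and simulation enters only at
`generate_cohort()`:

* per item, equally spaced thresholds (two free parameters: location and
  spread) are matched to the published item mean and SD — for the COMM's
  training sample these land within 0.01 of every target;
* a single common loading is tuned so the model-implied total-score SD
  matches the published 7.5 (yielding λ ≈ 0.78, i.e. an average inter-item
  correlation around 0.3 — the dependence level the published total-score
  dispersion implies);
* the gold intercept and slope are least-squares matched to three targets
  (gold prevalence 0.341, screen-vs-gold sensitivity 0.703 and specificity
  0.701). Two parameters cannot hit all three exactly: the best this
  family achieves is approximately 0.371/0.733/0.654, and the calibration
  reports its achieved values in the config's `"achieved"` attribute. The
  tests therefore hold the deterministic calibration to ±0.05 of each
  target and separately require simulated cohorts to track the achieved
  values; passing them shows the generator realises its own model
  faithfully, not that real COMM-vs-gold data behave exactly like a
  one-factor latent model.

What the generator does *not* emulate: site or cohort effects (the two
published samples differ slightly, 48.6% vs 42.8% screened in — the
calibrator targets either column but not both at once), item-specific
residual dependence, and any structure in the gold standard beyond a
monotone link to the single trait. Results on synthetic cohorts are
therefore structural checks (guarantees, nesting, orderings,
calibration), never estimates of the published data-dependent operating
characteristics, which depend on two clinical samples that were never
deposited.

## Numerical and design choices

* **SDs** are sample SDs (n − 1), for item summaries and test-length
  dispersion alike; **IQR** is Q3 − Q1 with type-7 quantiles. Published
  tables do not state their conventions, so item medians/IQRs are matched
  only to tolerance, never digit for digit.
* **Boundary hits are non-strict** (`<= neg_max`, `>= pos_min`), matching
  the "Score ≤ / Score ≥" reading of printed look-up tables; positive is
  checked first, though valid tables cannot overlap.
* **Absent boundaries** are `NA` end to end and an empty field on disk —
  never a sentinel integer — so "N/A" cells round-trip bit-exactly; the
  human-readable rendering (`format_rule()`) prints the equality form
  ("Score = 4") when a boundary coincides with the stage's attainable
  extreme.
* **Out-of-range and incomplete records** are excluded with a logged
  reason, never clamped or imputed; scoring functions refuse records that
  skipped validation.
* **Problem sizes in the tests**: training cohorts of 1,000–2,000, test
  cohorts of up to 1,000, one calibration check at n = 10,000, and the
  exhaustive oracle over all ≤ 4-item instruments — sizes chosen so the
  statistical checks are comfortably stable at their tolerances.
* **Stage n − 1 is fitted like any other stage** and stage n is fixed
  analytically by the cutoff partition.

## Known limitations

SC look-up tables are sample-specific: tables fitted on one population
should not be reused on another without refitting (the curtailment table,
by contrast, is population-free arithmetic). The package does not model
item reordering, multiple-logistic classifiers with covariates, IRT/CAT
scoring, or resampling uncertainty for boundaries — the rules here keep
the instrument's printed order and its simple cutoff, which is what makes
their guarantees exact.
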