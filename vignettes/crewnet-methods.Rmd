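---
title: "Methods: proximity networks and longitudinal psychometrics for isolated crews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity networks and longitudinal psychometrics for isolated crews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crewnet)
```

crewnet analyses team dynamics in isolated, confined and extreme (ICE)
settings — overwintering stations, spaceflight analogues — from two data
streams collected on the same small crew: wearable proximity sensors that
record face-to-face contact at 10-second resolution during repeated
multi-week deployments, and a questionnaire battery (loneliness, paranoid
thinking, team cohesion, conflict, performance) administered once per
deployment. This vignette documents the statistical model behind each
module, the conventions the implementation commits to, and the synthetic
data generator used to validate the whole pipeline.

## Data model and conventions

A **contact interval** is a row `(t, i, j)` meaning sensors `i` and `j` were
in face-to-face range during the half-open 10-second slot `[t, t + 10)`.
Sensors are either worn by **persons** (who have a nationality/agency group)
or mounted in **rooms** (shared spaces or accommodation areas). The roster
gives each sensor a presence interval `[first_day, last_day]`, inclusive on
both ends, which is how mid-mission crew replacements are represented: the
departing member's `last_day` precedes the arriving member's `first_day`.

**Deployment windows** are half-open in days: `[start_day, end_day)`. A
contact belongs to a window when its onset `t` falls inside the window's
second range and both sensors are present on that day. Half-open windows
make consecutive deployments partition time without double counting; this
is asserted by a property test.

## Network metrics

Per deployment, contacts aggregate into an undirected weighted graph whose
edge weight is the pair's total proximity time. From it the package
computes:

* **Strength centrality** — the sum of a node's edge weights, reported in
  hours; room edges can be excluded to isolate interpersonal time.
* **Node Gini selectivity** — the population Gini coefficient
  `G = sum_ij |w_i - w_j| / (2 n^2 mean(w))` of a person's contact-time
  vector over *all* co-present wearable partners, explicitly including
  zero-weight partners: a person who spends all their time with one
  crewmate scores close to 1, an even mixer close to 0. Rooms are excluded
  from the partner set by default because stationary sensors measure
  occupancy, not tie choice. A person with no recorded contact time has
  undefined selectivity (`NA`), not zero.
* **Daily strength distributions** — per sensor-day strength with an
  explicit distinction between *absent* days (not on station: `NA`) and
  *present-but-zero* days (on station, no contacts recorded). The
  zero-day fraction for wearables mixes true non-interaction with nonwear,
  which is why the generator models nonwear explicitly. Distributions from
  two deployments are compared with a two-sample Kolmogorov–Smirnov test
  (asymptotic p, since strengths contain ties).
* **Group contact matrices** — total hours between and within groups, and a
  pair-rescaled version dividing by the number of possible pairs
  (`n_g * n_h` off-diagonal, `n_g (n_g - 1) / 2` on the diagonal) so that
  groups of different sizes are comparable. A singleton group has no
  within-group pairs; its diagonal entry is `NA`, and singletons can be
  excluded via the `groups` argument.

## Questionnaire scoring

Scale definitions are data, not code. The defaults encode a 20-item
loneliness scale (options 1–4, summed, range 20–80, nine reverse-keyed
items), two 16-item paranoid-thoughts subscales (ideas of reference,
persecutory; options 1–5, summed, 16–80, with a severity flag above 40),
and 6/3+3/3-item team scales (cohesion, task + relationship conflict,
performance; options 1–5, item means). The overall conflict index is the
mean of the six conflict items. Internal consistency uses Cronbach's alpha
with sample variances over complete respondents. Scores are computed from
complete item sets by default; person-mean imputation of up to 10% missing
items is opt-in.

## Longitudinal models

Three complementary analyses quantify change over the four waves:

1. **Repeated-measures ANOVA** (complete cases, time as the single
   within-subject factor, no sphericity correction), built on
   `stats::aov(score ~ wave + Error(person))`. With `n` complete cases and
   `w` waves the df are `(w - 1, (w - 1)(n - 1))` — e.g. 9 complete cases
   over 4 waves give F(3, 24).
2. **Paired t tests** between two waves on within-person differences
   `a - b` (an increase yields negative t). Zero-variance differences are
   reported as degenerate (t of 0 or ±Inf) rather than an error.
3. **A two-level linear growth model** fitted by ML on all available
   observations: `score = (b0 + u0_p) + (b1 + u1_p) * time + e`, with
   correlated person-level random intercept and slope
   (`lmerTest::lmer(score ~ time + (time | person), REML = FALSE)`).
   With four waves and a dozen crew this coincides, in the fixed slope,
   with a latent growth model. Time is coded either as wave index
   (0, 1, 2, 3) or as elapsed mission months (0, 2, 5, 8); the slope's
   units follow the coding. When the random-slope variance is degenerate
   (`lme4::isSingular`, tolerance 1e-5) or the fit fails, the model falls
   back to a random intercept only and records the reason — a deliberate
   choice over erroring, because near-zero slope variance is common in
   panels this small.

### Bootstrap confidence intervals

Uncertainty for the growth slope uses a person-level Monte-Carlo bootstrap:
persons are resampled with replacement and all of a person's waves move
together, respecting the within-person dependence. Two numerical choices
matter here:

* **Fast exact refit.** For balanced complete panels the ML fixed slope
  equals the mean of the resampled persons' per-person OLS slopes (GLS
  reduces to OLS under balance; verified in tests to 1e-15), so each
  resample costs a vector mean rather than a mixed-model fit. Unbalanced
  panels refit the mixed model per resample, erroring if more than 10% of
  refits fail.
* **Expanded percentile interval.** With only ~12 resampling units the
  plain percentile interval systematically undercovers (measured ≈88% at
  nominal 95%): the bootstrap spread is deflated by `(n-1)/n` and normal
  rather than t quantiles are implied. By default the quantile levels are
  therefore widened to `pnorm(sqrt(n/(n-1)) * qt(alpha/2, n-1))`
  (the expanded percentile method), which restores ≈94% measured coverage
  in the acceptance tests. `expand = FALSE` gives the plain percentile
  interval; the method string records which was used.

## Linking sensors to questionnaires

Each repeated measure is decomposed into a stable person mean plus
wave-specific deviations (person-mean centering; the decomposition is exact
and idempotent). **Within-person** Spearman correlations pool the
deviations of persons with at least two observed waves on both measures —
they ask whether waves in which a person interacted more were also waves in
which they felt less lonely, regardless of stable individual differences.
**Across-person** correlations use one point per person (the person means).
Spearman with the asymptotic t approximation is used throughout because
scores are ordinal-ish, n is small, and ties are ubiquitous; significance
markers follow the conventional `***/**/*/†` cut-offs (0.001, 0.01, 0.05,
0.10).

## The synthetic crew generator

Because real crew data of this kind cannot be redistributed, the package
ships a generator whose defaults encode the study conditions the pipeline
targets, and the acceptance tests validate the pipeline against the
generator's known ground truth.

| Parameter | Default | Rationale |
|---|---|---|
| Crew | 6 IT + 5 FR + 1 out-group member | two nationality groups plus a singleton, 12 on station |
| Replacements | members 5 and 8 replaced after deployment 1 | mid-mission crew rotation; 14 wearers overall |
| Rooms | 5 shared (cafeteria, lounge, gym, lab, workshop) + 4 accommodation | stationary sensors in common vs private spaces |
| Windows | 4 × 14 days at days 0, 60, 150, 240 | four deployments across a 10-month mission |
| Day schedule | 3 meal blocks, 2 work blocks, 1 evening block, 08:00–22:00 | sensors worn in the daytime |
| Room choice | meals: cafeteria 0.90 / own quarters 0.10; work: work rooms 0.75 / lounge 0.10 / cafeteria 0.05 / quarters 0.10; evening: lounge 0.70 / quarters 0.25 / gym 0.05 | makes the cafeteria and lounge the highest-strength rooms |
| `contact_prob` | 0.04 per 10-s slot for a co-located cross-group pair | sets overall interaction volume |
| `homophily` | 1.2, 1.5, 2.0, 2.5 across deployments | within-group contact odds rise as the mission wears on |
| `activity` | 1.0, 0.85, 0.70, 0.50 across deployments | total interpersonal interaction declines while room usage stays stable |
| `nonwear_prob` | 0.35 per person-day | produces the person zero-day fraction; rooms are always on |
| `room_prob` | 0.10 per slot | person-room detection rate |

Two details are worth flagging. Work rooms are drawn **uniformly anew each
block** rather than assigned per person: a fixed person-to-room assignment
would make some pairs structurally more co-located than others and
confound the homophily null (ratio 1.0 would not produce a flat matrix).
Quarters *are* person-specific (a round-robin over the four areas), which
introduces a small structural co-location excess for quarters-sharing
pairs; with the default room probabilities this biases pair hours by well
under 1% and is accepted for realism. The closed-form
`expected_pair_hours()` accounts for both choices exactly, and a
law-of-large-numbers test checks simulated totals against it.

Questionnaire panels follow the same growth model the pipeline fits
(known β₀, β₁, random-effect SDs, residual SD, truncation to the scale
range), optionally expanded to item-level responses whose noise variance is
solved from the Spearman–Brown relation to hit a target Cronbach's alpha.
The reference fixture (`make_reference_fixture()`) applies a missingness
mask reproducing the study-like complete-case pattern: 9 complete cases on
loneliness, 10 on the team outcomes, 12 pairs for mid-mission paired t
tests.

What the generator does **not** attempt: radio-propagation realism,
circadian structure, behavioural feedback between questionnaire states and
contact behaviour (scores and contacts are generated independently unless a
covariate coupling is requested explicitly).

## Problem sizes and budgets

The package's own reference problem — 14 wearers, 9 rooms, 4 × 14 days,
~350k contact rows, 4-wave panels for 6 outcomes, B = 2000 bootstrap — runs
end to end in a few minutes on one core. Acceptance tests use 100–600
replicates per statistical claim (parameter recovery within 10%, bootstrap
coverage within [0.92, 0.98], null rejection within [0.02, 0.08], homophily
detection ≥95%), sized so Monte-Carlo noise is well inside the asserted
tolerance bands.

## Limitations

* The growth model assumes linear change in the chosen time coding;
  month-coded and wave-coded slopes answer different questions and both are
  reported by `analyze_panel()`.
* The repeated-measures ANOVA applies no sphericity correction, matching
  the field convention for four waves; users needing corrections should fit
  the growth model instead.
* Within-person correlations with four waves per person have limited power;
  the package reports n alongside every rho.
* The KS test p-values are asymptotic; with heavily tied daily strengths
  they are approximate.
* The severity flag for paranoid-thinking subscales is a fixed threshold
  (>40) and not a clinical instrument.
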