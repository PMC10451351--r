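---
title: "Behavioral welfare metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral welfare metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimpmetrics)
```

This vignette is the package's own account of the seven behavioral-welfare
metric protocols it implements, the assumptions behind each, the tunable
parameters that matter, and the design decisions taken where the underlying
protocols leave the implementation genuinely open.

## The problem

Sanctuaries and other facilities managing large groups of chimpanzees need
objective, repeatable answers to the question "how is this individual or
group doing?". The toolkit turns routine observational record streams —
behavioral scans, wound reports, wellness surveys, hair-loss surveys,
nightly proximity records, training and shifting logs — into per-animal
metrics, threshold-based alerts, and an integrated report, without any
dependence on a particular data-entry platform: everything exchanges as
plain CSV/JSON tables (`read_records()`, `write_records()`).

## Composite wellness score

Each assessor scores ten parameters (abnormal behavior, locomotion, access
to food/water, human–animal interaction, coat, self-aggression, social
interaction, staff concern, enrichment acceptance, wounds) on a raw 0–3
scale. `score_survey()` averages each parameter over assessors, multiplies
by a per-parameter weight, and sums:

$$\mathrm{Total} = \sum_{p} w_p \cdot \overline{s_p}$$

**Weights.** The operational protocol weights parameters "by level of
concern" but publishes no values; the package defaults to unit weights,
which reproduce the documented scale maximum of 30 (ten parameters × 3).
Custom weights are accepted and a warning is raised when they change the
attainable maximum, because the action bands below are defined on the
0–30 scale.

**Action bands.** The published cutpoints — 0–12 routine quarterly
monitoring, 12–29 elevated, above the scale top critical — overlap at 12
and leave a gap below the maximum. `classify_wellness()` resolves both
ambiguities *toward concern*: a total of exactly 12 is `elevated`, and
everything above 29 is `critical`. This is a deliberate, documented choice:
for a welfare alerting system a false escalation is cheaper than a missed
one.

**"Of concern" summaries.** Colony summaries (`parameter_concern_summary()`)
need a per-parameter concern predicate that the protocol does not define;
the default cutoff is a weighted parameter mean ≥ 1.0 — at least one
average assessor-step above "no concern" — and is configurable.

`schedule_wellness()` plans four surveys per animal per year, one per
quarter (mid-quarter by convention), so each animal is seen across seasons.

## Wound surveillance

The wound log is an *event* log: only a wound's initial occurrence and any
escalation to a higher severity grade (1 = superficial scratch … 5 =
gaping/missing body part) are recorded. Within any window a wound therefore
counts **once**, at its maximum in-window grade
(`effective_wounds_in_window()`).

Concern criteria are counts within a rolling two-week window: 10 wounds of
any grade, 4 of grade 3, 3 of grade 4, or 1 of grade 5
(`default_wound_criteria()`). Numerical choices:

* "Two weeks" is implemented as 14 consecutive calendar days inclusive of
  both endpoints.
* Candidate windows are anchored at event dates. For point events this is
  exhaustive: any real-valued window can be slid until its start coincides
  with the earliest event it contains without dropping events, so
  threshold detection over event-anchored windows equals detection over
  all windows. The test suite verifies this against a brute-force
  enumeration of every anchor date.
* Grade-specific criteria count wounds of **exactly** that grade. A grade-4
  wound does not advance the grade-3 criterion; higher grades carry their
  own stricter criteria. Cross-counting would be an assumption the
  protocol's criteria table does not state.
* One flag per (animal, criterion) per contiguous run of satisfying
  windows, reported at the earliest window, so a single wounding bout
  produces one alert rather than one per day.

## Hair loss

Observers score each of seven body zones on a five-point scale
{0, 25, 50, 75, 100}% hair lost; off-scale entries are snapped to the
nearest scale point on ingestion, with exact midpoints rounded *up*
(toward concern). The total is the zone-weighted sum, where a zone's
weight is its share of ideal hair surface area derived from grid-cell
counts over a body diagram (`zone_weights_from_grid()`). Typically
hairless body parts are excluded when the grid mask is drawn, not by
runtime logic. The packaged `default_zone_map()` (head 10%, torso 20%,
back 17%, arms 12% each, legs 14.5% each) is a documented default, not a
transcription of any published diagram, and is fully configurable.

Totals of 25% or more are *significant* (`flag_significant()`, closed
boundary) and escalate monitoring from one colony-wide survey per 15
months to three observers every 4 months (`schedule_hairloss()`); animals
with no survey on file are scheduled immediately for a baseline.

## Activity budgets and TIA triggers

`budget_from_scans()` estimates the fraction of time in each of nine
behavior categories from instantaneous scan samples; `budget_from_focal()`
does the duration-weighted equivalent for continuous focal follows.
Budgets always cover the full category set, sum to 100, and are
permutation-invariant in the records. All-occurrence behaviors — rare
events tallied whenever they occur — are excluded from budget denominators
and reported as events per observation hour (`all_occurrence_rates()`).

A Targeted Individual Assessment is triggered (`evaluate_tia_triggers()`)
by a high-priority abnormal-behavior report, by wound concern criteria, by
an abnormal-behavior budget share **strictly** greater than 10% (the
protocol says "more than 10%", so 10.0% exactly does not trigger), or by
an externally reported notable behavioral change. Notable changes are
accepted as supplied report records, not inferred: no detection rule for
"notable" is defined anywhere, and inventing one would produce alerts no
one calibrated.

The observation scheduler (`sms_schedule()`) is a fixed 13-row mapping
from monitoring reason to span and number of observations (e.g.
post-social integration: 13 observations over 3 months; yearly check-in:
6 over 6 weeks). `assign_observation_slots()` spreads the observations
evenly over the span and assigns each uniformly at random to one of the
three daily observation blocks (07:30–10:30, 10:30–12:30, 13:30–15:30),
deterministically per seed.

## Nearest-night-neighbor networks

One record per animal per night: location (indoor/outdoor), proximity
class (contact, arm's reach, within 3 m, outside 3 m, no neighbor) and the
neighbor's identity. `pair_matrix()` counts, per unordered pair, the
nights on which at least one of the two named the other. Decisions:

* A pair counts at most once per night even when both animals name each
  other — edge weights mean *nights*, not mentions.
* The `"all"` matrix accepts any named-neighbor proximity including
  outside-3 m; the three stratified matrices are per-class by default
  (matching how such matrices are usually reported side by side), with a
  `cumulative = TRUE` option for nested closer-than-x matrices.
* Nights with no record for an animal are simply absent from denominators;
  the record format cannot distinguish "unobserved" from "alone", so the
  package does not guess.

`sociogram_layout()` uses a seeded weighted Fruchterman–Reingold layout so
strongly bonded pairs render closer together; the layout is deterministic
given the seed.

## Training and shifting analytics

Training sessions are keyed by (date, time, trainer, chimp) with a
length-prefixed encoding that is injective even when components contain
the delimiter. Cue responses use the 1–3 scale (3 = correct response most
of the time). Shifting compliance is the percent of *eligible* asked-days
complied: days excluded for weather or with an alternate goal leave the
denominator entirely, and zero eligible days yields an undefined (`NA`)
result, deliberately distinct from 0%. Group-level compliance follows the
"all members shifted" convention, with per-animal analysis available for
animals whose plans define compliance differently. An optional
`co_trainers` field supports mentor/mentee sessions.

## The synthetic colony

`simulate_colony()` generates every record stream from known ground truth:
per-animal behavior mixtures (default inactive-dominant, roughly half of
observation time inactive, feeding next, abnormal and aggressive rare);
Poisson wound arrivals with a severity distribution concentrated on grades
1–2 and occasional one-grade escalations; bounded, slowly drifting latent
hair loss spread over zones and snapped to the observer scale; nightly
neighbors drawn proportionally to a symmetric preference matrix with one
*planted* strongest pair per group; Bernoulli shifting compliance; and
multi-assessor wellness scores as a latent per-animal concern level plus
assessor noise.

Each stream draws from its own RNG stream derived from the master seed via
fixed per-stream offsets, so adding a new stream never perturbs existing
ones, and bundles are reproducible byte-for-byte per seed.

**What it does and does not emulate.** The generator produces realistic
*marginal* shapes and known recoverable parameters. It does not model
demographic change, seasonal or social dynamics, observer bias, or
correlations between streams (e.g. wounding driving wellness scores), so
passing recovery tests demonstrates the estimators are correct on clean
generating processes — not that real colony data meet these assumptions.

**Problem sizes.** The recovery test suite uses 20,000 scans for budget
recovery (3-standard-error multinomial bound), 100 seeds × 200 nights for
planted-pair recovery (≥95% success), 200 random logs for the
rolling-window oracle equivalence and 100 random colonies for the pair
matrix oracle equivalence — sizes at which the statistical guarantees are
sharp while the whole suite runs in a couple of minutes on one CPU.

## Degenerate inputs and numerical conventions

* Dates are ISO-8601, timezone-naive facility-local; timestamps UTC.
* Empty wound logs yield empty flag tables; an empty period in
  `severity_distribution()` is an error, distinguishable from all-zero.
* Budgets with zero in-scope scans are errors, not all-zero budgets.
* Unknown names are *report content* (`validate_names()`, case-insensitive
  by default, Levenshtein suggestions with alphabetical tie-break), never
  exceptions — misspellings are expected operational noise.
* Probability vectors must sum to 1 within 1e-8; zone weights within 1e-9.

## Known limitations

* The wellness critical band is unreachable under default weights (the
  scale maximum is 30 and the band opens above 29 only because the gap
  resolution absorbs (29, 30] into critical); with the published ">30"
  reading it would be strictly unreachable. The package documents rather
  than resolves this tension.
* A reported hair-loss significance case below the 25% line exists in
  operational practice; the package follows the stated 25% rule.
* Wound body-location coding, intra-follow scan intervals, and the exact
  per-zone surface percentages are not published; the package makes each
  configurable and ships documented defaults.
* Group activity budgets pool scans (each scan equal weight); an
  equal-weight-per-individual aggregation can be had by averaging
  per-animal budgets with `pre_post_comparison()`-style arithmetic.
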