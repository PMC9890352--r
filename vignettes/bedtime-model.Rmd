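---
title: "Inferring bedtimes from posting time stamps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring bedtimes from posting time stamps: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bedtimer)
```

## The inference problem

A habitual bedtime cannot be read off the clock time of a user's last post
on any given night: the user may be awake but occupied, and bedtimes vary
from night to night. What is stable is the *rate* at which a user posts at
each time of day, averaged across their whole posting history. `bedtimer`
assumes that this rate is roughly constant while the user is awake and
declines smoothly around the habitual bedtime — smooth precisely because
night-to-night variability blurs an abrupt stop into a gradual depletion —
and estimates the bedtime as the phase at which the decline sits.

The estimator needs two inputs per user: UTC post time stamps and an IANA
time zone (bedtimes are announced, and slept, on the local clock). It is
trained on users whose bedtimes are known from self-report, and then
applied to users for whom only time stamps and a zone are available.

## The circadian fingerprint and bedtime-relative coordinates

Each user's activity is summarised as a **circadian fingerprint**: 96
fifteen-minute bins over the 24-hour local day, bin `i` (0-based) covering
minutes `[15i, 15(i+1))`, holding the *fraction* of the user's posts in
that bin. Fractions rather than percentages are stored throughout because
the model's normalization constraint ("all bins sum to one") is stated in
fractions; display layers may multiply by 100.

Averaging raw fingerprints across users with different bedtimes would blur
the night-time dip. Fingerprints of labeled users are therefore re-indexed
in **bedtime-relative coordinates**: a pure cyclic permutation placing the
bin containing the user's bedtime at offset zero, with bins labelled by
their start offset in hours after bedtime on the fixed grid −12.00,
−11.75, ..., +11.75. The symmetric ±12 h window comfortably contains the
night-time depletion (which in practice runs from under an hour before
bedtime to about ten hours after it). Aggregation is an unweighted
element-wise mean over users — each user counts equally, so prolific
posters cannot dominate the aggregate. Summing instead of averaging was
the other defensible reading of "combining" fingerprints; both yield the
same curve up to a scale factor that re-normalization removes, and the
mean keeps the aggregate on the same fractions-sum-to-one scale as the
inputs, so the mean was chosen.

## The unified model

The fraction `r` of posts in the bin starting `x` hours after bedtime is
modelled piecewise:

$$
r(x) = \begin{cases}
  a x^2 + b x + c & -S \le x \le E \\
  d               & \text{otherwise}
\end{cases}
\qquad
d = \frac{1 - \sum_{\text{parabolic bins}} (a x^2 + b x + c)}{96 - k}
$$

with `k` the number of parabolic bins. The parabola captures the
night-time depletion; the flat height `d` is not free but fixed by the
constraint that the 96 bins sum to one.

Conventions that matter, and why they were chosen:

* **Bin-start evaluation.** `r` is evaluated at bin *start* offsets, and
  the section bounds are read as the first and last parabolic bin starts:
  `S = 0.75, E = 10` means 44 parabolic bins starting at −0.75 h through
  +10.00 h. Under this reading the published parameter set (quadratic
  coefficient `4.12e-4`, linear magnitude `3.81e-3`, constant `1.06e-2`)
  reproduces the published flat height `d = 1.42e-2` to three significant
  figures, which is the consistency check the convention was chosen by.
* **Sign of the linear coefficient.** Coefficients are stored signed and
  fitted freely. With `x` in hours *after* bedtime, a depletion with an
  interior minimum a few hours into the night requires `b < 0` (an
  upward-opening parabola with vertex at `−b/2a > 0`); a positive linear
  term of the same magnitude would put the vertex before bedtime and
  drive the normalized flat height negative.
* **Nadir location vs depth.** The vertex of the reference parabola sits
  at `x = 4.62` h, and its depth relative to `d` rounds to an 87%
  reduction (`nadir_depletion()`). The depth is parametrization-invariant
  and is asserted in tests; the vertex location depends on rounding of
  3-significant-figure coefficients and is deliberately *not* asserted
  exactly anywhere.

## Fitting: exhaustive grid search

`fit_unified()` sweeps all cut-point combinations `S ∈ {0, 0.25, …, 6}`
and `E ∈ {0.25, …, 11.75}` hours in 15-minute increments. The bounds are
not part of the model: they were fixed once to cover physiologically
plausible sleep windows inside the 24-h relative frame (declines beginning
more than 6 h before a *reported* bedtime, or persisting 12 h after it,
would not be sleep). Within each candidate, `(a, b, c)` is the unweighted
ordinary-least-squares polynomial fit to the section's bin values (bins
are not weighted by user count), `d` follows from normalization, and the
candidate is scored by mean squared error over all 96 bins.

A candidate is **invalid** if `d < 0` or any modelled bin is negative —
`r` is a frequency — and invalid candidates are silently discarded rather
than raised, since discarding is exactly the role the validity rule plays
inside the sweep. Exact mse ties (they arise for degenerate inputs such as
a perfectly uniform profile, where every candidate fits perfectly) are
broken deterministically: narrowest section first, then smallest `S`. Ties
are compared with an absolute tolerance of `1e-15` so that floating-point
noise in algebraically identical fits cannot make the winner
platform-dependent. The search is exhaustive by construction, and the test
suite asserts equality against an independently coded nested-loop oracle
built on `lm()`.

## Estimation by template matching

`make_templates()` rotates the fitted curve into 96 bedtime-specific
templates, one per candidate 15-minute bedtime. `estimate_bedtime()`
returns the bedtime label of the template with maximal Spearman rank
correlation against the user's fingerprint.

* **Spearman ties.** The flat section makes tied values pervasive, so the
  rank method matters: average ranks (the `stats::cor` convention) are
  used.
* **Argmax ties.** Ties across templates are resolved toward the circular
  mean of the tied candidates (minimal circular distance to it), with any
  remainder broken by the first candidate clockwise from 12:00 noon —
  deterministic and unbiased toward midnight, unlike "first index wins",
  which would favour 00:00.
* **Degenerate fingerprints** (all mass in one bin, or fewer than two
  distinct values) leave rank correlation undefined; they are returned
  flagged (`status = "degenerate_fingerprint"`) rather than estimated.
  They cannot arise for users passing the 250-post activity floor with
  organic posting, only for pathological or adversarial inputs.

Because templates are exact rotations of one another, estimation is
rotation-equivariant: rotating a fingerprint by `j` bins shifts its
estimate by exactly `15j` minutes (mod 24 h). The suite asserts this for
all 96 rotations. When the fitted `S` is 0.75 h, the winning template's
bedtime coincides with "45 minutes after the start of the parabolic
portion", connecting the template-argmax view of estimation with the
cut-point view.

## Screening

Four bot rules, each individually sufficient: a burst of ≥9 posts in one
clock minute; lifetime volume ≥ 2^14 posts; ≥2% of posts on the same exact
minute-of-day across dates; a username containing "bot", "admin", "mod" or
"auto". Scheduled jobs run on local *or* UTC clocks, so the periodicity
tally is computed on both and the rule fires if either crosses 2%. Bot
flags are applied only in the application context: users who answered a
bedtime prompt are, by that act, evidenced humans, so the training context
applies only the activity floor and the outlier rule.

The cohort-wide bedtime-outlier exclusion removes reported bedtimes more
than 2 SDs from the cohort mean. Bedtimes straddle midnight, so both
moments are circular: the mean is the resultant-vector direction and the
SD is the standard circular SD `sqrt(−2 log R̄)` converted to hours. (A
naive linear SD on clock values would misbehave for cohorts centred near
midnight; whether the original rule was circular or linear is not
documented, so this is a recorded interpretation risk.) The rule is
applied in a single pass — no iterative re-exclusion — matching its
"all otherwise-included members" phrasing.

Reported clock times are snapped to the 15-minute grid by circular nearest
rounding; at 1-minute resolution the only tie-relevant offsets are 7 and 8
minutes, rounded down and up respectively (the nearest-integer-minute
convention), and 23:53 wraps forward to 00:00.

## Circular accuracy metrics

Estimated and reported bedtimes are compared with wrap-around distances
(`circular_diff`, in `[0, 12]` h; "within 1 hour" is inclusive of exactly
60 minutes) and with the angular correlation of Jammalamadaka and
SenGupta — the correlation of sine deviations from the respective circular
means. It is 1 whenever one variable is a fixed rotation of the other and
is invariant to rotating either variable. "Correlation in polar
coordinates" admits more than one formula; the sine-deviation coefficient
is the standard circular–circular choice, and this interpretation is the
single largest source of non-comparability when relating the package's
correlations to externally reported ones.

## Cross-validation

`kfold_validate()` randomly deals labeled users into `k` near-equal folds
(sizes differing by at most one; `k = 3` keeps both training and hold-out
sets adequately sized for cohorts of ~150 users), fits the model on the
training folds' aggregate profile, and scores both partitions, repeating
over (by default) 10 partition seeds — 30 hold-out evaluations for
`k = 3`. Comparable training and hold-out correlation medians indicate the
model is not overfitting, which is the property the harness exists to
check; `final_model()` then trains the released model on *all* labeled
users. Reports are bit-for-bit reproducible given the seed vector.

## The synthetic-data generator

Real labeled cohorts of this kind are survey-derived and not
redistributable, so the package ships a generator that emulates the
statistical structure the method assumes:

* **Bedtime law:** von Mises on the 24-h circle, centred at 23:45 —
  between the ~11:47 PM mean reported bedtime of survey-style cohorts and
  the slightly later means seen in large application sets — with
  `kappa = 6.5`, giving a circular SD of about 1.5 h; sampled bedtimes are
  snapped to the 15-minute grid. Sampling uses the Best–Fisher (1979)
  rejection algorithm (no circular-statistics dependency is required).
* **Posting law:** each user's minutes-of-day are i.i.d. draws from the
  bedtime-specific template of a generating model (default:
  `default_model()`, the reference parameterization with `S = 0.75`,
  `E = 10` and an 87% nadir), with uniform minute jitter inside the
  15-minute bin; dates are uniform over 2015–2020 and local times are
  converted to UTC epochs in the user's zone. Local times erased by a DST
  spring-forward fall back to local midnight plus the minute offset — a
  sub-0.1% effect.
* **User-level noise:** with weight `w` (default 0.1), the user's template
  is mixed with a flat-Dirichlet draw, `p = (1 − w)·template + w·u`. This
  emulates idiosyncratic daytime habits. Its aggregate effect is a flat
  admixture that shallows the curve without moving the cut points, so
  parameter recovery of `(S, E)` remains well-posed under noise.
* **Bot archetypes:** four accounts each constructed to trip exactly one
  screening rule (the burst bot's 9-post minute is diluted below the 2%
  periodicity threshold by 900 spread posts, and so on), for testing the
  screen's specificity as well as its sensitivity.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: weekday/weekend and seasonal structure,
per-night bedtime variability beyond the smooth depletion (a per-night
jitter would widen the parabola), non-stationary posting histories,
time-zone relocation, and any dependence between post timing and content.
Accuracy on synthetic cohorts is an upper bound on field accuracy.

## Problem sizes and numerical tolerances

The validation suite uses cohorts of 200 users × 2,000 posts for parameter
recovery (`(S, E)` recovered to within one 15-minute grid step), 159 users
for the cross-validation harness (3 folds of 53; hold-out vs training
correlation medians within 0.1 on low-noise data), and 60-user cohorts at
250/1,000/5,000 posts per user for the error-vs-activity trend — sizes at
which the checked properties are stable across seeds while the whole suite
runs in minutes. Conservation (bins summing to one) is asserted at `1e-9`;
noiseless least-squares recovery at `1e-9`; mse tie tolerance `1e-15`;
the degenerate-resultant guard in circular means at `1e-9` of resultant
length.

## Known limitations

Estimates exist only for users with ≥250 posts and a known time zone, and
inherit every bias of who posts frequently. One habitual bedtime per user
is assumed: shift workers, biphasic sleepers and users whose schedules
changed over their posting history violate the model. The depletion has a
fixed quadratic shape; adaptive-width or asymmetric depletions, wake
times and sleep durations are natural extensions, not implemented here.
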