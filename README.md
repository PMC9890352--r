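# bedtimer

Estimate the habitual bedtimes of social-media users from nothing but the
UTC time stamps of their posts and their time zones.

## The problem and who this is for

Bedtime is an emerging health metric: late sleepers are at elevated risk of
mood and substance-use problems, and researchers studying sleep at scale
increasingly want sleep parameters for social-media users without
recruiting them into a survey. A user's posting record is an objective,
machine-readable partial listing of when they are awake. On average a
user's posting rate is roughly flat during waking hours and dips overnight,
and the decline begins near the user's habitual bedtime — `bedtimer` turns
that signature into a validated estimator, together with the screening,
circular-statistics and cross-validation machinery needed to use it
responsibly.

## The model

Each user is summarised as a **circadian fingerprint**: the vector of
fractions of their posts falling in each of the 96 fifteen-minute bins of
the 24-hour local day. Fingerprints of users with *known* (reported)
bedtimes are re-indexed in hours after bedtime and averaged; the aggregate
profile is fitted with a piecewise **unified model** for the fraction `r`
of posts in the bin starting `x` hours after bedtime:

```
r(x) = a x^2 + b x + c   for -S <= x <= E      (night-time depletion)
r(x) = d                 otherwise             (flat daytime rate)

d = (1 - sum over parabolic bins of (a x^2 + b x + c)) / (96 - k)
```

with `k` the number of parabolic bins, so the 96 bins always sum to one.
The cut points `S` (hours before bedtime) and `E` (hours after) are chosen
by an exhaustive grid search in 15-minute increments, fitting `(a, b, c)`
by ordinary least squares within each candidate and keeping the
combination with the lowest mean squared error over all 96 bins.

To estimate an *unknown* bedtime, the fitted curve is rotated into 96
**bedtime-specific templates** (one per candidate 15-minute bedtime) and a
user is assigned the bedtime of the template their fingerprint most
resembles by Spearman rank correlation.

Around the core model the package provides:

- ingest of NDJSON/CSV time-stamp files and DST-aware localization to IANA
  zones (`read_posts()`, `localize()`);
- rule-based bot screening (posting bursts, lifetime volume, minute-of-day
  periodicity, username substrings) and eligibility rules, including a
  circular 2-SD bedtime-outlier exclusion (`bot_flags()`,
  `check_eligibility()`, `exclude_outliers()`);
- circular statistics: circular mean/SD, wrap-around distances, the
  angular (sine-deviation) correlation, within-1-h/2-h accuracy counts;
- a k-fold cross-validation harness over multiple partition seeds
  (`kfold_validate()`);
- a seeded synthetic-cohort generator (`simulate_cohort()`,
  `simulate_bot()`) so the whole pipeline can be exercised and validated
  without downloading anything.

## Worked example

Simulate a labeled 40-user cohort, fit the model to its aggregate
bedtime-relative profile, and estimate every user's bedtime back from
their own fingerprint:

```r
library(bedtimer)

co      <- simulate_cohort(n_users = 40, posts_per_user = 1000, noise = 0.05, seed = 42)
users   <- Map(localize, co$posts, co$users$tz_name, co$users$author_id)
fps     <- lapply(users, compute_fingerprint)
profile <- aggregate_profiles(Map(to_relative, fps, co$users$true_bedtime))

(fit <- fit_unified(profile))
#> <unified_model>
#>   parabolic section: 1.00 h before to 10.50 h after bedtime (47 bins)
#>   a = 0.0003816, b = -0.003551, c = 0.01054, d = 0.01401
#>   mse = 2.369e-07, pearson = 0.9944

est <- estimate_batch(users, make_templates(fit), min_posts = 250)
head(est, 3)
#>   author_id bedtime       rho n_posts status
#> 1  user0001      30 0.7736874    1000     ok
#> 2  user0002    1350 0.8336814    1000     ok
#> 3  user0003    1290 0.8059362    1000     ok

str(accuracy_report(est$bedtime, co$users$true_bedtime))
#> List of 4
#>  $ n        : int 40
#>  $ within_1h: int 40
#>  $ within_2h: int 40
#>  $ circ_corr: num 0.977
```

Reading the output: the fitted curve says posting starts declining about
an hour before bedtime, stays depressed for ten and a half hours, and
tracks the observed aggregate profile with Pearson correlation 0.994.
`bedtime` is in minutes after local midnight (30 = 00:30, 1350 = 22:30;
`format_clock()` renders them), `rho` is the winning template's Spearman
correlation, and on this cohort every estimate lands within an hour of the
true bedtime, with circular correlation 0.98.

A thin command-line front end over the same functions (subcommands
`simulate`, `fit`, `estimate`, `screen`, `validate`) ships in
`inst/scripts/bedtimer.R`.

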