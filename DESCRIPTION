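Package: bedtimer
Title: Estimating Habitual Bedtimes from Posting Time Stamps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the habitual bedtimes of social-media users from the UTC
    time stamps of their posts. Per-user posting activity is summarised as a
    96-bin circadian fingerprint over the 24-hour local day, fingerprints of
    users with known bedtimes are aggregated in bedtime-relative coordinates,
    and a piecewise model (a flat daytime posting rate with a quadratic
    night-time depletion) is fitted to the aggregate profile by an exhaustive
    grid search over the depletion's cut points. The fitted curve is then
    rotated into a bank of 96 bedtime-specific templates and each user's
    bedtime is estimated as the template best matching the user's fingerprint
    by Spearman rank correlation. Includes rule-based bot screening,
    circular summary statistics and accuracy metrics, a k-fold
    cross-validation harness, and a synthetic-cohort generator for end-to-end
    testing without any platform download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
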