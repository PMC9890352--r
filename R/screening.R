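# Screening: bot-filtration heuristics, eligibility thresholds and the
# cohort-wide bedtime-outlier exclusion.

#' Flag suspected bot accounts
#'
#' Four rules, each individually sufficient:
#' * `burst` — nine or more posts within a single clock minute (UTC epoch
#'   truncated to the minute);
#' * `volume` — a lifetime total of `2^14` (16,384) posts or more;
#' * `periodicity` — at least 2% of all posts landing on the same exact
#'   minute-of-day across dates (checked on both the local and the UTC
#'   clock, since scheduled jobs run on either; the flag fires if either
#'   tally crosses the threshold);
#' * `name` — the username contains `"bot"`, `"admin"`, `"mod"` or
#'   `"auto"`, case-insensitively.
#'
#' @param epochs UTC epoch seconds of the user's posts.
#' @param username Account name.
#' @param local_minutes Optional local minutes-of-day matching `epochs`;
#'   when absent, periodicity is checked on the UTC clock only.
#' @return An object of class `bot_flags`: list with logical `burst`,
#'   `volume`, `periodicity`, `name` and `is_bot` (their disjunction).
#' @export
bot_flags <- function(epochs, username = "", local_minutes = NULL) {
  n <- length(epochs)
  burst <- n > 0L && max(tabulate(factor(epochs %/% 60))) >= 9L
  volume <- n >= 2^14
  utc_mod <- (epochs %/% 60) %% 1440
  per_frac <- function(mins) {
    if (length(mins) == 0L) return(0)
    max(tabulate(factor(mins))) / length(mins)
  }
  periodicity <- per_frac(utc_mod) >= 0.02 ||
    (!is.null(local_minutes) && per_frac(local_minutes) >= 0.02)
  name <- grepl("bot|admin|mod|auto", username, ignore.case = TRUE)
  structure(list(burst = burst, volume = volume,
                 periodicity = periodicity, name = name,
                 is_bot = burst || volume || periodicity || name),
            class = "bot_flags")
}

#' @export
print.bot_flags <- function(x, ...) {
  on <- names(x)[vapply(x, isTRUE, logical(1))]
  cat("<bot_flags>", if (x$is_bot) paste("BOT:", paste(setdiff(on, "is_bot"),
                                                       collapse = ", "))
      else "clean", "\n")
  invisible(x)
}

#' Eligibility decision for one user
#'
#' Applies the inclusion/exclusion rules of the study design. In the
#' `training` context (users whose prompt-appropriate bedtime reports are
#' themselves evidence of human activity) bot flags are ignored; in the
#' `application` context they exclude. Both contexts require a known time
#' zone and at least `min_posts` lifetime posts; the cohort-wide 2-SD
#' bedtime-outlier exclusion is passed in as a precomputed flag (see
#' [exclude_outliers()]).
#'
#' @param n_posts Lifetime post count.
#' @param has_timezone Whether the user's time zone is known.
#' @param flags A `bot_flags` object, or `NULL`.
#' @param bedtime_outlier Whether the user's reported bedtime fell outside
#'   2 circular SDs of the cohort mean (training context only).
#' @param context `"training"` or `"application"`.
#' @param min_posts Post-count floor (default 250).
#' @return List (class `eligibility_decision`) with logical `eligible` and
#'   character `reasons` drawn from `too_few_posts`, `no_timezone`,
#'   `bot_flagged`, `bedtime_outlier`; `eligible` iff `reasons` is empty.
#' @export
check_eligibility <- function(n_posts, has_timezone = TRUE, flags = NULL,
                              bedtime_outlier = FALSE,
                              context = c("training", "application"),
                              min_posts = 250L) {
  context <- match.arg(context)
  reasons <- character()
  if (n_posts < min_posts) reasons <- c(reasons, "too_few_posts")
  if (!has_timezone) reasons <- c(reasons, "no_timezone")
  if (context == "application" && !is.null(flags) && isTRUE(flags$is_bot)) {
    reasons <- c(reasons, "bot_flagged")
  }
  if (context == "training" && isTRUE(bedtime_outlier)) {
    reasons <- c(reasons, "bedtime_outlier")
  }
  structure(list(eligible = length(reasons) == 0L, reasons = reasons),
            class = "eligibility_decision")
}

#' Cohort-wide 2-SD bedtime-outlier mask
#'
#' Computes the circular mean and circular SD of all reported bedtimes, and
#' flags for exclusion any bedtime whose circular distance from the mean
#' exceeds twice the circular SD. Applied in a single pass (no iterative
#' re-exclusion) and invariant under a common rotation of all bedtimes.
#'
#' @param bedtimes Reported bedtimes, minutes after midnight (length >= 2).
#' @param n_sd Exclusion threshold in circular SDs (default 2).
#' @return Logical inclusion mask: `TRUE` = keep.
#' @export
exclude_outliers <- function(bedtimes, n_sd = 2) {
  stopifnot(length(bedtimes) >= 2L)
  th <- minutes_to_angle(bedtimes)
  mu <- angle_to_minutes(atan2(mean(sin(th)), mean(cos(th))))  # unrounded
  sigma <- circular_sd(bedtimes)
  circular_diff(bedtimes, mu) <= n_sd * sigma
}
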