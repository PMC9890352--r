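# Synthetic cohorts: labeled users whose post times are drawn from a
# bedtime-shifted posting curve, plus bot archetypes that trip each
# screening rule. Everything is deterministic given a seed, so the whole
# pipeline is testable without any platform download.

#' Reference parameterization of the posting curve
#'
#' A fitted unified model representative of a large labeled cohort:
#' posting begins to decline 45 minutes before bedtime (`S = 0.75`),
#' reaches a nadir roughly 87% below the flat daytime rate about 4.6 hours
#' after bedtime, and returns to baseline 10.25 hours after bedtime
#' (`E = 10`). Used as the default generating model for synthetic cohorts.
#'
#' @return A `unified_model`.
#' @export
default_model <- function() {
  unified_model(S = 0.75, E = 10, a = 4.12e-4, b = -3.81e-3, c = 1.06e-2)
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher (1979) wrapped-Cauchy rejection sampler. Uses the current
#' RNG state; callers seed explicitly.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration (`>= 0`; 0 is the circular uniform).
#' @return Angles in `[0, 2*pi)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (sign(stats::runif(1) - 0.5) * acos(f) + mu) %% (2 * pi)
    }
  }
  out
}

.SIM_SPAN <- c("2015-01-01", "2020-12-31")

# local (date, minute-of-day) -> UTC epoch in tz; DST-gap times that do not
# exist on the wall clock fall back to local midnight + offset.
local_to_epoch <- function(dates, minutes, tz) {
  s <- sprintf("%s %02d:%02d:00", dates, minutes %/% 60L, minutes %% 60L)
  ep <- as.numeric(as.POSIXct(s, tz = tz))
  bad <- is.na(ep)
  if (any(bad)) {
    ep[bad] <- as.numeric(as.POSIXct(paste(dates[bad], "00:00:00"),
                                     tz = tz)) + minutes[bad] * 60
  }
  ep
}

#' Simulate one user's post epochs
#'
#' Post minutes-of-day are drawn i.i.d. from the bedtime-specific template
#' of the generating model, optionally perturbed per user by mixing in a
#' flat-Dirichlet draw with weight `noise` (emulating idiosyncratic daytime
#' habits); a uniform minute jitter is applied within the 15-minute bin,
#' dates are drawn uniformly over the simulation span, and local times are
#' converted to UTC epochs in the user's zone.
#'
#' @param bedtime True bedtime, minutes after midnight on the 15-minute
#'   grid.
#' @param n Number of posts.
#' @param model Generating `unified_model` (default [default_model()]).
#' @param noise Dirichlet-perturbation weight in `[0, 1]` (0 = sample the
#'   template exactly).
#' @param seed Integer seed; the draw is deterministic given it.
#' @param tz IANA zone for the epochs.
#' @param span Character vector of two dates bounding the posting history.
#' @return Numeric vector of `n` UTC epoch seconds.
#' @export
simulate_user <- function(bedtime, n, model = default_model(), noise = 0,
                          seed = 1L, tz = "UTC", span = .SIM_SPAN) {
  stopifnot(inherits(model, "unified_model"), n >= 1L,
            bedtime %% 15 == 0, noise >= 0, noise <= 1)
  set.seed(seed)
  p <- make_templates(model)[bedtime %/% 15L + 1L, ]
  if (noise > 0) {
    u <- stats::rgamma(96L, shape = 1)
    p <- (1 - noise) * p + noise * u / sum(u)
  }
  bins <- sample.int(96L, n, replace = TRUE, prob = p)
  minutes <- (bins - 1L) * 15L + sample.int(15L, n, replace = TRUE) - 1L
  days <- as.Date(span[1]) +
    sample.int(as.integer(as.Date(span[2]) - as.Date(span[1])) + 1L, n,
               replace = TRUE) - 1L
  local_to_epoch(as.character(days), minutes, tz) +
    sample.int(60L, n, replace = TRUE) - 1L
}

#' Simulate a labeled cohort
#'
#' Bedtimes are drawn from a von Mises law on the 24-hour circle and
#' rounded to the 15-minute grid; each user's posts are then drawn with
#' [simulate_user()]. Defaults describe a plausible adult cohort: mean
#' bedtime 23:45 with circular SD about 1.5 h (`kappa = 6.5`), 250-2500
#' posts per user, and a modest level of user-specific daytime noise.
#'
#' @param n_users Cohort size.
#' @param posts_per_user Single count or `c(min, max)` range sampled
#'   uniformly per user.
#' @param bedtime_mean Mean of the bedtime law, minutes after midnight.
#' @param kappa Von Mises concentration of the bedtime law.
#' @param model Generating `unified_model`.
#' @param noise Per-user Dirichlet perturbation weight.
#' @param tz_names Pool of IANA zones assigned round-robin.
#' @param seed Integer seed (per-user sub-seeds are derived from it).
#' @param span Posting-history date span.
#' @return An object of class `synthetic_cohort`: list with `users` (a
#'   data.frame of `author_id`, `true_bedtime`, `tz_name`, `n_posts`) and
#'   `posts` (named list of epoch vectors).
#' @export
simulate_cohort <- function(n_users, posts_per_user = c(250L, 2500L),
                            bedtime_mean = 1425L, kappa = 6.5,
                            model = default_model(), noise = 0.1,
                            tz_names = c("UTC", "America/New_York",
                                         "Europe/London",
                                         "America/Los_Angeles"),
                            seed = 1L, span = .SIM_SPAN) {
  stopifnot(n_users >= 1L, kappa >= 0)
  set.seed(seed)
  th <- rvonmises(n_users, minutes_to_angle(bedtime_mean), kappa)
  bedtimes <- round_bedtime(floor(angle_to_minutes(th)) %% 1440)
  npost <- if (length(posts_per_user) == 1L) rep(posts_per_user, n_users)
    else sample(posts_per_user[1]:posts_per_user[2], n_users, replace = TRUE)
  tz <- rep_len(tz_names, n_users)
  ids <- sprintf("user%04d", seq_len(n_users))
  subseeds <- sample.int(2^30, n_users)
  posts <- lapply(seq_len(n_users), function(i) {
    simulate_user(bedtimes[i], npost[i], model = model, noise = noise,
                  seed = subseeds[i], tz = tz[i], span = span)
  })
  names(posts) <- ids
  structure(list(users = data.frame(author_id = ids,
                                    true_bedtime = bedtimes,
                                    tz_name = tz,
                                    n_posts = lengths(posts),
                                    stringsAsFactors = FALSE),
                 posts = posts),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$users), "users,",
      sum(x$users$n_posts), "posts\n")
  invisible(x)
}

#' Write a synthetic cohort in the ingest formats
#'
#' Emits `posts.ndjson` (one `{"author": ..., "created_utc": ...}` object
#' per line), `meta.csv` (`author_id,tz_name,reported_bedtime` with the
#' true bedtime as the report) and `truth.csv` (`author_id,true_bedtime`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- unlist(lapply(names(cohort$posts), function(a) {
    sprintf('{"author":"%s","created_utc":%.0f}', a, cohort$posts[[a]])
  }))
  writeLines(lines, file.path(dir, "posts.ndjson"))
  meta <- data.frame(author_id = cohort$users$author_id,
                     tz_name = cohort$users$tz_name,
                     reported_bedtime = format_clock(cohort$users$true_bedtime))
  utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(data.frame(author_id = cohort$users$author_id,
                              true_bedtime = format_clock(cohort$users$true_bedtime)),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

# n distinct epoch-minutes uniform over the span, plus a random second
spread_epochs <- function(n, span = .SIM_SPAN) {
  lo <- as.numeric(as.POSIXct(paste(span[1], "00:00:00"), tz = "UTC")) %/% 60
  hi <- as.numeric(as.POSIXct(paste(span[2], "23:59:00"), tz = "UTC")) %/% 60
  mins <- sample(seq(lo, hi), n, replace = FALSE)
  mins * 60 + sample.int(60L, n, replace = TRUE) - 1
}

#' Simulate a bot account of a given archetype
#'
#' Each archetype is built to trip exactly one screening rule of
#' [bot_flags()] (plus the overall `is_bot`):
#' `"burst"` posts nine times within one clock minute amid otherwise
#' spread-out activity; `"volume"` accumulates `2^14` spread-out posts;
#' `"periodic"` lands 3% of its posts on the same minute-of-day across
#' dates; `"named"` is an ordinary account whose username contains a
#' flagged substring.
#'
#' @param archetype One of `"burst"`, `"volume"`, `"periodic"`, `"named"`.
#' @param seed Integer seed.
#' @return List with `username` and numeric `epochs`.
#' @export
simulate_bot <- function(archetype = c("burst", "volume", "periodic",
                                       "named"),
                         seed = 1L) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  out <- switch(archetype,
    burst = {
      base <- spread_epochs(900L)
      minute0 <- (base[1] %/% 60) * 60
      list(username = "stormchaser17",
           epochs = c(base, minute0 + sample.int(60L, 9L) - 1))
    },
    volume = list(username = "prolific_pat", epochs = spread_epochs(2^14)),
    periodic = {
      base <- spread_epochs(970L)
      days <- sort(sample(seq(as.Date(.SIM_SPAN[1]), as.Date(.SIM_SPAN[2]),
                              by = "day"), 30L))
      sched <- as.numeric(as.POSIXct(paste(days, "05:00:00"), tz = "UTC"))
      list(username = "daily_digest", epochs = c(base, sched))
    },
    named = list(username = "moderator_jane", epochs = spread_epochs(500L)))
  out$epochs <- sort(out$epochs)
  out
}
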