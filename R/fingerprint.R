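# Circadian fingerprints: the 96-bin distribution of a user's posts over
# the 24-hour local day, and its bedtime-relative recasting.

# Bin-start offsets, in hours after bedtime, of the relative coordinate
# system: -12.00, -11.75, ..., +11.75. Offset 0 sits at index 49.
relative_x_grid <- function() seq(-12, 11.75, by = 0.25)

.ZERO_INDEX <- 49L  # position of x = 0 in relative_x_grid()

#' Compute a user's circadian fingerprint
#'
#' Bins a user's posts into the 96 fifteen-minute intervals of the 24-hour
#' local day; bin `i` (1-based) covers minutes `[15(i-1), 15i)`. Values are
#' fractions of the user's posts and sum to one.
#'
#' @param posts A `localized_posts` object, or an integer vector of local
#'   minutes-of-day in `[0, 1439]`.
#' @return An object of class `circadian_fingerprint`: list with `values`
#'   (96 nonnegative fractions summing to 1) and `n_posts`.
#' @export
compute_fingerprint <- function(posts) {
  mins <- if (inherits(posts, "localized_posts")) posts$local_minutes else posts
  if (length(mins) == 0L) stop("cannot compute a fingerprint from zero posts")
  stopifnot(all(mins >= 0), all(mins <= 1439))
  counts <- tabulate(mins %/% 15L + 1L, nbins = 96L)
  structure(list(values = counts / length(mins), n_posts = length(mins)),
            class = "circadian_fingerprint")
}

#' Recast a fingerprint in bedtime-relative coordinates
#'
#' Cyclically shifts a clock-time fingerprint so that the bin containing the
#' given bedtime sits at offset zero; other bins are labelled by hours after
#' bedtime on the fixed grid -12.00 to +11.75 (bin starts, 0.25-h steps).
#' The operation is a pure cyclic permutation of the 96 values.
#'
#' @param fp A `circadian_fingerprint`.
#' @param bedtime Bedtime in minutes after midnight, on the 15-minute grid.
#' @return An object of class `relative_profile`: list with `x_grid`,
#'   `values` and `n_users = 1`.
#' @export
to_relative <- function(fp, bedtime) {
  stopifnot(inherits(fp, "circadian_fingerprint"))
  if (bedtime %% 15 != 0 || bedtime < 0 || bedtime >= 1440) {
    stop("bedtime must lie on the 15-minute grid in [0, 1440)")
  }
  k <- as.integer(bedtime) %/% 15L            # 0-based clock bin of bedtime
  # relative index i (1..96) holds the clock bin k + (i - .ZERO_INDEX), mod 96
  src <- (k + (seq_len(96L) - .ZERO_INDEX)) %% 96L + 1L
  structure(list(x_grid = relative_x_grid(), values = fp$values[src],
                 n_users = 1L),
            class = "relative_profile")
}

#' Invert a bedtime-relative profile back to clock time
#'
#' @param profile A `relative_profile`.
#' @param bedtime The bedtime (minutes after midnight, 15-minute grid) the
#'   profile was zeroed on.
#' @return A `circadian_fingerprint` whose `n_posts` is `NA` (aggregation
#'   loses the count).
#' @export
from_relative <- function(profile, bedtime) {
  stopifnot(inherits(profile, "relative_profile"))
  if (bedtime %% 15 != 0) stop("bedtime must lie on the 15-minute grid")
  k <- as.integer(bedtime) %/% 15L
  src <- (k + (seq_len(96L) - .ZERO_INDEX)) %% 96L + 1L
  vals <- numeric(96L)
  vals[src] <- profile$values
  structure(list(values = vals, n_posts = NA_integer_),
            class = "circadian_fingerprint")
}

#' Average bedtime-relative profiles across users
#'
#' Element-wise arithmetic mean; every user weighs equally regardless of
#' post count, so prolific posters do not dominate the aggregate.
#'
#' @param profiles A list of `relative_profile` objects.
#' @return A `relative_profile` with `n_users` set to the total.
#' @export
aggregate_profiles <- function(profiles) {
  if (length(profiles) == 0L) stop("no profiles to aggregate")
  stopifnot(all(vapply(profiles, inherits, logical(1), "relative_profile")))
  mat <- vapply(profiles, function(p) p$values, numeric(96L))
  structure(list(x_grid = relative_x_grid(),
                 values = rowMeans(mat),
                 n_users = sum(vapply(profiles, function(p) p$n_users,
                                      integer(1)))),
            class = "relative_profile")
}

#' @export
print.circadian_fingerprint <- function(x, ...) {
  cat("<circadian_fingerprint> 96 bins,", x$n_posts, "posts; peak bin",
      which.max(x$values) - 1L, "\n")
  invisible(x)
}

#' @export
print.relative_profile <- function(x, ...) {
  cat("<relative_profile> 96 bins over [-12, +11.75] h,", x$n_users,
      "user(s)\n")
  invisible(x)
}

#' Write fingerprints as a 96-column CSV matrix
#'
#' One row per user, columns labelled by the clock time of each bin start,
#' plus `author_id` and `n_posts`. This is also the export format for
#' benchmarking external models on the same features.
#'
#' @param fps Named list of `circadian_fingerprint` objects.
#' @param path Output CSV path.
#' @export
write_fingerprints <- function(fps, path) {
  mat <- t(vapply(fps, function(f) f$values, numeric(96L)))
  colnames(mat) <- format_clock(15L * (0:95))
  df <- data.frame(author_id = names(fps), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$n_posts <- vapply(fps, function(f) f$n_posts, integer(1))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
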