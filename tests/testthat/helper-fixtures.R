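# Shared fixtures: all built in code, no stored data.

# A fingerprint with the given minutes-of-day (unnormalized counts).
fp_from_minutes <- function(minutes) compute_fingerprint(as.integer(minutes))

# A relative profile taken verbatim from a vector of 96 fractions.
profile_from_values <- function(values) {
  stopifnot(length(values) == 96L)
  structure(list(x_grid = bedtimer:::relative_x_grid(),
                 values = values, n_users = 1L),
            class = "relative_profile")
}

# Noiseless profile generated exactly by a model.
profile_from_model <- function(m) profile_from_values(eval_model(m))

# A generic non-degenerate fingerprint: posts sampled from the reference
# curve for a 23:00 bedtime.
example_fingerprint <- function(n = 3000L, bedtime = parse_clock("23:00"),
                                seed = 7L) {
  ep <- simulate_user(bedtime, n, seed = seed, tz = "UTC")
  compute_fingerprint(as.integer((ep %/% 60) %% 1440))
}

# Cyclic rotation of a fingerprint by j clock bins (bin i -> bin i + j).
rotate_fingerprint <- function(fp, j) {
  v <- numeric(96L)
  v[(seq_len(96L) - 1L + j) %% 96L + 1L] <- fp$values
  structure(list(values = v, n_posts = fp$n_posts),
            class = "circadian_fingerprint")
}

# Write a small CSV/NDJSON posts file; returns the path.
write_posts_csv <- function(rows) {
  f <- tempfile(fileext = ".csv")
  writeLines(c("author_id,utc_epoch", rows), f)
  f
}
write_posts_ndjson <- function(lines) {
  f <- tempfile(fileext = ".ndjson")
  writeLines(lines, f)
  f
}
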