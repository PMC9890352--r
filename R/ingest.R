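# Reading post time stamps and user metadata, and localizing them to each
# user's wall clock.

#' Read per-user post time stamps
#'
#' Reads a file of post records and groups them by author. Two dialects are
#' supported: newline-delimited JSON with one object per line carrying keys
#' `author` and `created_utc`, and CSV with header columns
#' `author_id,utc_epoch`. Records with a missing, empty or non-integer epoch
#' (or a missing author) are dropped and counted, not errored on; duplicate
#' (author, epoch) pairs are retained, because posting bursts are signal for
#' bot screening.
#'
#' @param path Path to the input file.
#' @param format Either `"ndjson"` or `"csv"`.
#' @return An object of class `post_set`: a named list mapping each
#'   `author_id` to its numeric vector of UTC epoch seconds, with attribute
#'   `skipped` giving the number of dropped records.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("author_id,utc_epoch", "u1,1600000000", "u1,1600000060",
#'              "u2,1600000000"), f)
#' ps <- read_posts(f, "csv")
#' lengths(ps)
#' @export
read_posts <- function(path, format = c("ndjson", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("cannot read posts file: ", path)
  }
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "character",
                          strip.white = TRUE)
    if (!all(c("author_id", "utc_epoch") %in% names(df))) {
      stop("CSV posts file must have columns author_id, utc_epoch")
    }
    authors <- df$author_id
    epochs <- suppressWarnings(as.numeric(df$utc_epoch))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, function(l) {
      tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    })
    authors <- vapply(recs, function(r) {
      if (is.list(r) && !is.null(r$author)) as.character(r$author)[1] else NA_character_
    }, character(1))
    epochs <- vapply(recs, function(r) {
      if (is.list(r) && !is.null(r$created_utc)) {
        suppressWarnings(as.numeric(r$created_utc)[1])
      } else NA_real_
    }, numeric(1))
  }
  ok <- !is.na(authors) & nzchar(authors) & !is.na(epochs) &
    epochs >= 0 & epochs == trunc(epochs)
  skipped <- sum(!ok)
  authors <- authors[ok]
  epochs <- epochs[ok]
  if (length(epochs) == 0L) {
    stop("no valid post records in ", path)
  }
  out <- split(epochs, factor(authors, levels = unique(authors)))
  structure(out, skipped = skipped, class = c("post_set", "list"))
}

#' Read user metadata
#'
#' Reads the per-user metadata CSV with columns `author_id`, `tz_name` and
#' optionally `reported_bedtime` ("HH:MM" local clock, 24-hour).
#'
#' @param path Path to the metadata CSV.
#' @return A data.frame with columns `author_id`, `tz_name` and, when
#'   present in the file, `reported_bedtime` (minutes after local midnight).
#' @export
read_meta <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata file: ", path)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!all(c("author_id", "tz_name") %in% names(df))) {
    stop("metadata CSV must have columns author_id, tz_name")
  }
  out <- data.frame(author_id = df$author_id, tz_name = df$tz_name,
                    stringsAsFactors = FALSE)
  if ("reported_bedtime" %in% names(df)) {
    out$reported_bedtime <- vapply(df$reported_bedtime, function(s) {
      if (is.na(s) || !nzchar(s)) NA_integer_ else parse_clock(s)
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Convert "HH:MM" to minutes after midnight
#'
#' @param s Character vector of 24-hour clock strings.
#' @return Integer minutes after midnight, in `[0, 1440)`.
#' @export
parse_clock <- function(s) {
  m <- regmatches(s, regexec("^([0-9]{1,2}):([0-9]{2})$", s))
  vapply(m, function(g) {
    if (length(g) != 3L) stop("not a HH:MM clock time: '",
                              paste(g, collapse = ""), "'")
    h <- as.integer(g[2]); mm <- as.integer(g[3])
    if (h > 23 || mm > 59) stop("clock time out of range: ", g[1])
    h * 60L + mm
  }, integer(1))
}

#' Format minutes after midnight as "HH:MM"
#'
#' @param minutes Integer minutes after midnight, in `[0, 1440)`.
#' @export
format_clock <- function(minutes) {
  minutes <- as.integer(minutes) %% 1440L
  sprintf("%02d:%02d", minutes %/% 60L, minutes %% 60L)
}

#' Localize UTC epochs to a user's wall clock
#'
#' Converts UTC epoch seconds to the minute-of-day on the wall clock of an
#' IANA time zone, observing the zone's full offset history (so daylight
#' saving is applied per post, at the instant of the post).
#'
#' @param epochs Numeric vector of UTC epoch seconds for one user.
#' @param tz_name IANA zone identifier (e.g. `"America/New_York"`).
#' @param author_id Optional author label carried along.
#' @return An object of class `localized_posts`: a list with `author_id`,
#'   `tz_name`, `local_minutes` (integer minute-of-day in `[0, 1439]`) and
#'   `n_posts`.
#' @export
localize <- function(epochs, tz_name, author_id = NA_character_) {
  if (!is.character(tz_name) || length(tz_name) != 1L ||
      !(tz_name %in% OlsonNames())) {
    stop("unknown IANA time zone: ", tz_name)
  }
  stopifnot(is.numeric(epochs), length(epochs) >= 1L, all(epochs >= 0))
  lt <- as.POSIXlt(as.POSIXct(epochs, origin = "1970-01-01", tz = "UTC"),
                   tz = tz_name)
  mins <- lt$hour * 60L + lt$min
  structure(list(author_id = author_id, tz_name = tz_name,
                 local_minutes = as.integer(mins),
                 n_posts = length(mins)),
            class = "localized_posts")
}

#' Localize a whole post set
#'
#' @param posts A `post_set` from [read_posts()].
#' @param meta Metadata data.frame from [read_meta()]. Users without a
#'   time-zone entry are skipped.
#' @return A named list of `localized_posts`, one per user present in both
#'   inputs, with attribute `no_timezone` listing authors lacking a zone.
#' @export
localize_all <- function(posts, meta) {
  tz <- stats::setNames(meta$tz_name, meta$author_id)
  have <- names(posts) %in% names(tz)
  out <- lapply(names(posts)[have], function(a) {
    localize(posts[[a]], tz[[a]], author_id = a)
  })
  names(out) <- names(posts)[have]
  structure(out, no_timezone = names(posts)[!have])
}

#' Round a clock time to the 15-minute grid
#'
#' Circular rounding to the nearest 15-minute grid point: 23:53 rounds
#' forward across midnight to 00:00. Within a 15-minute bin, minute offsets
#' 1--7 round down and 8--14 round up (nearest integer minute; 7.5 minutes
#' never occurs at 1-minute resolution).
#'
#' @param minutes Integer minutes after midnight in `[0, 1440)`.
#' @return Minutes after midnight on the 15-minute grid (divisible by 15).
#' @examples
#' round_bedtime(parse_clock("23:53"))  # 0, i.e. midnight
#' @export
round_bedtime <- function(minutes) {
  stopifnot(all(minutes >= 0), all(minutes < 1440))
  minutes <- as.integer(minutes)
  (15L * (minutes %/% 15L + as.integer(minutes %% 15L >= 8L))) %% 1440L
}

#' @export
print.localized_posts <- function(x, ...) {
  cat("<localized_posts> user", x$author_id, "zone", x$tz_name,
      "-", x$n_posts, "posts\n")
  invisible(x)
}
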