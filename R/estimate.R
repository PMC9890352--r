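# Bedtime estimation: rotate the fitted unified curve into 96
# bedtime-specific templates and match each user's fingerprint against the
# bank by Spearman rank correlation.

#' Build the bank of bedtime-specific templates
#'
#' Relabels the unified model's bedtime point with each of the 96 candidate
#' clock times (00:00, 00:15, ...) by cyclically rotating the model curve
#' onto clock-time bins: template `k` places the model's `x = 0` bin at
#' clock bin `k` (bedtime label `15k` minutes). Templates are pure
#' rotations of one another.
#'
#' @param m A `unified_model`.
#' @return An object of class `template_set`: a 96 x 96 matrix, one row per
#'   candidate bedtime (row `k + 1` is bedtime `15k` minutes), columns the
#'   96 clock bins; each row sums to one.
#' @export
make_templates <- function(m) {
  stopifnot(inherits(m, "unified_model"))
  r <- eval_model(m)                    # indexed by relative_x_grid()
  tmpl <- matrix(0, 96L, 96L)
  i <- seq_len(96L)
  for (k in 0:95) {
    # clock bin (k + (i - .ZERO_INDEX)) mod 96 holds relative bin i
    tmpl[k + 1L, (k + (i - .ZERO_INDEX)) %% 96L + 1L] <- r
  }
  dimnames(tmpl) <- list(bedtime = format_clock(15L * (0:95)),
                         clock_bin = format_clock(15L * (0:95)))
  structure(tmpl, class = c("template_set", "matrix"))
}

#' @export
print.template_set <- function(x, ...) {
  cat("<template_set> 96 bedtime-specific curves x 96 clock bins\n")
  invisible(x)
}

# Deterministic argmax over tied template correlations: prefer the tied
# candidate closest (on the circle) to the circular mean of all tied
# candidates; any remaining tie goes to the candidate reached first moving
# clockwise from 12:00 noon.
resolve_tie <- function(tied_minutes) {
  if (length(tied_minutes) == 1L) return(tied_minutes)
  mu <- tryCatch(circular_mean(tied_minutes), error = function(e) NULL)
  if (!is.null(mu)) {
    dd <- circular_diff(tied_minutes, mu)
    tied_minutes <- tied_minutes[dd == min(dd)]
  }
  order_from_noon <- (tied_minutes - 720L) %% 1440L
  tied_minutes[which.min(order_from_noon)]
}

#' Estimate one user's bedtime by template matching
#'
#' Computes the Spearman rank correlation (average ranks for ties; the flat
#' section makes ties pervasive) between the user's circadian fingerprint
#' and each of the 96 bedtime-specific templates, and returns the bedtime
#' label of the best-matching template.
#'
#' @param fp A `circadian_fingerprint`.
#' @param templates A `template_set` from [make_templates()].
#' @param author_id Optional label carried into the result.
#' @return A one-row data.frame (class `bedtime_estimate`) with columns
#'   `author_id`, `bedtime` (minutes after midnight, 15-minute grid; `NA`
#'   if degenerate), `rho`, `n_posts` and `status` (`"ok"` or
#'   `"degenerate_fingerprint"` when the fingerprint has fewer than two
#'   distinct values and rank correlation is undefined).
#' @export
estimate_bedtime <- function(fp, templates, author_id = NA_character_) {
  stopifnot(inherits(fp, "circadian_fingerprint"),
            inherits(templates, "template_set"))
  if (length(unique(fp$values)) < 2L || sum(fp$values > 0) < 2L) {
    return(structure(data.frame(author_id = author_id,
                                bedtime = NA_integer_, rho = NA_real_,
                                n_posts = fp$n_posts,
                                status = "degenerate_fingerprint",
                                stringsAsFactors = FALSE),
                     class = c("bedtime_estimate", "data.frame")))
  }
  rho <- apply(templates, 1L, stats::cor, y = fp$values,
               method = "spearman")
  best <- max(rho)
  tied <- which(rho >= best - 1e-12)
  bedtime <- resolve_tie(15L * (tied - 1L))
  structure(data.frame(author_id = author_id, bedtime = bedtime,
                       rho = best, n_posts = fp$n_posts, status = "ok",
                       stringsAsFactors = FALSE),
            class = c("bedtime_estimate", "data.frame"))
}

#' Estimate bedtimes for a collection of users
#'
#' Applies the eligibility floor on post count, estimates each remaining
#' user with [estimate_bedtime()], and returns one row per input user with
#' a status/reason code for the skipped ones.
#'
#' @param users Named list of `localized_posts` (or of
#'   `circadian_fingerprint`) objects.
#' @param templates A `template_set`.
#' @param min_posts Minimum post count for estimation (default 250, the
#'   activity floor for a stable fingerprint).
#' @return Data.frame with columns `author_id`, `bedtime`, `rho`,
#'   `n_posts`, `status`; attribute `histogram` holds the count of
#'   estimates in each 15-minute bedtime bin.
#' @export
estimate_batch <- function(users, templates, min_posts = 250L) {
  stopifnot(min_posts >= 1L)
  rows <- lapply(seq_along(users), function(i) {
    u <- users[[i]]
    id <- if (!is.null(names(users))) names(users)[i] else
      if (inherits(u, "localized_posts")) u$author_id else NA_character_
    fp <- if (inherits(u, "circadian_fingerprint")) u else
      compute_fingerprint(u)
    if (fp$n_posts < min_posts) {
      return(data.frame(author_id = id, bedtime = NA_integer_,
                        rho = NA_real_, n_posts = fp$n_posts,
                        status = "too_few_posts", stringsAsFactors = FALSE))
    }
    as.data.frame(estimate_bedtime(fp, templates, author_id = id))
  })
  out <- if (length(rows) == 0L) {
    data.frame(author_id = character(), bedtime = integer(),
               rho = numeric(), n_posts = integer(),
               status = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  est <- out$bedtime[!is.na(out$bedtime)]
  hist96 <- tabulate(est %/% 15L + 1L, nbins = 96L)
  names(hist96) <- format_clock(15L * (0:95))
  attr(out, "histogram") <- hist96
  out
}
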