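# k-fold cross-validation of the bedtime estimator on a labeled cohort.

#' Randomly partition users into k near-equal folds
#'
#' Users are randomly permuted and dealt into `k` folds whose sizes differ
#' by at most one; the assignment is deterministic given the seed.
#'
#' @param ids Vector of user identifiers (`length(ids) >= k`).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` disjoint id vectors covering `ids`.
#' @export
partition <- function(ids, k = 3L, seed = 1L) {
  n <- length(ids)
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  perm <- sample(ids)
  split(perm, rep_len(seq_len(k), n))
}

#' k-fold cross-validation of bedtime estimation
#'
#' For every seed, users are partitioned into `k` folds; each fold in turn
#' is held out while the unified model is fitted to the aggregate
#' bedtime-relative profile of the remaining folds, turned into templates,
#' and used to estimate the bedtimes of both partitions. Per run the
#' circular correlation between estimated and reported bedtimes is
#' recorded for the training and hold-out users, along with hold-out
#' within-1-hour / within-2-hour counts; medians and IQRs across runs
#' summarise the report. A fitting failure marks that run failed and the
#' sweep continues.
#'
#' @param fingerprints Named list of `circadian_fingerprint`, one per user.
#' @param reported Named vector of reported bedtimes (minutes after
#'   midnight) covering the same users; values are snapped to the
#'   15-minute grid.
#' @param k Number of folds (default 3).
#' @param seeds Integer vector of partition seeds (default `1:10`).
#' @param min_posts Post floor passed to estimation.
#' @return An object of class `cv_report`: list with `runs` (one row per
#'   seed x fold) and `summary` (medians and IQRs of training and hold-out
#'   correlations).
#' @export
kfold_validate <- function(fingerprints, reported, k = 3L, seeds = 1:10,
                           min_posts = 1L) {
  ids <- names(fingerprints)
  stopifnot(length(ids) > 0L, all(ids %in% names(reported)))
  reported <- round_bedtime(reported[ids] %% 1440)
  names(reported) <- ids
  rows <- list()
  for (seed in seeds) {
    folds <- partition(ids, k = k, seed = seed)
    for (f in seq_len(k)) {
      hold <- folds[[f]]
      train <- setdiff(ids, hold)
      row <- data.frame(seed = seed, fold = f, n_train = length(train),
                        n_holdout = length(hold), train_corr = NA_real_,
                        holdout_corr = NA_real_, within_1h = NA_integer_,
                        within_2h = NA_integer_, failed = TRUE)
      res <- tryCatch({
        prof <- aggregate_profiles(lapply(train, function(a) {
          to_relative(fingerprints[[a]], reported[[a]])
        }))
        m <- fit_unified(prof)
        ts <- make_templates(m)
        est_of <- function(who) {
          e <- estimate_batch(fingerprints[who], ts, min_posts = min_posts)
          ok <- e$status == "ok"
          list(est = e$bedtime[ok], rep = unname(reported[who][ok]))
        }
        tr <- est_of(train); ho <- est_of(hold)
        acc <- accuracy_report(ho$est, ho$rep)
        row$train_corr <- suppressWarnings(circular_corr(tr$est, tr$rep))
        row$holdout_corr <- acc$circ_corr
        row$within_1h <- acc$within_1h
        row$within_2h <- acc$within_2h
        row$failed <- FALSE
        row
      }, error = function(e) row)
      rows[[length(rows) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, rows)
  ok <- !runs$failed
  structure(list(
    runs = runs,
    summary = list(
      train_median = stats::median(runs$train_corr[ok]),
      train_iqr = unname(stats::quantile(runs$train_corr[ok],
                                         c(0.25, 0.75), na.rm = TRUE)),
      holdout_median = stats::median(runs$holdout_corr[ok]),
      holdout_iqr = unname(stats::quantile(runs$holdout_corr[ok],
                                           c(0.25, 0.75), na.rm = TRUE)),
      n_runs = nrow(runs), n_failed = sum(runs$failed))),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  s <- x$summary
  cat("<cv_report>", s$n_runs, "runs (", s$n_failed, "failed )\n")
  cat(sprintf("  training correlation: median %.3f (IQR %.3f-%.3f)\n",
              s$train_median, s$train_iqr[1], s$train_iqr[2]))
  cat(sprintf("  hold-out correlation: median %.3f (IQR %.3f-%.3f)\n",
              s$holdout_median, s$holdout_iqr[1], s$holdout_iqr[2]))
  invisible(x)
}

#' Fit the released model on all labeled users
#'
#' The final model uses every labeled user in training (no hold-out): the
#' aggregate bedtime-relative profile of the whole cohort is fitted once.
#'
#' @inheritParams kfold_validate
#' @return A `unified_model`.
#' @export
final_model <- function(fingerprints, reported) {
  ids <- names(fingerprints)
  reported <- round_bedtime(reported[ids] %% 1440)
  fit_unified(aggregate_profiles(lapply(seq_along(ids), function(i) {
    to_relative(fingerprints[[i]], reported[[i]])
  })))
}
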