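# The unified circadian posting model: a flat daytime posting rate with a
# quadratic night-time depletion, on the 96-bin bedtime-relative grid.
#
# The fraction r of a user's posts in the 15-minute bin starting x hours
# after bedtime is modelled as
#     r(x) = a x^2 + b x + c   for -S <= x <= E   (parabolic section)
#     r(x) = d                 otherwise          (flat section)
# with d fixed by normalization so the 96 bins sum to one:
#     d = (1 - sum_{section bins} (a x^2 + b x + c)) / (96 - k),
# k the number of parabolic bins. S and E are chosen by exhaustive grid
# search in 15-minute increments; (a, b, c) by ordinary least squares
# within each (S, E) candidate.

section_index <- function(S, E) {
  xg <- relative_x_grid()
  which(xg >= -S & xg <= E)
}

#' Flat-section height from the normalization constraint
#'
#' Given the parabolic section bounds and quadratic coefficients, returns
#' the constant per-bin frequency `d` of the flat section that makes all 96
#' modelled bins sum to one. A negative result marks the `(S, E)` candidate
#' invalid during fitting (a frequency cannot be negative); it is returned
#' as-is rather than raised, so the grid search can discard it.
#'
#' @param S Hours before bedtime of the first parabolic bin start
#'   (nonnegative multiple of 0.25).
#' @param E Hours after bedtime of the last parabolic bin start (multiple
#'   of 0.25).
#' @param a,b,c Quadratic coefficients, `x` in signed hours after bedtime.
#' @return The flat height `d` (fraction per 15-minute bin); `NA` if the
#'   parabolic section spans all 96 bins.
#' @examples
#' flat_height(0.75, 10, 4.12e-4, -3.81e-3, 1.06e-2)  # ~0.0142
#' @export
flat_height <- function(S, E, a, b, c) {
  idx <- section_index(S, E)
  k <- length(idx)
  if (k < 3L) stop("parabolic section must contain at least 3 bins")
  if (k == 96L) return(NA_real_)
  x <- relative_x_grid()[idx]
  (1 - sum(a * x^2 + b * x + c)) / (96L - k)
}

#' Construct a unified model
#'
#' Validates the piecewise-model invariants: at least 3 parabolic bins,
#' nonnegative flat height, all 96 modelled values nonnegative, and total
#' mass 1 within 1e-9. `d` is derived from the normalization constraint
#' when not supplied.
#'
#' @inheritParams flat_height
#' @param d Flat height; computed via [flat_height()] if `NULL`.
#' @param mse,pearson Optional fit diagnostics carried on the object.
#' @return An object of class `unified_model`.
#' @export
unified_model <- function(S, E, a, b, c, d = NULL, mse = NA_real_,
                          pearson = NA_real_) {
  stopifnot(S >= 0, (S * 4) %% 1 == 0, (E * 4) %% 1 == 0)
  if (is.null(d)) d <- flat_height(S, E, a, b, c)
  m <- structure(list(S = S, E = E, a = a, b = b, c = c, d = d,
                      mse = mse, pearson = pearson),
                 class = "unified_model")
  v <- eval_model(m, check = FALSE)
  if (length(section_index(S, E)) < 3L) {
    stop("parabolic section must contain at least 3 bins")
  }
  if (is.na(d) || d < 0) stop("flat height d is negative or undefined")
  if (any(v < -1e-12)) stop("model has negative bin values")
  if (abs(sum(v) - 1) > 1e-9) stop("model bins do not sum to 1")
  m
}

#' Evaluate a unified model on the relative grid
#'
#' @param m A `unified_model`.
#' @param check Validate invariants before evaluating.
#' @return Numeric vector of 96 expected per-bin frequencies at the
#'   bin-start offsets of `relative_x_grid()`, summing to one.
#' @export
eval_model <- function(m, check = TRUE) {
  if (check) stopifnot(inherits(m, "unified_model"))
  xg <- relative_x_grid()
  v <- rep(m$d, 96L)
  idx <- section_index(m$S, m$E)
  v[idx] <- m$a * xg[idx]^2 + m$b * xg[idx] + m$c
  v
}

#' Least-squares quadratic fit for one (S, E) candidate
#'
#' Fits the degree-2 polynomial to the profile values over the parabolic
#' section's bin starts by unweighted ordinary least squares, derives the
#' flat height from normalization, and scores the full 96-bin curve by mean
#' squared error against the profile.
#'
#' @param profile A `relative_profile`.
#' @param S,E Candidate section bounds (hours, multiples of 0.25).
#' @return List with `a`, `b`, `c`, `d`, `mse`, `valid` (`FALSE` when the
#'   candidate yields a negative flat height or any negative modelled
#'   value), and `values` (the 96 modelled frequencies).
#' @export
fit_quadratic <- function(profile, S, E) {
  stopifnot(inherits(profile, "relative_profile"))
  idx <- section_index(S, E)
  if (length(idx) < 3L) stop("parabolic section must contain at least 3 bins")
  xg <- relative_x_grid()
  x <- xg[idx]
  y <- profile$values[idx]
  X <- cbind(1, x, x * x)
  beta <- unname(qr.solve(X, y))
  c0 <- beta[1]; b <- beta[2]; a <- beta[3]
  d <- flat_height(S, E, a, b, c0)
  v <- rep(d, 96L)
  v[idx] <- a * xg[idx]^2 + b * xg[idx] + c0
  valid <- !is.na(d) && d >= 0 && all(v >= -1e-12)
  list(a = a, b = b, c = c0, d = d,
       mse = mean((v - profile$values)^2), valid = valid, values = v)
}

#' Fit the unified model by exhaustive grid search
#'
#' Sweeps every combination of the parabolic start `S` in 0, 0.25, ..., 6
#' hours before bedtime and end `E` in 0.25, ..., 11.75 hours after bedtime
#' (15-minute increments), requiring at least 3 bins in the section. For
#' each candidate, the quadratic is fitted by [fit_quadratic()]; candidates
#' whose flat height is negative or whose curve dips below zero are
#' discarded, since a posting frequency cannot be negative. The candidate
#' with the lowest mean squared error over all 96 bins wins; exact ties go
#' to the narrower section, then the smaller `S`, so the result is
#' deterministic.
#'
#' @param profile A `relative_profile` (typically the aggregate of many
#'   users' bedtime-relative fingerprints).
#' @param s_max,e_max Upper grid bounds for `S` and `E`, in hours.
#' @return A `unified_model` carrying `mse` and `pearson` (correlation of
#'   modelled vs observed bin values).
#' @export
fit_unified <- function(profile, s_max = 6, e_max = 11.75) {
  stopifnot(inherits(profile, "relative_profile"))
  tol <- 1e-15
  best <- NULL
  for (S in seq(0, s_max, by = 0.25)) {
    for (E in seq(0.25, e_max, by = 0.25)) {
      if ((E + S) / 0.25 + 1 < 3) next
      fit <- fit_quadratic(profile, S, E)
      if (!fit$valid) next
      width <- E + S
      if (is.null(best) ||
          fit$mse < best$mse - tol ||
          (abs(fit$mse - best$mse) <= tol &&
           (width < best$width ||
            (width == best$width && S < best$S)))) {
        best <- c(fit, list(S = S, E = E, width = width))
      }
    }
  }
  if (is.null(best)) stop("no valid (S, E) combination found")
  unified_model(best$S, best$E, best$a, best$b, best$c, d = best$d,
                mse = best$mse,
                pearson = suppressWarnings(stats::cor(best$values,
                                                      profile$values)))
}

#' Depth of the modelled night-time depletion
#'
#' The modelled posting rate at the parabola's minimum, expressed as a
#' fractional reduction relative to the flat daytime rate `d`. When the
#' parabola opens upward with its vertex inside the section the minimum is
#' the analytic vertex value `c - b^2 / (4a)`; otherwise the lowest
#' evaluated section bin is used.
#'
#' @param m A `unified_model`.
#' @return Fraction in `[0, 1]`: 0.87 means the nadir is 87% below the
#'   daytime rate.
#' @export
nadir_depletion <- function(m) {
  stopifnot(inherits(m, "unified_model"))
  vx <- if (m$a > 0) -m$b / (2 * m$a) else NA_real_
  mn <- if (!is.na(vx) && vx >= -m$S && vx <= m$E) {
    m$c - m$b^2 / (4 * m$a)
  } else {
    idx <- section_index(m$S, m$E)
    min(eval_model(m)[idx])
  }
  1 - mn / m$d
}

#' @export
print.unified_model <- function(x, ...) {
  cat("<unified_model>\n",
      sprintf("  parabolic section: %.2f h before to %.2f h after bedtime (%d bins)\n",
              x$S, x$E, length(section_index(x$S, x$E))),
      sprintf("  a = %.4g, b = %.4g, c = %.4g, d = %.4g\n",
              x$a, x$b, x$c, x$d),
      sprintf("  mse = %.4g, pearson = %.4g\n", x$mse, x$pearson), sep = "")
  invisible(x)
}

#' Serialize / restore a fitted model as JSON
#'
#' @param m A `unified_model`.
#' @param path Output (or input) JSON path.
#' @export
write_model <- function(m, path) {
  stopifnot(inherits(m, "unified_model"))
  jsonlite::write_json(
    list(S = m$S, E = m$E, a = m$a, b = m$b, c = m$c, d = m$d,
         mse = m$mse, pearson = m$pearson,
         grid_spec = "96 bins of 15 min; x = hours after bedtime, bin starts -12..+11.75"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  unified_model(j$S, j$E, j$a, j$b, j$c, d = j$d,
                mse = j$mse %||% NA_real_, pearson = j$pearson %||% NA_real_)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Draw a random valid unified model
#'
#' Samples section bounds uniformly from the fitting grid and quadratic
#' coefficients with an interior minimum, retrying until the normalization
#' yields a valid curve (nonnegative flat height and bin values). Uses the
#' current RNG state; intended for simulation studies and property tests.
#'
#' @param s_max,e_max Grid bounds, as in [fit_unified()].
#' @return A `unified_model`.
#' @export
random_model <- function(s_max = 6, e_max = 11.75) {
  repeat {
    S <- sample(seq(0, s_max, by = 0.25), 1L)
    E <- sample(seq(max(0.25, 0.75 - S), e_max, by = 0.25), 1L)
    if ((E + S) / 0.25 + 1 < 3) next
    a <- stats::runif(1, 1e-4, 6e-4)
    xv <- stats::runif(1, -S, E)          # vertex inside the section
    b <- -2 * a * xv
    c0 <- stats::runif(1, 0, 4e-3) + a * xv^2   # min value >= 0
    d <- flat_height(S, E, a, b, c0)
    if (is.na(d) || d < 0) next
    m <- tryCatch(unified_model(S, E, a, b, c0, d = d),
                  error = function(e) NULL)
    if (!is.null(m)) return(m)
  }
}
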