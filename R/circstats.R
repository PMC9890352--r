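# Circular statistics on clock times. Clock times are treated as angles on
# the 24-hour circle (1440 minutes = 2 pi); all summaries are invariant
# under a common rotation of their inputs.

minutes_to_angle <- function(minutes) minutes / 1440 * 2 * pi
angle_to_minutes <- function(theta) (theta %% (2 * pi)) / (2 * pi) * 1440

#' Circular mean of clock times
#'
#' The direction of the mean resultant vector of the times on the 24-hour
#' circle, mapped back to the nearest minute. Used, e.g., to combine
#' repeated bedtime reports from one user.
#'
#' @param times Minutes after midnight, in `[0, 1440)`.
#' @return Minutes after midnight at 1-minute resolution.
#' @examples
#' format_clock(circular_mean(parse_clock(c("23:00", "01:00"))))  # "00:00"
#' @export
circular_mean <- function(times) {
  stopifnot(length(times) >= 1L)
  th <- minutes_to_angle(times)
  s <- mean(sin(th)); co <- mean(cos(th))
  if (sqrt(s^2 + co^2) <= 1e-9) {
    stop("circular mean undefined: near-zero resultant vector")
  }
  round(angle_to_minutes(atan2(s, co))) %% 1440
}

#' Circular standard deviation of clock times, in hours
#'
#' The standard circular SD, `sqrt(-2 log Rbar)` with `Rbar` the mean
#' resultant length, converted from radians to hours on the 24-hour circle.
#'
#' @inheritParams circular_mean
#' @export
circular_sd <- function(times) {
  th <- minutes_to_angle(times)
  rbar <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  sqrt(-2 * log(rbar)) * 24 / (2 * pi)
}

#' Shortest distance between clock times, in hours
#'
#' `min(|t1 - t2|, 24 - |t1 - t2|)`: the wrap-around distance on the
#' 24-hour circle, always in `[0, 12]`.
#'
#' @param t1,t2 Minutes after midnight (vectors recycle).
#' @export
circular_diff <- function(t1, t2) {
  dh <- abs(t1 - t2) / 60
  dh <- dh %% 24
  pmin(dh, 24 - dh)
}

#' Circular-circular correlation of paired clock times
#'
#' The angular correlation of Jammalamadaka and SenGupta: the correlation
#' of sine deviations from the respective circular means,
#' `sum sin(a - abar) sin(b - bbar) / sqrt(sum sin^2(a - abar) sum sin^2(b - bbar))`.
#' It lies in `[-1, 1]`, equals 1 when one variable is a fixed rotation of
#' the other, and is invariant to rotating either variable.
#'
#' @param est,rep Paired minutes after midnight, equal lengths `>= 3`.
#' @return The correlation coefficient, or `NA` (with a warning) when
#'   either sequence is constant and the coefficient is undefined.
#' @export
circular_corr <- function(est, rep) {
  stopifnot(length(est) == length(rep), length(est) >= 3L)
  a <- minutes_to_angle(est); b <- minutes_to_angle(rep)
  abar <- atan2(mean(sin(a)), mean(cos(a)))
  bbar <- atan2(mean(sin(b)), mean(cos(b)))
  sa <- sin(a - abar); sb <- sin(b - bbar)
  den <- sqrt(sum(sa^2) * sum(sb^2))
  if (den <= 1e-12) {
    warning("circular correlation undefined for constant input")
    return(NA_real_)
  }
  sum(sa * sb) / den
}

#' Accuracy summary for estimated vs reported bedtimes
#'
#' Counts estimates within 1 and within 2 hours (inclusive: exactly 60
#' minutes counts as within 1 hour) of the reported bedtime by circular
#' distance, plus the circular correlation of the paired times.
#'
#' @param est,rep Paired minutes after midnight.
#' @return List with `n`, `within_1h`, `within_2h`, `circ_corr`.
#' @export
accuracy_report <- function(est, rep) {
  stopifnot(length(est) == length(rep), length(est) >= 1L)
  d <- circular_diff(est, rep)
  list(n = length(est),
       within_1h = sum(d <= 1.0),
       within_2h = sum(d <= 2.0),
       circ_corr = if (length(est) >= 3L) {
         suppressWarnings(circular_corr(est, rep))
       } else NA_real_)
}
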