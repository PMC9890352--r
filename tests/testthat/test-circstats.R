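test_that("circular_mean follows the mean resultant vector", {
  expect_equal(circular_mean(parse_clock(c("23:00", "01:00"))), 0)
  expect_equal(circular_mean(parse_clock("22:00")), parse_clock("22:00"))
  # {21:00, 00:00, 00:00}: atan2 of summed sines/cosines -> 23:01
  expect_equal(circular_mean(c(1260, 0, 0)), parse_clock("23:01"))
  # antipodal pair has no defined mean
  expect_error(circular_mean(c(0, 720)), "undefined")
})

test_that("circular_diff is the wrap-around distance in [0, 12] hours", {
  expect_equal(circular_diff(parse_clock("23:00"), parse_clock("01:00")), 2)
  expect_equal(circular_diff(360, 360), 0)
  expect_equal(circular_diff(0, 720), 12)
  # symmetric, and triangle inequality on the circle
  set.seed(51)
  t1 <- sample(0:1439, 50); t2 <- sample(0:1439, 50); t3 <- sample(0:1439, 50)
  expect_equal(circular_diff(t1, t2), circular_diff(t2, t1))
  expect_true(all(circular_diff(t1, t3) <=
                    circular_diff(t1, t2) + circular_diff(t2, t3) + 1e-12))
})

test_that("circular summaries are invariant under common rotation", {
  set.seed(52)
  t1 <- sample(0:1439, 30)
  t2 <- sample(0:1439, 30)
  for (shift in c(90, 360, 1000)) {
    expect_equal(circular_mean((t1 + shift) %% 1440),
                 (circular_mean(t1) + shift) %% 1440)
    expect_equal(circular_corr((t1 + shift) %% 1440, t2),
                 circular_corr(t1, t2))
    expect_equal(circular_sd((t1 + shift) %% 1440), circular_sd(t1))
  }
})

test_that("circular_corr is 1 for rotations and matches a Monte-Carlo oracle", {
  set.seed(53)
  est <- sample(0:1439, 20)
  expect_equal(circular_corr(est, est), 1)
  expect_equal(circular_corr((est + 360) %% 1440, est), 1)

  # von Mises noise of known concentration: sample coefficient at n = 3000
  # vs the population value from an independently coded 1e5-draw oracle
  kappa <- 8
  mk_pairs <- function(n) {
    a <- rvonmises(n, pi, 2)
    b <- (a + rvonmises(n, 0, kappa)) %% (2 * pi)
    cbind(a, b)
  }
  js_corr_oracle <- function(a, b) {
    # Jammalamadaka-SenGupta, coded from the definition
    am <- atan2(sum(sin(a)), sum(cos(a)))
    bm <- atan2(sum(sin(b)), sum(cos(b)))
    num <- sum(sin(a - am) * sin(b - bm))
    num / sqrt(sum(sin(a - am)^2) * sum(sin(b - bm)^2))
  }
  big <- mk_pairs(1e5)
  pop <- js_corr_oracle(big[, 1], big[, 2])
  smp <- mk_pairs(3000)
  smp_min <- round(smp / (2 * pi) * 1440) %% 1440
  expect_lt(abs(circular_corr(smp_min[, 1], smp_min[, 2]) - pop), 0.02)
  expect_warning(out <- circular_corr(rep(300, 5), c(1, 2, 3, 4, 5)),
                 "constant")
  expect_true(is.na(out))
})

test_that("accuracy_report counts inclusively and matches a direct tally", {
  # identical pairs: everything within 1 h
  r <- accuracy_report(c(0, 100, 900), c(0, 100, 900))
  expect_equal(r$within_1h, 3L)
  # exactly 2 h across midnight is within 2 h but not 1 h
  r2 <- accuracy_report(parse_clock("23:00"), parse_clock("01:00"))
  expect_equal(c(r2$within_1h, r2$within_2h), c(0L, 1L))

  set.seed(54)
  est <- sample(0:1439, 200, replace = TRUE)
  rep_ <- sample(0:1439, 200, replace = TRUE)
  r3 <- accuracy_report(est, rep_)
  # brute-force recount with explicit wrap arithmetic
  n1 <- 0L; n2 <- 0L
  for (i in 1:200) {
    dm <- min(abs(est[i] - rep_[i]), 1440 - abs(est[i] - rep_[i]))
    if (dm <= 60) n1 <- n1 + 1L
    if (dm <= 120) n2 <- n2 + 1L
  }
  expect_equal(r3$within_1h, n1)
  expect_equal(r3$within_2h, n2)
  expect_gte(r3$within_2h, r3$within_1h)
})
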