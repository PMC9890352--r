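test_that("each bot rule is individually sufficient", {
  base <- as.numeric(as.POSIXct("2019-06-01 12:00:00", tz = "UTC"))
  # nine posts inside one clock minute
  fl <- bot_flags(rep(base, 9) + 0:8, username = "alice")
  expect_true(fl$burst); expect_true(fl$is_bot)
  expect_false(fl$volume); expect_false(fl$name)

  # 2^14 posts spread one per minute
  set.seed(61)
  fl2 <- bot_flags(base + 60 * seq_len(2^14), username = "carol")
  expect_true(fl2$volume); expect_true(fl2$is_bot)
  expect_false(fl2$burst)

  # flagged username substrings, case-insensitive
  for (nm in c("autotldr", "MODERATOR_jane", "AdminHelper", "rObOt9000")) {
    expect_true(bot_flags(base, username = nm)$name)
  }
  expect_false(bot_flags(base, username = "alice")$name)
})

test_that("periodicity threshold is exactly 2% of posts on one minute-of-day", {
  day <- 86400
  base <- as.numeric(as.POSIXct("2019-01-01 05:00:00", tz = "UTC"))
  # spread posts one per minute within distinct hours: unique minute-of-day
  spread <- function(n) base + 3600 * seq_len(n) + 60 * (seq_len(n) %% 50)
  # same minute-of-day (23:59, unreachable by the spread) across k days
  sched <- as.numeric(as.POSIXct("2019-01-01 23:59:00", tz = "UTC"))
  at_minute <- function(k) sched + day * seq_len(k)
  ep_hot <- c(spread(975), at_minute(25))           # 25/1000 = 2.5%
  expect_true(bot_flags(ep_hot, "u")$periodicity)
  ep_cool <- c(spread(981), at_minute(19))          # 19/1000 = 1.9%
  expect_false(bot_flags(ep_cool, "u")$periodicity)
  # local-clock schedules are caught when local minutes are supplied
  lm <- c(rep(300L, 30L), as.integer(seq(0, 1439, length.out = 970)))
  expect_true(bot_flags(spread(1000), "u", local_minutes = lm)$periodicity)
})

test_that("bot archetypes trip exactly their targeted rule", {
  for (arch in c("burst", "volume", "periodic", "named")) {
    bot <- simulate_bot(arch, seed = 5L)
    fl <- bot_flags(bot$epochs, username = bot$username)
    expect_true(fl$is_bot)
    want <- c(burst = "burst", volume = "volume",
              periodic = "periodicity", named = "name")[[arch]]
    for (rule in c("burst", "volume", "periodicity", "name")) {
      expect_identical(fl[[rule]], rule == want)
    }
  }
})

test_that("eligibility applies context-dependent rules with reason codes", {
  bot <- list(is_bot = TRUE)
  d1 <- check_eligibility(260, flags = bot, context = "application")
  expect_false(d1$eligible)
  expect_equal(d1$reasons, "bot_flagged")
  # training ignores bot flags: the bedtime report is evidence of humanity
  d2 <- check_eligibility(260, flags = bot, context = "training")
  expect_true(d2$eligible)
  d3 <- check_eligibility(249, context = "training")
  expect_equal(d3$reasons, "too_few_posts")
  d4 <- check_eligibility(300, bedtime_outlier = FALSE, context = "training")
  expect_true(d4$eligible)
  d5 <- check_eligibility(100, has_timezone = FALSE, flags = bot,
                          context = "application")
  expect_equal(sort(d5$reasons),
               sort(c("too_few_posts", "no_timezone", "bot_flagged")))
  expect_false(d5$eligible)
})

test_that("2-SD outlier exclusion is circular and matches a direct oracle", {
  keep <- exclude_outliers(rep(parse_clock(c("23:00", "23:30")), each = 10))
  expect_true(all(keep))
  keep2 <- exclude_outliers(c(rep(parse_clock("23:00"), 20),
                              parse_clock("11:00")))
  expect_equal(which(!keep2), 21L)

  # von Mises bedtimes: recompute the mask with cold circular arithmetic
  set.seed(62)
  bt <- round(rvonmises(150, 2 * pi * 1425 / 1440, 4) / (2 * pi) * 1440) %% 1440
  mask <- exclude_outliers(bt)
  th <- bt / 1440 * 2 * pi
  mu <- atan2(mean(sin(th)), mean(cos(th)))
  rbar <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  sd_h <- sqrt(-2 * log(rbar)) * 24 / (2 * pi)
  dh <- abs(bt / 60 - (mu %% (2 * pi)) / (2 * pi) * 24)
  dist <- pmin(dh %% 24, 24 - dh %% 24)
  expect_equal(mask, dist <= 2 * sd_h)

  # invariant under a common rotation of all bedtimes
  expect_equal(exclude_outliers((bt + 480) %% 1440), mask)
  expect_error(exclude_outliers(100), "length")
})
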