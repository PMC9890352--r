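ref <- default_model()  # S=0.75, E=10, a=4.12e-4, b=-3.81e-3, c=1.06e-2

test_that("eval_model evaluates the piecewise curve at bin starts", {
  # degenerate uniform model: flat quadratic at 1/96 everywhere
  u <- unified_model(1, 1, a = 0, b = 0, c = 1 / 96)
  expect_equal(eval_model(u), rep(1 / 96, 96))
  expect_equal(u$d, 1 / 96)

  # reference parameterization: 44 parabolic bins, 52 flat, nadir ~1.8e-3
  v <- eval_model(ref)
  idx <- bedtimer:::section_index(ref$S, ref$E)
  expect_length(idx, 44L)
  expect_equal(sum(v[-idx] == ref$d), 52L)
  expect_equal(min(v[idx]), 1.798e-3, tolerance = 1e-4)
  expect_equal(sum(v), 1)
})

test_that("modeled curves sum to one for random valid parameter sets", {
  set.seed(31)
  sums <- replicate(200, sum(eval_model(random_model())))
  expect_true(all(abs(sums - 1) <= 1e-9))
})

test_that("flat_height matches an independent summation oracle", {
  expect_equal(flat_height(1, 1, 0, 0, 1 / 96), 1 / 96)
  # reference coefficients reproduce the documented flat height to 3 s.f.
  expect_equal(signif(flat_height(0.75, 10, 4.12e-4, -3.81e-3, 1.06e-2), 3),
               0.0142)
  # random quadratics over a 44-bin section: (1 - sum)/52 recomputed cold
  set.seed(32)
  for (i in 1:25) {
    a <- runif(1, -1e-3, 1e-3); b <- runif(1, -5e-3, 5e-3)
    c0 <- runif(1, 0, 2e-2)
    acc <- 0
    for (x in seq(-0.75, 10, by = 0.25)) acc <- acc + a * x^2 + b * x + c0
    expect_equal(flat_height(0.75, 10, a, b, c0), (1 - acc) / 52)
  }
  expect_error(flat_height(0, 0.25, 0, 0, 0.01), "at least 3 bins")
})

test_that("fit_quadratic equals the closed-form least-squares solution", {
  # noiseless recovery of known coefficients
  m <- unified_model(2, 8, a = 3e-4, b = -2.4e-3, c = 8e-3)
  fit <- fit_quadratic(profile_from_model(m), m$S, m$E)
  expect_equal(fit$a, m$a, tolerance = 1e-9)
  expect_equal(fit$b, m$b, tolerance = 1e-9)
  expect_equal(fit$c, m$c, tolerance = 1e-9)
  expect_equal(fit$mse, 0, tolerance = 1e-18)

  # constant section values give a = b = 0, c = v
  pr <- profile_from_values(rep(1 / 96, 96))
  fitc <- fit_quadratic(pr, 1, 2)
  expect_equal(fitc$a, 0, tolerance = 1e-12)
  expect_equal(fitc$b, 0, tolerance = 1e-12)
  expect_equal(fitc$c, 1 / 96)

  # noisy values: agree with lm(), the independent OLS oracle
  set.seed(33)
  vals <- rexp(96); vals <- vals / sum(vals)
  prn <- profile_from_values(vals)
  idx <- bedtimer:::section_index(1.5, 9)
  x <- bedtimer:::relative_x_grid()[idx]
  ora <- unname(coef(lm(vals[idx] ~ x + I(x^2))))
  fitn <- fit_quadratic(prn, 1.5, 9)
  expect_equal(c(fitn$c, fitn$b, fitn$a), ora, tolerance = 1e-9)
})

test_that("fit_unified recovers a generating model exactly from its curve", {
  set.seed(34)
  for (i in 1:5) {
    m <- random_model()
    fit <- fit_unified(profile_from_model(m))
    expect_identical(c(fit$S, fit$E), c(m$S, m$E))
    expect_equal(c(fit$a, fit$b, fit$c, fit$d), c(m$a, m$b, m$c, m$d),
                 tolerance = 1e-9)
  }
})

test_that("fit_unified breaks exact ties by narrowest section then smallest S", {
  fit <- fit_unified(profile_from_values(rep(1 / 96, 96)))
  # every (S, E) fits a uniform profile perfectly; minimal width is 3 bins
  # (S + E = 0.5) and the smallest such S is 0
  expect_equal(fit$S, 0)
  expect_equal(fit$E, 0.5)
  expect_equal(fit$mse, 0, tolerance = 1e-18)
})

test_that("model constructor rejects invariant violations", {
  expect_error(unified_model(0, 0.25, 0, 0, 0.01), "at least 3 bins")
  # a deep parabola whose normalization would need a negative flat height
  expect_error(unified_model(0.75, 10, 0, 0, 0.03), "negative")
  expect_error(unified_model(0.75, 10, 4.12e-4, -3.81e-3, 1.06e-2, d = 0.5),
               "sum to 1")
})

test_that("model JSON serialization round-trips", {
  f <- tempfile(fileext = ".json")
  write_model(ref, f)
  back <- read_model(f)
  expect_equal(back[c("S", "E", "a", "b", "c", "d")],
               ref[c("S", "E", "a", "b", "c", "d")])
})

test_that("nadir depletion is ~87% for the reference curve", {
  expect_equal(round(100 * nadir_depletion(ref)), 87)
  # analytic vertex value agrees with a fine-grid minimisation oracle
  xs <- seq(-ref$S, ref$E, by = 1e-4)
  fine_min <- min(ref$a * xs^2 + ref$b * xs + ref$c)
  expect_equal(nadir_depletion(ref), 1 - fine_min / ref$d, tolerance = 1e-6)
})
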