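test_that("time scaling maps days affinely onto [0, 1]", {
  expect_equal(scale_time(c(1, 11, 21))$u, c(0, 0.5, 1))
  expect_equal(scale_time(c(1, 2))$u, c(0, 1))
  expect_equal(scale_time(c(1, 4, 7, 31))$u, c(0, 0.1, 0.2, 1.0))
  st <- scale_time(c(3, 10, 500))
  expect_equal(st$scaling[["offset"]] + st$u * st$scaling[["range"]],
               c(3, 10, 500))
  expect_error(scale_time(c(5)), "at least 2")
  expect_error(scale_time(c(5, 5, 5)), "degenerate")
})

test_that("polynomial fitting recovers exact structure and validates inputs", {
  # constant data: slope 0, zero rss, marked perfect
  f <- fit_polynomial(list(days = 1:3, values = c(5, 5, 5)), 1)
  expect_equal(unname(f$coefficients), c(5, 0), tolerance = 1e-12)
  expect_equal(f$rss, 0)
  expect_true(f$perfect)
  # noiseless line recovered exactly after the basis change
  days <- 1:10
  f <- fit_polynomial(list(days = days, values = 2 + 0.5 * days), 1)
  expect_equal(evaluate_fit(f, days), 2 + 0.5 * days, tolerance = 1e-10)
  expect_lt(f$rss, 1e-10)
  # n = p + 1 interpolates
  f <- fit_polynomial(list(days = c(1, 11), values = c(60, 70)), 1)
  expect_equal(evaluate_fit(f, c(1, 11)), c(60, 70), tolerance = 1e-10)
  expect_error(fit_polynomial(list(days = c(1, 11), values = c(60, 70)), 2),
               "insufficient points")
})

test_that("fit statistics agree with a reference lm fit", {
  set.seed(4)
  days <- sort(sample(1:500, 20))
  y <- 70 + 0.01 * days + rnorm(20, 0, 3)
  seg <- list(days = days, values = y)
  for (p in 1:4) {
    f <- fit_polynomial(seg, p)
    u <- (days - days[1]) / (days[20] - days[1])
    ref <- lm(y ~ poly(u, p, raw = TRUE))
    expect_equal(unname(f$coefficients), unname(coef(ref)), tolerance = 1e-8)
    expect_equal(f$rss, sum(residuals(ref)^2), tolerance = 1e-8)
    expect_equal(f$aic, AIC(ref), tolerance = 1e-8)
    expect_equal(f$standard_error, summary(ref)$sigma, tolerance = 1e-8)
    expect_equal(f$r_squared, summary(ref)$r.squared, tolerance = 1e-8)
    # rss reproduced by evaluating the fit at its own days
    expect_equal(sum((y - evaluate_fit(f, days))^2), f$rss,
                 tolerance = 1e-8 * max(f$rss, 1))
  }
})

test_that("rss is non-increasing in polynomial order on the same segment", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(6:30, 1)
    days <- cumsum(c(1, sample(1:90, n - 1, replace = TRUE)))
    seg <- list(days = days, values = rnorm(n, 70, 6))
    rss <- vapply(1:4, function(p) fit_polynomial(seg, p)$rss, numeric(1))
    expect_true(all(diff(rss) <= 1e-8))
  }
})

test_that("the Gaussian AIC follows the full-likelihood convention", {
  expect_equal(gaussian_aic(10, n = 10, order = 1),
               10 * log(2 * pi) + 10 + 6, tolerance = 1e-10)
  expect_equal(round(gaussian_aic(10, n = 10, order = 1), 4), 34.3788)
  # same n and rss: one extra order costs exactly +2
  expect_equal(gaussian_aic(3.7, n = 12, order = 2) -
                 gaussian_aic(3.7, n = 12, order = 1), 2)
  # halving rss at fixed n lowers AIC by n log 2
  expect_equal(gaussian_aic(8, n = 20, order = 3) -
                 gaussian_aic(4, n = 20, order = 3), 20 * log(2))
})

test_that("candidate orders honour the sparsity-conditional rules", {
  r <- rule_config()
  u <- rule_config(rule_mode = "UNRESTRICTED")
  # order capped below the number of values
  expect_equal(candidate_orders(2, 2, u), 1L)
  expect_equal(candidate_orders(3, 3, u), 1:2)
  expect_equal(candidate_orders(4, 4, u), 1:3)
  expect_equal(candidate_orders(5, 5, u), 1:4)
  expect_equal(candidate_orders(50, 50, u), 1:4)  # never above max_order
  # forced linear below 8 measurements, conditional mode only
  expect_equal(candidate_orders(7, 7, r), 1L)
  expect_equal(candidate_orders(8, 8, r), 1:4)
  expect_equal(candidate_orders(7, 7, u), 1:4)
  # segment length caps the order even for rich subjects
  expect_equal(candidate_orders(20, 3, r), 1:2)
  expect_equal(candidate_orders(20, 1, r), integer(0))
})

test_that("selection minimises AIC over the candidate set", {
  set.seed(21)
  s <- random_single_segment(25)
  m <- select_trajectory(s)
  seg <- m$segments[[1]]
  expect_equal(seg$fit$aic, min(seg$candidate_aics))
  expect_equal(seg$selected_order,
               as.integer(names(which.min(seg$candidate_aics))))
  expect_true(all(seg$fit$aic <= seg$candidate_aics))
})

test_that("a noiseless cubic is selected and two points give the exact line", {
  sp <- cohort_spec(n_subjects = 1, n_range = c(30, 30), noise_sd = 0,
                    order_probs = c(0, 0, 1, 0), seed = 303)
  g <- generate_subject(sp, 1)
  m <- select_trajectory(g$series)
  expect_equal(m$selected_orders, 3L)
  two <- make_series(c(1, 11), c(60, 70))
  m2 <- select_trajectory(two)
  expect_equal(m2$selected_orders, 1L)
  expect_equal(evaluate_fit(m2$segments[[1]]$fit, c(1, 11)), c(60, 70),
               tolerance = 1e-10)
  expect_true("FORCED_LINEAR" %in% m2$rule_flags)
})

test_that("equal-AIC ties break toward the lower order", {
  # noiseless quadratic with n >= 8: orders 2..4 all hit the rss floor, so
  # their AICs differ only by the +2-per-order penalty and 2 must win;
  # a manual tie (identical AIC values) must also resolve to the lowest order.
  days <- seq(1, 121, by = 15)
  y <- 70 + 3 * ((days - 1) / 120)^2
  m <- select_trajectory(make_series(days, y))
  expect_equal(m$selected_orders, 2L)
  aics <- m$segments[[1]]$candidate_aics
  expect_equal(unname(aics[["3"]] - aics[["2"]]), 2, tolerance = 1e-8)
  expect_equal(unname(aics[["4"]] - aics[["2"]]), 4, tolerance = 1e-8)
})

test_that("selection and predictions are invariant to shifting all days", {
  set.seed(33)
  for (rep in 1:10) {
    s <- random_single_segment(sample(5:30, 1))
    shift <- sample(1000:100000, 1)
    s2 <- make_series(s$days + shift, s$values, id = s$subject_id)
    m1 <- select_trajectory(s)
    m2 <- select_trajectory(s2)
    expect_identical(m1$selected_orders, m2$selected_orders)
    f1 <- m1$segments[[1]]$fit
    f2 <- m2$segments[[1]]$fit
    expect_equal(f1$rss, f2$rss, tolerance = 1e-8)
    expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
    expect_equal(evaluate_fit(f1, s$days), evaluate_fit(f2, s$days + shift),
                 tolerance = 1e-8)
  }
})

test_that("degenerate constant outcomes select the linear model", {
  m <- select_trajectory(make_series(seq(1, 400, by = 40), rep(70, 10)))
  expect_equal(m$selected_orders, 1L)
  expect_equal(unname(m$segments[[1]]$fit$coefficients), c(70, 0),
               tolerance = 1e-10)
})

test_that("per-segment selection works and unmodellable subjects are flagged", {
  # sparse subject with a long gap: two segments, each fitted independently
  days <- c(1, 30, 60, 90, 120, 150, 400, 430, 460, 490)
  set.seed(5)
  s <- make_series(days, 70 + rnorm(10, 0, 3))
  m <- select_trajectory(s)
  expect_true(all(c("SEGMENTED") %in% m$rule_flags))
  expect_length(m$segments, 2)
  expect_false(anyNA(m$selected_orders))
  # a 2-point segment separated from a singleton: singleton is unmodellable
  s2 <- make_series(c(1, 30, 300), c(70, 71, 72))
  m2 <- select_trajectory(s2)
  expect_true("UNMODELLABLE_SEGMENT" %in% m2$rule_flags)
  expect_equal(m2$selected_orders, c(1L, NA))
})
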