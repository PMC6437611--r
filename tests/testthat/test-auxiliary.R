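test_that("multiplier arithmetic and homogeneity", {
  expect_equal(multiplier_estimate(50, 0.5)$point, 100)
  expect_equal(multiplier_estimate(100, 1.0)$point, 100)
  # homogeneous in the count
  e1 <- multiplier_estimate(30, 0.25)$point
  e2 <- multiplier_estimate(90, 0.25)$point
  expect_equal(e2, 3 * e1)
  # never below the enumerated count
  set.seed(2)
  for (i in 1:20) {
    cnt <- sample(10:500, 1); p <- runif(1, 0.05, 1)
    expect_gte(multiplier_estimate(cnt, p)$point, cnt)
  }
  expect_error(multiplier_estimate(50, 0), class = "rdsize_error_multiplier")
})

test_that("delta-method interval agrees with a parametric bootstrap", {
  cnt <- 120; p <- 0.4; se <- 0.03
  est <- multiplier_estimate(cnt, p, proportion_se = se)
  set.seed(7)
  boot <- cnt / pmin(pmax(rnorm(1e4, p, se), 1e-6), 1)
  bq <- quantile(boot, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(est$low - bq[1]) / bq[1], 0.05)
  expect_lt(abs(est$high - bq[2]) / bq[2], 0.05)
})

test_that("wisdom of the crowds averages valid guesses", {
  expect_equal(wisdom_of_crowds(c(10, 20, 30))$point, 20)
  expect_equal(wisdom_of_crowds(42)$point, 42)
  msg <- capture.output(
    w <- wisdom_of_crowds(c(5, -1, NA, Inf, 15)), type = "message")
  expect_equal(w$point, 10)
  expect_equal(w$n_used, 2)
  expect_match(paste(msg, collapse = " "), "dropped 3")
  expect_error(wisdom_of_crowds(c(-1, NA)), class = "rdsize_error_woc")
  # mean of lognormal guesses approaches the distribution mean
  set.seed(5)
  g <- rlnorm(1e4, log(500), 0.8)
  est <- wisdom_of_crowds(g)$point
  mu <- 500 * exp(0.8^2 / 2)
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(est - mu), 3 * se)
})

test_that("compare_methods flags estimates outside the expert range", {
  b <- expert_bounds(c(167, 300), c(584, 584), c(1000, 1446))
  est <- dplyr::bind_rows(
    multiplier_estimate(150, 0.05, method = "object_multiplier"), # 3000
    wisdom_of_crowds(c(500, 700)),
    tibble::tibble(method = "sspse", point = 596))
  cmp <- compare_methods(est, b)
  expect_equal(cmp$implausible, c(TRUE, FALSE, FALSE))
  expect_equal(cmp$min_low[1], 167)
  expect_equal(cmp$max_high[1], 1446)
  expect_error(compare_methods(est[0, ], b), class = "rdsize_error_compare")
})

test_that("published comparison table flags the known implausible entries", {
  t2 <- armenia_table2()
  pg <- t2[t2$population == "PWID" & t2$city == "Gyumri", ]
  b <- expert_bounds(c(pg$expert_low, pg$expert_low),
                     c(pg$expert_median, pg$expert_median),
                     c(pg$expert_high, pg$expert_high))
  cmp <- compare_methods(
    tibble::tibble(method = c("object_multiplier", "sspse_visibility"),
                   point = c(pg$object_multiplier, pg$sspse_visibility)), b)
  expect_true(cmp$implausible[cmp$method == "object_multiplier"])  # 3000
  expect_false(cmp$implausible[cmp$method == "sspse_visibility"]) # 596
})
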