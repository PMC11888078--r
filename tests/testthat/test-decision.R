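test_that("plane classification sums and aggregates are exact", {
  one_each <- make_draws(1, 1, 1, 1)
  pl <- classify_plane(one_each)
  expect_equal(c(pl$se, pl$sw, pl$ne, pl$nw), rep(25, 4))
  expect_equal(pl$south, 50)
  expect_equal(pl$east, 50)

  set.seed(31)
  for (i in 1:10) {
    draws <- data.frame(delta_qaly = rnorm(500), delta_cost = rnorm(500))
    p <- classify_plane(draws)
    expect_equal(p$se + p$sw + p$ne + p$nw, 100)
    expect_equal(p$south, p$se + p$sw)
    expect_equal(p$east, p$se + p$ne)
    # south + north and east + west partition the plane
    expect_equal(p$south + (p$ne + p$nw), 100)
    expect_equal(p$east + (p$sw + p$nw), 100)
  }
  # boundary draws go to the positive side
  b <- classify_plane(data.frame(delta_qaly = 0, delta_cost = 0))
  expect_equal(b$ne, 100)
  expect_error(classify_plane(make_draws(0, 0, 0, 0)), "nonempty")
})

test_that("all-dominant draw sets give certainty at every threshold", {
  draws <- make_draws(50, 0, 0, 0)
  expect_equal(classify_plane(draws)$se, 100)
  cv <- ceac(draws, c(0, 1e4, 1e6))
  expect_equal(cv$probability, rep(1, 3))
})

test_that("net monetary benefit follows the decision rule", {
  expect_equal(nmb(0.0046, -899.45, 0), 899.45)
  expect_equal(nmb(0.0046, -899.45, 80976), 80976 * 0.0046 + 899.45)
  expect_equal(nmb(0.0046, -899.45, 80976), 1271.94, tolerance = 1e-4)
  expect_equal(nmb(0, 0, 123456), 0)
  expect_error(nmb(1, 1, -5), "threshold")
})

test_that("the WTP grid multiplies the GDP anchor exactly", {
  g <- wtp_grid(80976)
  expect_equal(unname(g$thresholds), c(80976, 121464, 242928))
  expect_equal(unname(g$thresholds["1.5x"]), 80976 * 1.5)
  expect_equal(range(g$display_thresholds), c(0, 242928))
  expect_error(wtp_grid(-1), "positive")
  expect_error(wtp_grid(80976, c(3, 1)), "increasing")
})

test_that("CEAC equals brute-force NMB classification", {
  # dual route: the curve must agree with explicit draw-by-draw counting
  set.seed(99)
  for (i in 1:100) {
    n <- sample(10:10000, 1)
    draws <- data.frame(delta_qaly = rnorm(n, 0.002, 0.01),
                        delta_cost = rnorm(n, -100, 1000))
    lam <- runif(3, 0, 3 * 80976)
    cv <- ceac(draws, lam)
    brute <- vapply(lam, function(l) {
      sum(l * draws$delta_qaly - draws$delta_cost > 0) / n
    }, 0)
    expect_identical(cv$probability, brute)
  }
})

test_that("CEAC endpoints and restricted monotonicity hold", {
  draws <- data.frame(delta_qaly = c(0.01, 0.01),
                      delta_cost = c(100, -100))
  cv <- ceac(draws, c(0, 20000))
  expect_equal(cv$probability, c(0.5, 1.0))

  set.seed(7)
  for (i in 1:10) {
    d <- data.frame(delta_qaly = abs(rnorm(300, 0.005, 0.003)) + 1e-9,
                    delta_cost = rnorm(300, 0, 800))
    lam <- seq(0, 3 * 80976, length.out = 50)
    pr <- ceac(d, lam)$probability
    # with every draw effective, the curve is non-decreasing in lambda
    expect_true(all(diff(pr) >= 0))
    expect_equal(pr[1], mean(d$delta_cost < 0))
    expect_equal(ceac(d, 1e12)$probability, mean(d$delta_qaly > 0))
  }
})

test_that("ICUR reports ratio, quadrant, and dominance", {
  r <- icur(-899.45, 0.0046)
  expect_equal(r$icur, -899.45 / 0.0046)
  expect_equal(r$icur, -195532.61, tolerance = 1e-7)
  expect_equal(r$quadrant, "SE")
  expect_equal(r$dominance, "dominant")

  expect_equal(icur(0, 0.01)$icur, 0)

  r2 <- icur(201.90, 0.0041)
  expect_equal(r2$icur, 49243.90, tolerance = 1e-6)
  expect_equal(r2$quadrant, "NE")
  expect_equal(r2$dominance, "none")

  expect_equal(icur(100, -0.01)$dominance, "dominated")
  expect_warning(z <- icur(500, 0), "zero")
  expect_identical(z$icur, Inf)
})

test_that("percentile ICUR intervals follow the documented quantile rule", {
  same <- data.frame(delta_qaly = rep(0.004, 200),
                     delta_cost = rep(-800, 200))
  ci <- icur_ci(same)
  expect_equal(ci$lower, -800 / 0.004)
  expect_equal(ci$upper, -800 / 0.004)
  expect_false(ci$mixed_quadrants)

  graded <- data.frame(delta_qaly = rep(1, 100), delta_cost = 1:100)
  ci2 <- icur_ci(graded)
  expect_equal(ci2$lower, unname(quantile(1:100, 0.025)))
  expect_equal(ci2$lower, 3.475)
  expect_equal(ci2$upper, 97.525)

  mixed <- make_draws(10, 0, 10, 0)
  expect_warning(ci3 <- icur_ci(mixed), "quadrant")
  expect_true(ci3$mixed_quadrants)
})

test_that("identity bootstrap reproduces the point estimate", {
  d <- make_analysis_data(n = 100, delta_cost = -300, delta_qaly = 0.004,
                          seed = 2)
  point <- fit_sur(d)
  draws <- bootstrap_ce(d, B = 1, seed = 1, identity = TRUE)
  expect_equal(draws$delta_cost, point$delta_cost)
  expect_equal(draws$delta_qaly, point$delta_qaly)
})

test_that("bootstrap draw sets are seed-deterministic and arm-stratified", {
  d <- make_analysis_data(n = 80, seed = 4)
  b1 <- bootstrap_ce(d, B = 25, seed = 42)
  b2 <- bootstrap_ce(d, B = 25, seed = 42)
  expect_identical(as.data.frame(b1), as.data.frame(b2))
  b3 <- bootstrap_ce(d, B = 25, seed = 43)
  expect_false(identical(b1$delta_cost, b3$delta_cost))

  sizes <- list()
  probe <- bootstrap_ce(d, B = 10, seed = 7, refit = function(dd) {
    sizes[[length(sizes) + 1]] <<- c(sum(dd$treatment == 1),
                                     sum(dd$treatment == 0))
    c(0, 0)
  })
  for (s in sizes) {
    expect_equal(s[1], sum(d$treatment == 1))
    expect_equal(s[2], sum(d$treatment == 0))
  }
})

test_that("bootstrap SE tracks the sampling distribution of the deltas", {
  set.seed(66)
  outer <- t(replicate(60, {
    d <- make_analysis_data(n = 120, delta_cost = -300, delta_qaly = 0.004,
                            seed = sample.int(1e6, 1))
    f <- fit_sur(d)
    c(f$delta_cost, f$delta_qaly)
  }))
  emp_se <- sd(outer[, 1])
  d <- make_analysis_data(n = 120, delta_cost = -300, delta_qaly = 0.004,
                          seed = 101)
  boots <- bootstrap_ce(d, B = 300, seed = 11)
  expect_equal(sd(boots$delta_cost), emp_se, tolerance = 0.35)
})

test_that("an inestimable bootstrap aborts with a diagnostic", {
  d <- make_analysis_data(n = 40, seed = 3)
  expect_error(
    bootstrap_ce(d, B = 50, seed = 1,
                 refit = function(dd) stop("boom")),
    "inestimable")
})
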