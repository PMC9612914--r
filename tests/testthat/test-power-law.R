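test_that("exact power data are recovered exactly", {
  b <- c(1, 2, 4, 8)
  pl <- fit_power(b, 2 * b^3)
  expect_equal(pl$k, 2, tolerance = 1e-12)
  expect_equal(pl$a, 3, tolerance = 1e-12)
  expect_equal(pl$r2, 1, tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    ks <- exp(rnorm(1)); as <- rnorm(1, 0, 2)
    x <- exp(runif(30, -1, 2))
    pl <- fit_power(x, ks * x^as)
    expect_lt(abs(pl$k - ks) / ks, 1e-10)
    expect_lt(abs(pl$a - as) / max(abs(as), 1), 1e-10)
  }
})

test_that("fit_power agrees with the normal-equations oracle", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    x <- exp(rnorm(n)); y <- exp(1 + 0.8 * log(x) + rnorm(n, 0, 0.4))
    pl <- fit_power(x, y)
    o <- ols_log_oracle(x, y)
    expect_lt(abs(pl$a - o$slope) / abs(o$slope), 1e-10)
    expect_lt(abs(pl$k - o$k) / o$k, 1e-10)
    expect_lt(abs(pl$r2 - o$r2), 1e-10)
    expect_lt(abs(pl$p - o$p) / o$p, 1e-8)
    expect_equal(pl$a_ci, o$slope_ci, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(pl$k_ci, o$k_ci, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_power(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_power(c(2, 2, 2), c(1, 2, 3)), "identical")
  expect_error(fit_power(c(1, 2, 3), c(1, -2, 3)), "positive")
})

test_that("r-squared is symmetric under axis swap", {
  set.seed(8)
  x <- exp(rnorm(50)); y <- exp(0.5 * log(x) + rnorm(50, 0, 0.3))
  expect_equal(fit_power(x, y)$r2, fit_power(y, x)$r2, tolerance = 1e-12)
})

test_that("analytic inversion reproduces the published inverse size law", {
  ident <- invert_power(power_law(1, 1))
  expect_equal(c(ident$k, ident$a), c(1, 1))

  r_law <- power_law(9.6e5, -2.43, "R", "S_MN")
  inv <- invert_power(r_law)
  expect_equal(inv$k, exp(log(9.6e5) / 2.43), tolerance = 1e-12)
  expect_equal(inv$k, 2.9e2, tolerance = 0.01)    # printed 2.9e2
  expect_equal(inv$a, -1 / 2.43, tolerance = 1e-12)
  expect_equal(round(inv$a, 1), -0.4)             # printed -0.4

  pl <- power_law(5, -1.7, "A", "B")
  twice <- invert_power(invert_power(pl))
  expect_equal(twice$k, pl$k, tolerance = 1e-12)
  expect_equal(twice$a, pl$a, tolerance = 1e-12)
  expect_error(invert_power(power_law(2, 0)), "zero exponent")
})

test_that("refit inversion gives the attenuated axis-swap slope", {
  set.seed(13)
  x <- exp(runif(200)); y <- exp(2 * log(x) + rnorm(200, 0, 0.5))
  pl <- fit_power(x, y)
  inv <- invert_power(pl, method = "refit", x = x, y = y)
  # textbook identity: swapped OLS slope = r2 / forward slope
  expect_equal(inv$a, pl$r2 / pl$a, tolerance = 1e-10)
  expect_error(invert_power(pl, method = "refit"), "data")
})

test_that("composition multiplies exponents and combines intercepts", {
  id <- compose_power(power_law(1, 1, "A", "S"), power_law(1, 1, "S", "B"))
  expect_equal(c(id$k, id$a), c(1, 1))

  ith_s <- power_law(9.4e-4, 2.5, "I_th", "S_MN")
  s_r <- power_law(2.9e2, -0.4, "S_MN", "R")
  ith_r <- compose_power(ith_s, s_r)
  expect_equal(ith_r$k, 9.4e-4 * (2.9e2)^2.5, tolerance = 1e-12)
  expect_equal(ith_r$a, -1, tolerance = 1e-12)
  # the printed normalized intercept family is 1.4-1.5e3; arithmetic ~1.35e3
  expect_gt(ith_r$k, 1.2e3); expect_lt(ith_r$k, 1.5e3)

  pl <- power_law(3.2, -1.4, "A", "B")
  round_trip <- compose_power(pl, invert_power(pl))
  expect_equal(round_trip$k, 1, tolerance = 1e-12)
  expect_equal(round_trip$a, 1, tolerance = 1e-12)

  expect_error(compose_power(ith_s, power_law(1, 1, "C", "B")), "chain")
})

test_that("composition is associative", {
  p1 <- power_law(2, 1.5, "A", "B"); p2 <- power_law(0.3, -2, "B", "C")
  p3 <- power_law(7, 0.5, "C", "D")
  left <- compose_power(compose_power(p1, p2), p3)
  right <- compose_power(p1, compose_power(p2, p3))
  expect_equal(left$k, right$k, tolerance = 1e-12)
  expect_equal(left$a, right$a, tolerance = 1e-12)
})

test_that("evaluation is elementwise and guards its domain", {
  pl <- power_law(2, 3)
  expect_equal(predict(pl, 2), 16)
  acv <- power_law(8.1e4, 0.69, "ACV", "D_soma", space = "absolute")
  expect_equal(predict(acv, 5e-5), 8.1e4 * (5e-5)^0.69, tolerance = 1e-12)
  expect_equal(predict(acv, 5e-5), 87, tolerance = 0.01)
  v <- c(3, 1, 2)
  expect_equal(predict(pl, v), 2 * v^3)
  expect_error(predict(pl, c(1, -1)), "positive")
})

test_that("exponent confidence intervals achieve nominal coverage", {
  set.seed(77)
  truth <- 1.3; sigma <- 0.25
  hits <- 0L
  for (r in 1:500) {
    x <- exp(rnorm(100, 0, 0.5))
    y <- 0.7 * x^truth * exp(rnorm(100, 0, sigma))
    ci <- fit_power(x, y)$a_ci
    hits <- hits + (truth >= ci[1] && truth <= ci[2])
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
})

test_that("JSON serialization round-trips losslessly", {
  pl <- fit_power(exp(rnorm(20)), exp(rnorm(20, 1, 0.7)),
                  prop_x = "R", prop_y = "I_th")
  back <- power_law_from_json(power_law_to_json(pl))
  expect_equal(unclass(back), unclass(pl))
})
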