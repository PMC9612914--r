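test_that("empirical fold ratio averages per-study max/min ratios", {
  expect_equal(empirical_fold_ratio(10, 24), 2.4)
  expect_equal(empirical_fold_ratio(c(10, 10), c(20, 30)), 2.5)
  expect_error(empirical_fold_ratio(5, 5), "min < max")
})

test_that("sub-range sampling biases the empirical fold downward", {
  spec_full <- synthetic_spec(trim_range = c(0, 0), seed = 6)
  spec_trim <- synthetic_spec(trim_range = c(0.25, 0.25), seed = 6)
  fold_of <- function(spec) {
    studies <- lapply(1:4, function(i)
      generate_study(spec, c("ACV", "S_MN"), i))
    empirical_fold_ratio(vapply(studies, function(d) min(d$x), 0),
                         vapply(studies, function(d) max(d$x), 0))
  }
  expect_equal(fold_of(spec_full), 2.4, tolerance = 1e-12)
  expect_lt(fold_of(spec_trim), 2.4)
})

test_that("theoretical folds reproduce the published q ratios", {
  expect_equal(round(theoretical_fold(2.4, 2.43), 1), 8.4)
  expect_equal(round(theoretical_fold(2.4, 2.52), 1), 9.1)
  expect_equal(theoretical_fold(2.4, -2.43), theoretical_fold(2.4, 2.43))
  expect_equal(theoretical_fold(2.4, 0), 1)
})

test_that("theoretical ranges satisfy both constraints exactly", {
  r <- theoretical_range(3, 1.5, 2.5)   # midpoint 2 -> (1, 3)
  expect_equal(c(r$min, r$max), c(1, 3))

  near <- theoretical_range(1.0001, 1.9, 2.1)
  expect_equal(near$max / near$min, 1.0001, tolerance = 1e-12)
  expect_equal((near$min + near$max) / 2, 2, tolerance = 1e-6)

  set.seed(14)
  for (i in 1:25) {
    q <- 1 + rexp(1); lo <- rexp(1) + 0.01; hi <- lo * (1 + rexp(1))
    r <- theoretical_range(q, lo, hi)
    expect_lt(abs(r$max / r$min - q) / q, 1e-12)
    expect_lt(abs((r$min + r$max) - (lo + hi)) / (lo + hi), 1e-12)
  }
  expect_error(theoretical_range(1, 1, 2), "degenerate")
})

test_that("intercept anchoring reproduces the published scaled constants", {
  rg <- cat_ranges()
  ith <- scale_intercept(2.52, rg$I_th, rg$S_neuron, "I_th", "S_neuron")
  expect_equal(ith$k, 3.9e-9 / (1.8e-7)^2.52, tolerance = 1e-12)
  expect_equal(ith$k, 3.8e8, tolerance = 0.1)    # printed 3.8e8

  unit <- scale_intercept(1, property_range(1, 2), property_range(1, 2))
  expect_equal(unit$k, 1)

  r_law <- scale_intercept(-2.43, rg$R, rg$S_neuron, "R", "S_neuron")
  expect_equal(r_law$k, 4.0e6 * (1.8e-7)^2.43, tolerance = 1e-12)
  expect_equal(r_law$k, 1.7e-10, tolerance = 0.1)  # printed 1.7e-10
  # the anchored extreme is met exactly
  expect_equal(predict(r_law, 1.8e-7), 4.0e6, tolerance = 1e-12)

  expect_error(scale_intercept(0, rg$R, rg$S_neuron), "zero")
})

test_that("a scaled law spans exactly the target range when folds agree", {
  s <- property_range(2, 6)             # 3-fold size range
  a <- theoretical_range(3^1.7, 5, 40)  # matched fold for exponent 1.7
  law <- scale_intercept(1.7, a, s)
  expect_equal(predict(law, s$min), a$min, tolerance = 1e-12)
  expect_equal(predict(law, s$max), a$max, tolerance = 1e-12)
})

test_that("full scaling of a derived set anchors every size law", {
  spec <- synthetic_spec(sigma_log = 0, seed = 2, studies_per_pair = 2,
                         points_per_study = 15)
  rs <- derive_relationships(corpus_to_globals(generate_corpus(spec)))
  extremes <- list(ACV = c(40, 100), AHP = c(5e-2, 2e-1), R = c(5e5, 4e6),
                   I_th = c(4e-9, 3.5e-8), C = c(3e-9, 8e-9),
                   tau = c(3e-3, 1e-2))
  abs_rs <- scale_relationships(rs, property_range(1.8e-7, 4.4e-7),
                                extremes)
  expect_identical(abs_rs$space, "absolute")
  for (p in abs_rs$order) {
    law <- abs_rs$size_laws[[p]]
    rng <- abs_rs$ranges[[p]]
    anchor <- predict(law, 1.8e-7)
    target <- if (law$a > 0) rng$min else rng$max
    expect_equal(anchor, target, tolerance = 1e-12)
  }
})

test_that("Rall quantities satisfy the cable identities", {
  expect_equal(rall_quantities(tau = 5e-3, tau1 = 1e-3)$L, pi / 2,
               tolerance = 1e-12)
  expect_equal(rall_quantities(tau = 4e-3, R = 1e6, tanh_ratio = 0.5)$C,
               8e-9, tolerance = 1e-12)
  q <- rall_quantities(tau = 6e-3, tau1 = 1.2e-3, R = 1.2e6,
                       S_neuron = 3e-7)
  expect_equal(q$C * 1.2e6, 6e-3 * q$L / tanh(q$L), tolerance = 1e-12)
  expect_equal(q$R_m * q$C_m, 6e-3, tolerance = 1e-12)
  expect_error(rall_quantities(tau = 1e-3, tau1 = 2e-3), "tau > tau1")
})

test_that("the specific-resistivity law follows from the resistance law", {
  r_law <- power_law(1.7e-10, -2.43, "R", "S_neuron", space = "absolute")
  rm_law <- derive_rm_law(r_law, tanh_ratio = 0.6)
  expect_equal(rm_law$k, 0.6 * 1.7e-10, tolerance = 1e-12)
  expect_equal(rm_law$k, 1.0e-10, tolerance = 0.05)  # printed 1.0e-10
  expect_equal(rm_law$a, -1.43, tolerance = 1e-12)
})

test_that("the voltage threshold reads off only near-Ohmic laws", {
  ohmic <- power_law(2.7e-2, -1.0, "I_th", "R", space = "absolute")
  expect_equal(delta_vth(ohmic), 0.027)
  expect_error(
    delta_vth(power_law(1, -0.5, "I_th", "R", space = "absolute")),
    "not Ohmic")
})
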