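test_that("loading converts entry units to SI and keeps block structure", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    study_id = "s1", species = "cat", prop_x = "R", prop_y = "I_th",
    x = c(1, 2, 4), y = c(20, 10, 5), unit_x = "MOhm", unit_y = "nA"
  ), f, row.names = FALSE)
  ds <- load_study_data(f)
  expect_equal(ds$x, c(1e6, 2e6, 4e6))
  expect_equal(ds$y, c(20e-9, 10e-9, 5e-9))
  expect_false(ds$normalized)
})

test_that("non-positive rows are dropped with a warning, not clamped", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    study_id = "s1", species = "cat", prop_x = "R", prop_y = "I_th",
    x = c(1, 0, 4), y = c(20, 10, 5), unit_x = "MOhm", unit_y = "nA"
  ), f, row.names = FALSE)
  expect_warning(ds <- load_study_data(f), "dropped")
  expect_length(ds$x, 2)

  # all rows unusable -> empty-dataset error
  f2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(
    study_id = "s1", species = "cat", prop_x = "R", prop_y = "I_th",
    x = c(0, -1), y = c(1, 2), unit_x = "MOhm", unit_y = "nA"
  ), f2, row.names = FALSE)
  expect_error(suppressWarnings(load_study_data(f2)), "no usable rows")
})

test_that("a multi-block corpus file yields one dataset per (study, pair)", {
  # layout mimicking the published source-data supplement: several studies,
  # several pairs, in one table (synthetic stand-in values)
  blocks <- expand.grid(study = c("a", "b", "c"),
                        pair = c("ACV~S_MN", "AHP~ACV"),
                        stringsAsFactors = FALSE)
  rows <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
    p <- strsplit(blocks$pair[i], "~")[[1]]
    data.frame(study_id = blocks$study[i], species = "cat",
               prop_x = p[2], prop_y = p[1],
               x = c(10, 20, 30), y = c(3, 2, 1),
               unit_x = "1", unit_y = "1")
  }))
  f <- tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE)
  corpus <- load_corpus(f)
  # independent count: distinct (study, pair) keys in the raw text table
  raw <- read.csv(f)
  expect_length(corpus, nrow(unique(raw[c("study_id", "prop_y", "prop_x")])))
  expect_error(load_study_data(f), "single")
})

test_that("schema violations are rejected", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(study_id = "s", species = "cat",
                       prop_x = "bogus", prop_y = "I_th",
                       x = 1, y = 1, unit_x = "1", unit_y = "1"),
            f, row.names = FALSE)
  expect_error(load_corpus(f), "unknown properties")
  expect_error(to_si(1, "furlong"), "unknown unit")
})

test_that("normalization maps each column to percent of its own maximum", {
  ds <- study_dataset("s", "cat", "S_MN", "ACV", c(2, 4, 8), c(3, 6, 12))
  n <- normalize_study(ds)
  expect_equal(n$x, c(25, 50, 100))

  one <- normalize_study(study_dataset("s", "cat", "S_MN", "ACV", 3, 7))
  expect_equal(c(one$x, one$y), c(100, 100))

  two <- normalize_study(
    study_dataset("s", "cat", "S_MN", "ACV", c(3, 6), c(10, 5)))
  expect_equal(two$x, c(50, 100))   # columns scale independently
  expect_equal(two$y, c(100, 50))

  expect_error(normalize_study(n), "already normalized")
})

test_that("normalization is scale invariant and preserves order", {
  set.seed(11)
  for (rep in 1:10) {
    x <- exp(rnorm(20)); y <- exp(rnorm(20)); c1 <- exp(rnorm(1))
    a <- normalize_study(study_dataset("s", "cat", "S_MN", "R", x, y))
    b <- normalize_study(study_dataset("s", "cat", "S_MN", "R",
                                       c1 * x, c1 * y))
    expect_equal(a$x, b$x)
    expect_equal(a$y, b$y)
    expect_equal(order(a$x), order(x))
  }
})

test_that("merging conserves points, provenance and study maxima", {
  a <- make_norm_ds("a", "S_MN", "R", c(1, 2, 3), c(9, 5, 1))
  b <- make_norm_ds("b", "S_MN", "R", c(2, 4, 6, 8), c(7, 5, 3, 1))
  g <- merge_global(list(a, b))
  expect_length(g$x, 7)
  expect_setequal(unique(g$study), c("a", "b"))
  expect_equal(max(g$x[g$study == "a"]), 100)
  expect_equal(max(g$x[g$study == "b"]), 100)

  solo <- merge_global(list(a))
  expect_equal(solo$x, a$x)

  wrong_pair <- make_norm_ds("c", "S_MN", "ACV", 1:3, 1:3)
  expect_error(merge_global(list(a, wrong_pair)), "pair mismatch")
  raw <- study_dataset("d", "cat", "S_MN", "R", 1:3, 1:3)
  expect_error(merge_global(list(a, raw)), "normalized")
})

test_that("a synthetic 4-study pair merges to the expected global dataset", {
  spec <- synthetic_spec(studies_per_pair = 4, points_per_study = 30,
                         seed = 5)
  members <- lapply(1:4, function(i)
    normalize_study(generate_study(spec, c("AHP", "ACV"), i)))
  g <- merge_global(members)
  expect_length(g$x, 120)
  for (st in unique(g$study)) {
    expect_equal(max(g$x[g$study == st]), 100)
    expect_equal(max(g$y[g$study == st]), 100)
  }
})

test_that("distribution metrics match hand arithmetic", {
  m <- distribution_metrics(c(1, 2, 3))
  expect_equal(m$range, 2)
  expect_equal(m$mean, 2)
  expect_equal(m$cov, 0.5)     # sample sd = 1
  expect_equal(m$me_md, 1)

  flat <- distribution_metrics(c(5, 5, 5))
  expect_equal(flat$range, 0)
  expect_equal(flat$cov, 0)
  expect_equal(flat$me_md, 1)

  m2 <- distribution_metrics(c(10, 20, 30, 100))
  expect_equal(m2$range, 90)
  expect_equal(m2$mean, 40)
  expect_equal(m2$me_md, 0.625)  # midpoint median 25 over mean 40

  expect_error(distribution_metrics(7), "at least 2")
})

test_that("metrics respond to rescaling as dimensional analysis requires", {
  set.seed(4)
  v <- rexp(30) + 0.1
  for (c1 in c(0.2, 3, 40)) {
    m0 <- distribution_metrics(v)
    m1 <- distribution_metrics(c1 * v)
    expect_equal(m1$range, c1 * m0$range)
    expect_equal(m1$mean, c1 * m0$mean)
    expect_equal(m1$cov, m0$cov)
    expect_equal(m1$me_md, m0$me_md)
  }
})

test_that("homogeneity gate follows the sd_g < 10 and ratio < 0.15 rule", {
  s <- distribution_metrics(c(20, 50, 100))
  h <- homogeneity_check(list(s, s))
  expect_true(all(h$sd_g == 0))
  expect_true(all(h$homogeneous))

  # two studies with means 50 and 70 (percent): sd_g ~ 14.14, ratio 0.236
  a <- list(range = 60, mean = 50, cov = 0.3, me_md = 0.9)
  b <- list(range = 60, mean = 70, cov = 0.3, me_md = 0.9)
  h2 <- homogeneity_check(list(a, b))
  mean_row <- h2[h2$metric == "mean", ]
  expect_equal(mean_row$mean_g, 60)
  expect_equal(mean_row$sd_g, sqrt(200), tolerance = 1e-12)
  expect_equal(mean_row$ratio, sqrt(200) / 60, tolerance = 1e-12)
  expect_false(mean_row$homogeneous)

  h1 <- homogeneity_check(list(a))
  expect_true(all(is.na(h1$homogeneous)))
})

test_that("a low-noise synthetic corpus passes all four homogeneity flags", {
  spec <- synthetic_spec(sigma_log = 0.05, points_per_study = 50, seed = 2)
  members <- lapply(1:4, function(i)
    normalize_study(generate_study(spec, c("ACV", "S_MN"), i)))
  for (col in c("x", "y")) {
    sets <- lapply(members, function(d) distribution_metrics(d[[col]]))
    expect_true(all(homogeneity_check(sets)$homogeneous))
  }
})
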