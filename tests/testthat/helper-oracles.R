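# Independent oracles, written from first principles so they share no code
# path with the package implementation.

# OLS of ln(y) on ln(x) via explicit normal-equation sums, with t-based
# intervals and slope test.
ols_log_oracle <- function(x, y) {
  lx <- log(x); ly <- log(y)
  n <- length(lx)
  sx <- sum(lx); sy <- sum(ly)
  sxx <- sum(lx^2); sxy <- sum(lx * ly); syy <- sum(ly^2)
  b <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  a0 <- (sy - b * sx) / n
  res <- ly - a0 - b * lx
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / (sxx - sx^2 / n))
  se_a <- sqrt(s2 * (1 / n + (sx / n)^2 / (sxx - sx^2 / n)))
  tq <- qt(0.975, n - 2)
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(
    slope = b, intercept = a0, k = exp(a0),
    r2 = r^2,
    p = 2 * pt(abs(b / se_b), n - 2, lower.tail = FALSE),
    slope_ci = c(b - tq * se_b, b + tq * se_b),
    k_ci = exp(c(a0 - tq * se_a, a0 + tq * se_a))
  )
}

# Two-loop k-fold cross-validation reference: same seeded shuffling
# contract, but folds, fits and metrics all recomputed from scratch.
cv_oracle <- function(x, y, folds, seed) {
  n <- length(x)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  perm <- sample.int(n)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(folds), n)
  nME <- nRMSE <- r2p <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    o <- ols_log_oracle(x[tr], y[tr])
    pred <- o$k * x[te]^o$slope
    obs <- y[te]
    nME[f] <- 100 * max(abs(pred - obs) / obs)
    nRMSE[f] <- 100 * sqrt(mean((pred - obs)^2)) / mean(obs)
    r2p[f] <- cor(obs, pred)^2
  }
  list(nME = mean(nME), nRMSE = mean(nRMSE), r2pred = mean(r2p))
}

# small helper: exact synthetic study pair in normalized space
make_norm_ds <- function(study, prop_x, prop_y, x, y, species = "cat") {
  normalize_study(study_dataset(study, species, prop_x, prop_y, x, y))
}
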