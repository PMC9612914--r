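#' Power-law relationship between two properties
#'
#' Construct a `power_law` object representing `y = k * x^a`. Fitted laws
#' carry regression statistics (r-squared of the log-log fit, two-sided
#' p-value of the slope, 95% confidence bounds from the t distribution);
#' analytically derived laws (inverted or composed) carry `NA` statistics
#' and consumers must not gate on them.
#'
#' @param k Positive intercept (value of `y` at `x = 1`).
#' @param a Exponent (dimensionless).
#' @param prop_y,prop_x Property names.
#' @param space `"normalized"` (percent-of-maximum) or `"absolute"` (SI).
#' @param k_ci,a_ci Length-2 95% bounds, or `NULL`.
#' @param r2,p,n Fit statistics (optional).
#' @param provenance Free-text origin tag.
#' @return A `power_law` object.
#' @export
power_law <- function(k, a, prop_y = "y", prop_x = "x",
                      space = c("normalized", "absolute"),
                      k_ci = NULL, a_ci = NULL,
                      r2 = NA_real_, p = NA_real_, n = NA_integer_,
                      provenance = "constructed") {
  stopifnot_positive(k, "intercept k")
  if (!is.finite(a)) stop("exponent a must be finite", call. = FALSE)
  structure(list(
    prop_y = prop_y, prop_x = prop_x,
    k = as.numeric(k), a = as.numeric(a),
    k_ci = if (is.null(k_ci)) c(NA_real_, NA_real_) else as.numeric(k_ci),
    a_ci = if (is.null(a_ci)) c(NA_real_, NA_real_) else as.numeric(a_ci),
    r2 = r2, p = p, n = n,
    space = match.arg(space),
    provenance = provenance
  ), class = "power_law")
}

#' Fit a power law by ordinary least squares in log-log space
#'
#' Fits `ln y = a ln x + ln k` by OLS (natural logarithms), the regression
#' model under which multiplicative log-normal noise on `y` is
#' homoscedastic. The returned intercept is exponentiated, the r-squared is
#' the squared Pearson correlation of the logs, the p-value is the
#' two-sided t-test of slope != 0, and 95% confidence bounds come from the
#' t distribution on the slope and log-intercept (the latter exponentiated).
#'
#' @param x,y Strictly positive paired vectors (length >= 3), or `x` a
#'   `global_dataset` and `y` missing.
#' @param prop_x,prop_y Property names attached to the fit.
#' @param space Space label of the data.
#' @return A `power_law` with fit statistics.
#' @examples
#' b <- c(1, 2, 4, 8)
#' fit_power(b, 2 * b^3)
#' @export
fit_power <- function(x, y, prop_x = "x", prop_y = "y",
                      space = c("normalized", "absolute")) {
  if (inherits(x, "global_dataset")) {
    prop_x <- x$prop_x; prop_y <- x$prop_y
    space <- if (isTRUE(x$normalized)) "normalized" else "absolute"
    y <- x$y; x <- x$x
  } else {
    space <- match.arg(space)
  }
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 points to fit", call. = FALSE)
  stopifnot_positive(x, "x"); stopifnot_positive(y, "y")
  lx <- log(x); ly <- log(y)
  if (stats::var(lx) == 0) {
    stop("degenerate fit: x values are all identical", call. = FALSE)
  }
  fit <- stats::lm(ly ~ lx)
  # noiseless data are a legitimate input (analytic identities); silence
  # summary.lm's perfect-fit warning
  sm <- suppressWarnings(summary(fit))
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  co <- stats::coef(fit)
  power_law(
    k = exp(co[[1]]), a = co[[2]],
    prop_y = prop_y, prop_x = prop_x, space = space,
    k_ci = exp(ci[1, ]), a_ci = ci[2, ],
    r2 = sm$r.squared,
    p = sm$coefficients[2, 4],
    n = length(x),
    provenance = "fitted"
  )
}

#' Invert a power law
#'
#' Returns the law expressing `x` as a function of `y`. By default the
#' inversion is analytic: from `y = k x^a`, `x = k^(-1/a) y^(1/a)`; the
#' r-squared, p-value and point count are copied (squared correlation is
#' symmetric under axis swap) and the exponent/intercept intervals are the
#' mapped images of the forward intervals. `method = "refit"` instead
#' re-runs OLS with the axes swapped on supplied data, which gives the
#' shallower slope `r2/a` characteristic of regression-to-the-mean; it is
#' provided for diagnostic comparison.
#'
#' @param pl A `power_law` with `a != 0`.
#' @param method `"analytic"` (default) or `"refit"`.
#' @param x,y The original data, required for `method = "refit"`.
#' @return A `power_law` for the inverse relationship.
#' @examples
#' invert_power(power_law(9.6e5, -2.43, "R", "S_MN"))  # ~ 2.9e2 * R^-0.41
#' @export
invert_power <- function(pl, method = c("analytic", "refit"),
                         x = NULL, y = NULL) {
  stopifnot(inherits(pl, "power_law"))
  method <- match.arg(method)
  if (method == "refit") {
    if (is.null(x) || is.null(y)) {
      stop("method = \"refit\" needs the original x and y data", call. = FALSE)
    }
    out <- fit_power(y, x, prop_x = pl$prop_y, prop_y = pl$prop_x,
                     space = pl$space)
    out$provenance <- "inverted-refit"
    return(out)
  }
  if (pl$a == 0) stop("cannot invert a law with zero exponent", call. = FALSE)
  a_inv <- 1 / pl$a
  # map the forward CIs through the (monotone per branch) transforms
  a_ci <- sort(1 / pl$a_ci)
  k_ci <- sort(pl$k_ci^(-1 / pl$a))
  power_law(
    k = pl$k^(-1 / pl$a), a = a_inv,
    prop_y = pl$prop_x, prop_x = pl$prop_y, space = pl$space,
    k_ci = k_ci, a_ci = a_ci,
    r2 = pl$r2, p = pl$p, n = pl$n,
    provenance = "inverted-analytic"
  )
}

#' Compose two power laws
#'
#' Given `A = k_A S^{a_A}` (outer) and `S = k_S B^{a_S}` (inner), returns
#' `A = k_A k_S^{a_A} B^{a_A a_S}`. The chained variable of the outer law
#' must be the response of the inner law. Composition is exact, so the
#' result carries no r-squared or p-value; `n` is the smaller of the two
#' inputs' counts.
#'
#' @param outer,inner `power_law` objects with `outer$prop_x == inner$prop_y`.
#' @return A derived `power_law` from `inner$prop_x` to `outer$prop_y`.
#' @export
compose_power <- function(outer, inner) {
  stopifnot(inherits(outer, "power_law"), inherits(inner, "power_law"))
  if (!identical(outer$prop_x, inner$prop_y)) {
    stop("cannot chain: outer law is in terms of '", outer$prop_x,
         "' but inner law yields '", inner$prop_y, "'", call. = FALSE)
  }
  if (!identical(outer$space, inner$space)) {
    stop("cannot compose laws from different spaces", call. = FALSE)
  }
  n <- suppressWarnings(min(outer$n, inner$n, na.rm = TRUE))
  power_law(
    k = outer$k * inner$k^outer$a,
    a = outer$a * inner$a,
    prop_y = outer$prop_y, prop_x = inner$prop_x, space = outer$space,
    n = if (is.finite(n)) as.integer(n) else NA_integer_,
    provenance = "composed"
  )
}

#' Evaluate a power law
#'
#' @param object A `power_law`.
#' @param x Strictly positive value(s) of the regressor property.
#' @param ... Unused.
#' @return `k * x^a`, elementwise.
#' @export
predict.power_law <- function(object, x, ...) {
  stopifnot_positive(x, paste0(object$prop_x, " value"))
  object$k * x^object$a
}

#' @export
print.power_law <- function(x, ...) {
  cat(sprintf("%s = %.4g * %s^%.3g   [%s, %s]\n",
              x$prop_y, x$k, x$prop_x, x$a, x$space, x$provenance))
  if (is.finite(x$r2)) {
    cat(sprintf("  r2 = %.3f, p = %.3g, n = %d; a in [%.3g, %.3g]\n",
                x$r2, x$p, x$n, x$a_ci[1], x$a_ci[2]))
  }
  invisible(x)
}

#' Serialize / deserialize a power law as JSON
#'
#' The JSON object round-trips losslessly through
#' `power_law_from_json(power_law_to_json(pl))`.
#'
#' @param pl A `power_law`.
#' @return `power_law_to_json`: a JSON string. `power_law_from_json`: a
#'   `power_law`.
#' @export
power_law_to_json <- function(pl) {
  stopifnot(inherits(pl, "power_law"))
  jsonlite::toJSON(unclass(pl), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname power_law_to_json
#' @param json JSON string produced by `power_law_to_json`.
#' @export
power_law_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  power_law(
    k = obj$k, a = obj$a, prop_y = obj$prop_y, prop_x = obj$prop_x,
    space = obj$space, k_ci = obj$k_ci, a_ci = obj$a_ci,
    r2 = if (is.null(obj$r2)) NA_real_ else obj$r2,
    p = if (is.null(obj$p)) NA_real_ else obj$p,
    n = if (is.null(obj$n)) NA_integer_ else obj$n,
    provenance = obj$provenance
  )
}
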