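#' Single-pass outlier removal by standard-deviation distance
#'
#' Removes points whose value on the chosen axis lies outside
#' `mean +/- threshold_sd * sd`, with mean and sample sd computed once on
#' the raw scale (no iteration after removal). Used before fitting
#' muscle-unit couplings when a dataset contains isolated aberrant points;
#' removal is opt-in per dataset.
#'
#' @param x,y Paired values (>= 4 points).
#' @param on Axis screened for outliers: `"x"` or `"y"`.
#' @param threshold_sd Distance threshold in sd units (default 2).
#' @return List with filtered `x`, `y` and the integer indices `removed`.
#' @export
remove_outliers <- function(x, y, on = c("x", "y"), threshold_sd = 2) {
  on <- match.arg(on)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 4) stop("need at least 4 points", call. = FALSE)
  v <- if (on == "x") x else y
  m <- mean(v); s <- stats::sd(v)
  out <- which(abs(v - m) > threshold_sd * s)
  if (length(out) == length(v)) {
    stop("outlier rule removed every point", call. = FALSE)
  }
  keep <- setdiff(seq_along(v), out)
  list(x = x[keep], y = y[keep], removed = out)
}

#' Muscle-unit / motoneuron size-coupling exponent
#'
#' Fits the normalized power law `A_mU = k * B_MN^b` between a muscle-unit
#' size index and a motoneuron property, then converts the exponent into a
#' size coupling `S_mU ~ S_MN^c` with `c = b * c_B`, where `c_B` is the
#' size exponent of the motoneuron property (`B_MN = k_c S_MN^{c_B}`).
#' Because every admitted muscle-unit size index is linearly related to
#' `S_mU`, a linear rescaling of the index changes the intercept but not
#' `b`, so `c` is invariant to the choice of index. The sign of `c` is
#' `sign(b) * sign(c_B)` by construction.
#'
#' @param gds Normalized `global_dataset` with `prop_y` a muscle-unit size
#'   index (see [mu_size_indices()]) and `prop_x` a motoneuron property.
#' @param size_laws A `relationship_set` covering `prop_x`, or a named
#'   numeric vector of size exponents (e.g. `c(ACV = 0.7)`).
#' @return An `mu_link_result`: the fitted law, `b`, `c_B`, `c`, species.
#' @export
mu_coupling <- function(gds, size_laws) {
  stopifnot(inherits(gds, "global_dataset"))
  if (!gds$prop_y %in% mu_size_indices()) {
    stop("'", gds$prop_y, "' is not an admitted muscle-unit size index",
         call. = FALSE)
  }
  c_b <- size_exponent(size_laws, gds$prop_x)
  fit <- fit_power(gds)
  structure(list(
    law = fit, b = fit$a, c_B = c_b, c = fit$a * c_b,
    species = gds$species
  ), class = "mu_link_result")
}

size_exponent <- function(size_laws, prop) {
  if (inherits(size_laws, "relationship_set")) {
    if (identical(prop, size_laws$size_prop) || identical(prop, "S_MN")) {
      return(1)
    }
    if (!prop %in% names(size_laws$size_laws)) {
      stop("no size law for '", prop, "'", call. = FALSE)
    }
    size_laws$size_laws[[prop]]$a
  } else {
    if (identical(prop, "S_MN") || identical(prop, "S_neuron")) return(1)
    if (!prop %in% names(size_laws)) {
      stop("no size exponent supplied for '", prop, "'", call. = FALSE)
    }
    unname(size_laws[[prop]])
  }
}

#' @export
print.mu_link_result <- function(x, ...) {
  cat(sprintf("mU-MN coupling (%s): %s = k * %s^%.3g;  c_B = %.3g  =>  S_mU ~ S_MN^%.3g\n",
              x$species, x$law$prop_y, x$law$prop_x, x$b, x$c_B, x$c))
  invisible(x)
}

#' Summary of size-coupling exponents across studies
#'
#' Arithmetic mean, population (divide-by-n) standard deviation and fold
#' range (max/min) of a set of coupling exponents, plus the monotonicity
#' verdict: muscle-unit and motoneuron sizes are monotonically related only
#' if all exponents share one sign.
#'
#' @param c_values Coupling exponents (from [mu_coupling()] results or
#'   printed tables); at least 2.
#' @return List with `mean`, `sd` (population), `fold`, `monotonic`,
#'   `sign`.
#' @export
coupling_summary <- function(c_values) {
  if (inherits(c_values, "mu_link_result")) c_values <- list(c_values)
  if (is.list(c_values)) {
    c_values <- vapply(c_values, function(r)
      if (inherits(r, "mu_link_result")) r$c else as.numeric(r), 0)
  }
  if (length(c_values) < 2) stop("need at least 2 exponents", call. = FALSE)
  sgn <- unique(sign(c_values))
  list(
    mean = mean(c_values),
    sd = sqrt(mean((c_values - mean(c_values))^2)),
    fold = max(abs(c_values)) / min(abs(c_values)),
    monotonic = length(sgn) == 1 && sgn != 0,
    sign = if (length(sgn) == 1) sgn else NA_real_
  )
}

#' Bundled muscle-unit coupling table
#'
#' The eight published muscle-unit/motoneuron couplings: species, fitted
#' pair, fitted exponent `b`, and the final size-coupling exponent `c`
#' obtained through the motoneuron size exponents (ACV 0.7; R -2.43;
#' I_th 2.52; direct size 1).
#'
#' @return Data.frame with columns `species`, `prop_mu`, `prop_mn`, `b`,
#'   `c`.
#' @export
mu_coupling_table <- function() {
  data.frame(
    species = c("rat", "cat", "cat", "cat", "cat",
                "mouse", "mouse", "mouse"),
    prop_mu = c("IR", "F_tw", "F_tet", "F_tet", "F_tet",
                "F_tw", "F_tw", "F_tet"),
    prop_mn = c("ACV", "ACV", "ACV", "R", "S_MN",
                "R", "I_th", "I_th"),
    b = c(3.4, 9.4, 7.2, -1.3, 2.0, -2.1, 1.3, 1.0),
    c = c(2.4, 6.6, 5.0, 3.2, 2.0, 5.1, 3.3, 2.5),
    stringsAsFactors = FALSE
  )
}
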