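#' Bundled cat relationship framework in absolute SI units
#'
#' The final adult-cat framework as a `relationship_set` in absolute SI
#' units, referenced to the neuron surface area `S_neuron` (m^2). The
#' constants are the published 2-significant-figure values, so chained
#' look-ups are accurate to roughly 10%; a framework recomputed from source
#' corpora by [derive_relationships()] plus [scale_relationships()] carries
#' unrounded constants instead. The soma diameter is linked linearly to
#' surface area (`D_soma = 1.8e2 * S_neuron`); specific resistivity is the
#' Rall-derived extension with `tanh(L)/L = 0.6`.
#'
#' @return A `relationship_set` with size laws for `D_soma`, `ACV`, `AHP`,
#'   `R`, `R_m`, `I_th`, `C`, `tau` versus `S_neuron`.
#' @export
cat_framework <- function() {
  tab <- list(
    D_soma = c(1.8e2, 1),
    R      = c(1.7e-10, -2.43),
    R_m    = c(1.0e-10, -1.43),
    C      = c(1.3e-2, 1),
    tau    = c(1.0e-12, -1.48),
    I_th   = c(3.8e8, 2.52),
    AHP    = c(1.0e-11, -1.51),
    ACV    = c(3.0e6, 0.69)
  )
  size_laws <- lapply(names(tab), function(p) {
    power_law(tab[[p]][1], tab[[p]][2], prop_y = p, prop_x = "S_neuron",
              space = "absolute", provenance = "bundled")
  })
  names(size_laws) <- names(tab)
  structure(list(
    size_prop = "S_neuron", space = "absolute",
    order = names(tab),
    size_laws = size_laws, inverse_laws = list(), pairwise = list(),
    ranges = cat_ranges()
  ), class = "relationship_set")
}

#' Reconstruct a complete motoneuron profile from one property
#'
#' Given a single known property value, inverts that property's size law
#' to recover the neuron surface area and evaluates every other law of the
#' framework, yielding one internally consistent profile of morphometric
#' and electrophysiological properties. The voltage threshold is attached
#' as the product `I_th * R`, so its (small) deviation from a constant
#' under the near-Ohmic framework is visible. Seeding from any property of
#' a profile rebuilds the others to within the framework's rounding
#' tolerance (about 10% for the bundled 2-significant-figure constants).
#'
#' @param seed_property Property name among the framework's laws (or the
#'   size property itself).
#' @param value Positive value in SI units.
#' @param framework Absolute `relationship_set` (default [cat_framework()]).
#' @param range_factor Admissible multiple of the bundled size range for
#'   the implied size (default 5); values outside error.
#' @return An `mn_profile`: named list of SI values plus `delta_V_th`,
#'   with the seeding property recorded as attribute `provenance`.
#' @examples
#' build_profile("D_soma", 50e-6)  # ACV ~ 87 m/s
#' @export
build_profile <- function(seed_property, value,
                          framework = cat_framework(),
                          range_factor = 5) {
  stopifnot(inherits(framework, "relationship_set"))
  if (!identical(framework$space, "absolute")) {
    stop("profile reconstruction needs an absolute-SI framework",
         call. = FALSE)
  }
  stopifnot_positive(value, seed_property)
  size_prop <- framework$size_prop
  s <- if (identical(seed_property, size_prop)) {
    value
  } else if (seed_property %in% names(framework$size_laws)) {
    predict(invert_power(framework$size_laws[[seed_property]]), value)
  } else {
    stop("unknown seed property '", seed_property, "'", call. = FALSE)
  }
  rng <- framework$ranges[[size_prop]]
  if (!is.null(rng) && (s < rng$min / range_factor ||
                        s > rng$max * range_factor)) {
    stop(sprintf(
      "implied %s = %.3g m2 is outside %g times the bundled range [%.3g, %.3g]",
      size_prop, s, range_factor, rng$min, rng$max), call. = FALSE)
  }
  prof <- c(
    stats::setNames(list(s), size_prop),
    lapply(framework$size_laws, function(l) predict(l, s))
  )
  prof[[seed_property]] <- value  # seed returned unchanged
  if (all(c("I_th", "R") %in% names(prof))) {
    prof$delta_V_th <- prof$I_th * prof$R
  }
  structure(prof, class = "mn_profile", provenance = seed_property)
}

#' @export
print.mn_profile <- function(x, ...) {
  units <- stats::setNames(mn_properties()$si_unit,
                           mn_properties()$property)
  cat("motoneuron profile (seeded from ", attr(x, "provenance"), "):\n",
      sep = "")
  for (p in names(x)) {
    cat(sprintf("  %-10s %.4g %s\n", p, x[[p]],
                if (p %in% names(units)) units[[p]] else ""))
  }
  invisible(x)
}

#' Generate a pool of inter-consistent motoneuron profiles
#'
#' Draws `n` neuron sizes from a right-skewed distribution (truncated
#' log-normal by default, with its mode towards small cells: motoneuron
#' pools contain many small and few large cells) spanning the framework's
#' bundled size range, and reconstructs a full profile for each size.
#' Profiles are returned sorted by size, so every property column is
#' monotone: conduction velocity, capacitance and rheobase increase with
#' size while afterhyperpolarization duration, time constant and input
#' resistance decrease. Reruns under the same seed are identical.
#'
#' @param n Number of motoneurons (>= 1).
#' @param size_dist `"lognormal"` (right-skewed, default) or
#'   `"loguniform"`.
#' @param seed RNG seed (default 0).
#' @param framework Absolute `relationship_set`.
#' @param s_range Size `property_range`; defaults to the framework's
#'   bundled range.
#' @return An `mn_pool` data.frame, one row per motoneuron, SI columns,
#'   with attributes `seed` and `size_dist`.
#' @export
generate_pool <- function(n, size_dist = c("lognormal", "loguniform"),
                          seed = 0, framework = cat_framework(),
                          s_range = NULL) {
  size_dist <- match.arg(size_dist)
  if (n < 1) stop("need n >= 1", call. = FALSE)
  if (is.null(s_range)) s_range <- framework$ranges[[framework$size_prop]]
  if (is.null(s_range)) stop("no size range available", call. = FALSE)
  lmin <- log(s_range$min); lmax <- log(s_range$max)
  sizes <- with_seed(seed, {
    if (size_dist == "loguniform") {
      exp(stats::runif(n, lmin, lmax))
    } else {
      # truncated lognormal, mode in the lower third of the log range
      mu <- lmin + 0.3 * (lmax - lmin)
      sg <- 0.45 * (lmax - lmin)
      plo <- stats::pnorm((lmin - mu) / sg)
      phi <- stats::pnorm((lmax - mu) / sg)
      exp(mu + sg * stats::qnorm(plo + stats::runif(n) * (phi - plo)))
    }
  })
  sizes <- sort(sizes)
  profs <- lapply(sizes, function(s)
    build_profile(framework$size_prop, s, framework))
  pool <- do.call(rbind, lapply(profs, function(p)
    as.data.frame(unclass(p))))
  structure(pool, class = c("mn_pool", "data.frame"),
            seed = seed, size_dist = size_dist)
}

#' Score framework predictions on an external dataset
#'
#' Applies a framework law to the regressor column of an absolute-SI
#' dataset (e.g. rat or mouse measurements) without any refitting, and
#' scores the predictions with [prediction_metrics()]. A species-specific
#' multiplicative offset in the true relationship leaves the r-squared
#' unchanged but inflates the normalized errors, which is the signature of
#' an intercept (scaling-factor) difference rather than a different
#' exponent.
#'
#' @param gds Absolute-SI `global_dataset`.
#' @param framework Absolute `relationship_set` covering the dataset's
#'   pair.
#' @param ... Metric switches passed to [prediction_metrics()].
#' @return List with `nME`, `nRMSE`, `r2`, `n`, `law`.
#' @export
score_external <- function(gds, framework, ...) {
  stopifnot(inherits(gds, "global_dataset"))
  if (isTRUE(gds$normalized)) {
    stop("external scoring needs absolute-SI data", call. = FALSE)
  }
  law <- relationship(framework, gds$prop_y, gds$prop_x)
  m <- prediction_metrics(gds$y, predict(law, gds$x), ...)
  c(m, list(n = length(gds$x), law = law))
}
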