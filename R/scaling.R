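#' Empirical fold range of a property across studies
#'
#' The empirical fold range `q_E` is the average across studies of the
#' per-study max/min ratio. Because individual studies sample sub-ranges of
#' the pool, `q_E` underestimates the fold range of the full pool.
#'
#' @param mins,maxs Per-study minimum and maximum values (positive,
#'   `mins < maxs` elementwise).
#' @return The mean of `maxs / mins`.
#' @examples
#' empirical_fold_ratio(c(10, 10), c(20, 30))  # mean of 2 and 3 -> 2.5
#' @export
empirical_fold_ratio <- function(mins, maxs) {
  stopifnot(length(mins) == length(maxs))
  stopifnot_positive(mins, "minima")
  if (any(mins >= maxs)) {
    stop("each study must have min < max", call. = FALSE)
  }
  mean(maxs / mins)
}

#' Theoretical fold range propagated through a size exponent
#'
#' If a property follows `A = k S^c` and size spans a `q_S`-fold range,
#' the property can span at most a `q_S^|c|`-fold range.
#'
#' @param q_s Size fold range (>= 1).
#' @param c Size exponent.
#' @return `q_s^abs(c)`.
#' @examples
#' theoretical_fold(2.4, -2.43)  # ~8.4
#' @export
theoretical_fold <- function(q_s, c) {
  if (q_s < 1) stop("fold range must be >= 1", call. = FALSE)
  q_s^abs(c)
}

#' Theoretical property range consistent with a fold and empirical midpoint
#'
#' Builds the range `[A_min, A_max]` enforcing both constraints exactly:
#' `A_max / A_min = q_T` and `(A_min + A_max)/2 = (A_minE + A_maxE)/2`,
#' where `A_minE`, `A_maxE` are the averages across studies of the observed
#' extremes. Closed form: `A_min = (A_minE + A_maxE) / (1 + q_T)`.
#'
#' @param q_t Theoretical fold range (> 1).
#' @param a_min_e,a_max_e Empirical average minimum and maximum (SI).
#' @return A `property_range` list with `min`, `max`, `provenance`.
#' @export
theoretical_range <- function(q_t, a_min_e, a_max_e) {
  if (q_t <= 1) stop("degenerate range: fold must exceed 1", call. = FALSE)
  stopifnot_positive(c(a_min_e, a_max_e), "empirical extremes")
  if (a_min_e >= a_max_e) stop("need a_min_e < a_max_e", call. = FALSE)
  a_min <- (a_min_e + a_max_e) / (1 + q_t)
  property_range(a_min, q_t * a_min, provenance = "theoretical")
}

#' @rdname theoretical_range
#' @param min,max Range bounds (0 < min < max).
#' @param provenance `"empirical"` or `"theoretical"`.
#' @export
property_range <- function(min, max, provenance = "empirical") {
  stopifnot_positive(c(min, max), "range bounds")
  if (min >= max) stop("need min < max", call. = FALSE)
  structure(list(min = min, max = max, provenance = provenance),
            class = "property_range")
}

#' Anchor a normalized law to absolute units
#'
#' Scales the intercept of a size-dependent law `A = k_c S^c` so that it
#' maps the small-size end of the size range onto the appropriate extreme
#' of the property range: `k_c = A_min / S_min^c` for increasing properties
#' (`c > 0`) and `k_c = A_max / S_min^c` for decreasing ones (`c < 0`).
#' The same anchoring rule applies between two electrophysiological
#' properties, with the regressor's minimum as the anchor point.
#'
#' @param c Size exponent (nonzero).
#' @param a_range `property_range` of the response property (SI).
#' @param s_range `property_range` of the regressor (SI).
#' @param prop_y,prop_x Property names for the returned law.
#' @return An absolute-space `power_law`.
#' @examples
#' scale_intercept(2.52, property_range(3.9e-9, 35e-9),
#'                 property_range(1.8e-7, 4.4e-7),
#'                 "I_th", "S_neuron")  # k ~ 3.8e8
#' @export
scale_intercept <- function(c, a_range, s_range,
                            prop_y = "A", prop_x = "S_neuron") {
  stopifnot(inherits(a_range, "property_range"),
            inherits(s_range, "property_range"))
  if (c == 0) stop("undefined anchor: exponent is zero", call. = FALSE)
  anchor <- if (c > 0) a_range$min else a_range$max
  power_law(anchor / s_range$min^c, c, prop_y, prop_x,
            space = "absolute", provenance = "scaled")
}

#' Scale a normalized relationship set to absolute SI units
#'
#' Applies the three-step scaling procedure to every size law of a
#' normalized `relationship_set`: (1) propagate the size fold `q_S` through
#' each exponent to a theoretical fold `q_T`; (2) build the theoretical
#' property range centred on the empirical average extremes; (3) anchor the
#' intercept at the small-size end. Pairwise laws are recomposed from the
#' scaled size laws.
#'
#' @param rs Normalized `relationship_set`.
#' @param s_range `property_range` for the absolute size property (SI).
#' @param prop_extremes Named list: per property, `c(A_minE, A_maxE)` in
#'   SI (empirical averages of observed extremes).
#' @param q_s Size fold range; default `s_range$max / s_range$min`.
#' @param size_prop Absolute size property name (default `"S_neuron"`).
#' @return An absolute `relationship_set` (also carrying the per-property
#'   theoretical ranges).
#' @export
scale_relationships <- function(rs, s_range, prop_extremes,
                                q_s = s_range$max / s_range$min,
                                size_prop = "S_neuron") {
  stopifnot(inherits(rs, "relationship_set"),
            inherits(s_range, "property_range"))
  missing_props <- setdiff(names(rs$size_laws), names(prop_extremes))
  if (length(missing_props)) {
    stop("no empirical extremes supplied for: ",
         paste(missing_props, collapse = ", "), call. = FALSE)
  }
  size_laws <- list(); ranges <- list()
  for (A in names(rs$size_laws)) {
    c_a <- rs$size_laws[[A]]$a
    q_t <- theoretical_fold(q_s, c_a)
    ext <- prop_extremes[[A]]
    rng <- theoretical_range(q_t, ext[1], ext[2])
    ranges[[A]] <- rng
    size_laws[[A]] <- scale_intercept(c_a, rng, s_range,
                                      prop_y = A, prop_x = size_prop)
  }
  pairwise <- list()
  for (A in names(size_laws)) for (B in names(size_laws)) {
    if (A != B) {
      pairwise[[paste(A, B, sep = "~")]] <-
        compose_power(size_laws[[A]], invert_power(size_laws[[B]]))
    }
  }
  structure(list(
    size_prop = size_prop, space = "absolute",
    order = names(size_laws),
    size_laws = size_laws, inverse_laws = list(),
    pairwise = pairwise,
    ranges = ranges, s_range = s_range, q_s = q_s
  ), class = "relationship_set")
}

#' Bundled cat property ranges
#'
#' The typical adult-cat ranges used by the bundled framework: neuron
#' surface area 0.18--0.44 mm^2 (2.4-fold, the same fold as the soma
#' diameter), input resistance 0.5--4.0 MOhm, rheobase 3.9--35.0 nA. Other
#' properties' ranges must be supplied by the user.
#'
#' @return Named list of `property_range` objects (SI) plus `q_S`.
#' @export
cat_ranges <- function() {
  list(
    S_neuron = property_range(1.8e-7, 4.4e-7),
    R = property_range(0.5e6, 4.0e6),
    I_th = property_range(3.9e-9, 35.0e-9),
    q_S = 2.4
  )
}

#' Rall equivalent-cylinder quantities
#'
#' Passive cable quantities for a motoneuron modelled as Rall's equivalent
#' cylinder with uniform membrane resistivity and capacitance:
#' * electrotonic length `L = pi * (tau/tau1 - 1)^(-1/2)` from the membrane
#'   time constant `tau` and the first equalizing constant `tau1`;
#' * total capacitance `C = (tau / R) * L / tanh(L)`;
#' * specific resistivity `R_m = R * S_neuron * tanh(L) / L`;
#' * specific capacitance `C_m = C / S_neuron`.
#' The identities `C * R = tau * L / tanh(L)` and `R_m * C_m = tau` hold
#' for any self-consistent inputs.
#'
#' @param tau Membrane time constant (s).
#' @param tau1 First equalizing time constant (s); required unless `L` or
#'   `tanh_ratio` is given.
#' @param L Electrotonic length (dimensionless), alternative to `tau1`.
#' @param tanh_ratio `tanh(L)/L` directly (the literature standard value is
#'   0.6; 0.5 is also in common use), alternative to `L`.
#' @param R Input resistance (Ohm), for `C` and `R_m`.
#' @param S_neuron Neuron surface area (m^2), for `R_m` and `C_m`.
#' @return List with whichever of `L`, `tanh_ratio`, `C`, `R_m`, `C_m` are
#'   computable from the inputs.
#' @examples
#' rall_quantities(tau = 5e-3, tau1 = 1e-3)$L       # pi/2
#' rall_quantities(tau = 4e-3, R = 1e6, tanh_ratio = 0.5)$C  # 8e-9 F
#' @export
rall_quantities <- function(tau, tau1 = NULL, L = NULL, tanh_ratio = NULL,
                            R = NULL, S_neuron = NULL) {
  stopifnot_positive(tau, "tau")
  if (is.null(L) && !is.null(tau1)) {
    stopifnot_positive(tau1, "tau1")
    if (tau <= tau1) {
      stop("electrotonic length undefined: need tau > tau1", call. = FALSE)
    }
    L <- pi * (tau / tau1 - 1)^(-1 / 2)
  }
  if (is.null(tanh_ratio)) {
    if (is.null(L)) {
      stop("supply tau1, L or tanh_ratio", call. = FALSE)
    }
    stopifnot_positive(L, "L")
    tanh_ratio <- tanh(L) / L
  }
  if (tanh_ratio <= 0 || tanh_ratio >= 1) {
    stop("tanh(L)/L must lie in (0, 1)", call. = FALSE)
  }
  out <- list(L = L, tanh_ratio = tanh_ratio)
  if (!is.null(R)) {
    stopifnot_positive(R, "R")
    out$C <- (tau / R) / tanh_ratio
    if (!is.null(S_neuron)) {
      stopifnot_positive(S_neuron, "S_neuron")
      out$R_m <- R * S_neuron * tanh_ratio
      out$C_m <- out$C / S_neuron
    }
  }
  out
}

#' Specific-resistivity law from an input-resistance law
#'
#' From `R = R_m / S_neuron * L / tanh(L)`, an absolute input-resistance
#' law `R = k S^c` implies `R_m = tanh(L)/L * k * S^(c+1)`.
#'
#' @param law_r Absolute `power_law` of `R` versus `S_neuron`.
#' @param tanh_ratio `tanh(L)/L` (default 0.6).
#' @return A `power_law` of `R_m` versus the same size property.
#' @examples
#' derive_rm_law(power_law(1.7e-10, -2.43, "R", "S_neuron",
#'                         space = "absolute"))
#' @export
derive_rm_law <- function(law_r, tanh_ratio = 0.6) {
  stopifnot(inherits(law_r, "power_law"))
  if (tanh_ratio <= 0 || tanh_ratio >= 1) {
    stop("tanh(L)/L must lie in (0, 1)", call. = FALSE)
  }
  power_law(tanh_ratio * law_r$k, law_r$a + 1,
            prop_y = "R_m", prop_x = law_r$prop_x,
            space = law_r$space, provenance = "rall-derived")
}

#' Voltage threshold from a near-Ohmic rheobase--resistance law
#'
#' When the rheobase--resistance relationship is close to Ohm's law
#' (`I_th = k R^-1`), the product `I_th * R` is a constant depolarization
#' threshold voltage and the law's intercept can be read directly as that
#' voltage. The exponent must lie within `tol` of -1.
#'
#' @param law Absolute `power_law` of `I_th` versus `R`.
#' @param tol Admissible deviation of the exponent from -1 (default 0.1).
#' @return Threshold voltage in volts.
#' @examples
#' delta_vth(power_law(2.7e-2, -1.0, "I_th", "R", space = "absolute"))
#' @export
delta_vth <- function(law, tol = 0.1) {
  stopifnot(inherits(law, "power_law"))
  if (abs(law$a + 1) > tol) {
    stop(sprintf(
      "relationship is not Ohmic: exponent %.3g is farther than %.2g from -1",
      law$a, tol), call. = FALSE)
  }
  law$k
}
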