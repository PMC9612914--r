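#' Motoneuron and muscle-unit property registry
#'
#' Each property handled by the package carries semantic metadata: its role
#' (motoneuron or muscle-unit side of the motor unit), its SI base unit, and
#' its orientation with respect to motoneuron size (whether it increases or
#' decreases in larger cells). `S_MN` denotes motoneuron size in the
#' normalized (percent-of-maximum) space; in absolute space size is measured
#' by the surface area `S_neuron` (m^2) or the soma diameter `D_soma` (m).
#' Muscle-unit size `S_mU` is a conceptual quantity never stored as a
#' measured column: it is represented by its linearly related indices
#' (tetanic force, twitch force, innervation ratio, fibre cross-sectional
#' areas).
#'
#' @return A data.frame with one row per property: `property`, `role`
#'   (`"MN"` or `"mU"`), `si_unit`, `size_direction` (+1 increasing with
#'   size, -1 decreasing, 0 size index itself, NA not size-referenced).
#' @examples
#' mn_properties()
#' @export
mn_properties <- function() {
  data.frame(
    property = c("S_MN", "S_neuron", "D_soma",
                 "ACV", "AHP", "R", "R_m", "I_th", "C", "C_m", "tau",
                 "delta_V_th",
                 "F_tet", "F_tw", "IR", "CSA_mean", "CSA_tot"),
    role = c(rep("MN", 12), rep("mU", 5)),
    si_unit = c("m2", "m2", "m",
                "m/s", "s", "Ohm", "Ohm*m2", "A", "F", "F/m2", "s",
                "V",
                "N", "N", "1", "m2", "m2"),
    size_direction = c(0, 0, 0,
                       +1, -1, -1, -1, +1, +1, NA, -1,
                       NA,
                       +1, +1, +1, +1, +1),
    stringsAsFactors = FALSE
  )
}

#' Measurable muscle-unit size indices
#'
#' The muscle-unit size indices admitted as linearly related to `S_mU`:
#' tetanic force, twitch force, innervation ratio and the mean and total
#' fibre cross-sectional areas. Coupling exponents derived through any of
#' these indices are invariant under linear rescaling of the index.
#'
#' @return Character vector of property names.
#' @export
mu_size_indices <- function() c("F_tet", "F_tw", "IR", "CSA_mean", "CSA_tot")

is_known_property <- function(p) p %in% mn_properties()$property

#' Unit registry and SI conversion
#'
#' Converts a value in a supported entry unit to SI base units. Supported
#' entry units: micrometres (`um`) and metres for lengths, square
#' millimetres (`mm2`) and square metres for areas, megaohms (`MOhm`) and
#' ohms, nanoamperes (`nA`) and amperes, milliseconds (`ms`) and seconds,
#' nanofarads (`nF`) and farads, millivolts (`mV`) and volts, `m/s`,
#' newtons, and the dimensionless unit `1`.
#'
#' @param x Numeric vector.
#' @param unit Entry unit name (case sensitive).
#' @return `x` converted to the SI base unit.
#' @examples
#' to_si(1, "MOhm")  # 1e6 Ohm
#' @export
to_si <- function(x, unit) {
  f <- si_factor(unit)
  x * f
}

si_factor <- function(unit) {
  factors <- c(
    "m" = 1, "um" = 1e-6, "mm" = 1e-3,
    "m2" = 1, "mm2" = 1e-6, "um2" = 1e-12,
    "Ohm" = 1, "MOhm" = 1e6, "kOhm" = 1e3,
    "Ohm*m2" = 1,
    "A" = 1, "nA" = 1e-9, "uA" = 1e-6,
    "s" = 1, "ms" = 1e-3,
    "F" = 1, "nF" = 1e-9, "uF" = 1e-6,
    "F/m2" = 1,
    "V" = 1, "mV" = 1e-3,
    "m/s" = 1,
    "N" = 1, "mN" = 1e-3,
    "1" = 1, "percent" = 1, "arbitrary" = 1
  )
  if (is.na(unit) || !nzchar(unit)) unit <- "1"
  if (!unit %in% names(factors)) {
    stop("unknown unit '", unit, "'; supported: ",
         paste(setdiff(names(factors), ""), collapse = ", "), call. = FALSE)
  }
  unname(factors[unit])
}
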