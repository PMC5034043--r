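#' Thermodynamic state
#'
#' Bundles the absolute temperature with the molar gas constant in
#' kcal/(mol K) and the derived thermal energy `RT`. Every exponential
#' formula in the package (Boltzmann weights, the Zwanzig estimator, the
#' standard-state correction, and the `K_D` <-> free-energy conversions)
#' draws its `RT` from one of these objects, so temperature enters the
#' pipeline in exactly one place.
#'
#' @param temperature Absolute temperature in kelvin. The default, 300 K,
#'   is the thermostat setpoint of the simulations the toy sampler stands
#'   in for.
#' @return An object of class `thermo_state` with fields `temperature`,
#'   `R` (1.9872e-3 kcal/(mol K)) and `rt` (kcal/mol).
#' @examples
#' th <- thermo_state(300)
#' th$rt  # ~0.596 kcal/mol
#' @export
thermo_state <- function(temperature = 300) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0) {
    stop("`temperature` must be a single positive, finite number (kelvin)")
  }
  R <- 1.9872e-3 # kcal / (mol K)
  structure(
    list(temperature = temperature, R = R, rt = R * temperature),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo_state: T = %g K, RT = %.5f kcal/mol\n",
              x$temperature, x$rt))
  invisible(x)
}

as_thermo <- function(thermo) {
  if (inherits(thermo, "thermo_state")) return(thermo)
  if (is.numeric(thermo) && length(thermo) == 1L) return(thermo_state(thermo))
  stop("`thermo` must be a thermo_state object or a temperature in kelvin")
}

#' Volume per molecule in the 1 M standard state
#'
#' The available volume per molecule of an ideal 1 mol/L solution,
#' `1e27 / N_A` cubic angstroms (~1660.5 A^3; commonly quoted rounded to
#' 1,660 A^3). This is the reference volume `V0` of the standard-state
#' (site-volume) correction to a binding free energy.
#'
#' @return Volume in cubic angstroms (single number).
#' @examples
#' standard_volume_A3()  # 1660.539
#' @export
standard_volume_A3 <- function() {
  avogadro <- 6.02214076e23 # 1/mol
  1e27 / avogadro           # A^3 per molecule at 1 mol/L
}
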