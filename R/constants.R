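# Physical constants pinned to CODATA; single source of truth for unit work.

#' Physical constants used throughout the package
#'
#' Returns the pinned set of physical constants (CODATA 2018, exact SI where
#' defined) used by every computation in the package. Pinning them in one
#' place makes all derived quantities bit-reproducible.
#'
#' @return A named list with components:
#'   \describe{
#'     \item{gas_constant_R}{ideal gas constant, kcal mol^-1 K^-1}
#'     \item{boltzmann_kB}{Boltzmann constant, J K^-1 (exact SI)}
#'     \item{planck_h}{Planck constant, J s (exact SI)}
#'     \item{eV_to_kcal_per_mol}{1 eV in kcal mol^-1}
#'     \item{nm_eV_product}{wavelength-energy product hc, nm eV}
#'     \item{hartree_eV}{1 hartree in eV}
#'     \item{fine_structure_alpha}{fine-structure constant}
#'     \item{bohr_radius_a0}{Bohr radius, cm}
#'     \item{speed_of_light_c}{speed of light in vacuum, cm s^-1}
#'     \item{GM_unit}{1 Goeppert-Mayer in cm^4 s photon^-1}
#'   }
#' @examples
#' ps_constants()$nm_eV_product
#' @export
ps_constants <- function() {
  list(
    gas_constant_R       = 1.987204259e-3,   # kcal mol^-1 K^-1
    boltzmann_kB         = 1.380649e-23,     # J K^-1
    planck_h             = 6.62607015e-34,   # J s
    eV_to_kcal_per_mol   = 23.060548,
    nm_eV_product        = 1239.841984,      # hc in nm eV
    hartree_eV           = 27.211386245988,
    fine_structure_alpha = 7.2973525693e-3,
    bohr_radius_a0       = 5.29177210903e-9, # cm
    speed_of_light_c     = 2.99792458e10,    # cm s^-1
    GM_unit              = 1e-50             # cm^4 s photon^-1
  )
}

.const <- ps_constants()

#' Eyring prefactor kB*T/h
#'
#' @param temperature temperature in kelvin.
#' @return Frequency prefactor in s^-1 (6.2124e12 s^-1 at 298.15 K).
#' @examples
#' eyring_prefactor(298.15)
#' @export
eyring_prefactor <- function(temperature) {
  stopifnot(is.numeric(temperature))
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  .const$boltzmann_kB * temperature / .const$planck_h
}

#' Thermodynamic and environmental conditions
#'
#' Bundles the temperature and pH at which speciation, kinetics and binding
#' are evaluated. Defaults correspond to aqueous physiological conditions.
#'
#' @param temperature temperature in kelvin; must be positive.
#' @param pH solution pH; must be finite.
#' @return An object of class \code{ps_conditions}.
#' @examples
#' ps_conditions()                 # 298.15 K, pH 7.4
#' ps_conditions(310, pH = 7.0)
#' @export
ps_conditions <- function(temperature = 298.15, pH = 7.4) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(pH), length(pH) == 1L)
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive finite number (kelvin)", call. = FALSE)
  if (!is.finite(pH))
    stop("pH must be finite", call. = FALSE)
  structure(list(temperature = temperature, pH = pH), class = "ps_conditions")
}

#' @export
print.ps_conditions <- function(x, ...) {
  cat(sprintf("Conditions: T = %.2f K, pH = %.2f\n", x$temperature, x$pH))
  invisible(x)
}

# RT in kcal/mol for a conditions object (internal)
.RT <- function(conditions) {
  .const$gas_constant_R * conditions$temperature
}

.as_conditions <- function(conditions) {
  if (inherits(conditions, "ps_conditions")) return(conditions)
  if (is.numeric(conditions) && length(conditions) == 1L)
    return(ps_conditions(temperature = conditions))
  stop("'conditions' must be a ps_conditions object or a temperature in K",
       call. = FALSE)
}
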