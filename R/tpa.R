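# Two-photon absorption cross sections.
#
# The raw cross section at resonance (2w = w0) is
#   sigma = N pi^3 alpha a0^5 (w^2 / c) <delta> g_peak
# with w the photon energy and <delta> the rotationally averaged two-photon
# transition strength, both in atomic units, and g the unit-area lineshape
# evaluated at its peak (so g carries inverse energy, atomic units). a0^5/c
# supplies cm^4 s; dividing by 1e-50 yields GM.

#' Effective two-photon photon wavelength
#'
#' Each of the two degenerate photons carries half the excitation energy, so
#' the photon wavelength is double the one-photon wavelength of the
#' transition.
#'
#' @param excitation_energy transition energy in eV; must be positive.
#' @return Photon wavelength in nm, vectorized.
#' @examples
#' photon_wavelength(2)       # 1239.842 nm
#' photon_wavelength(3.0900)  # ~802.5 nm
#' @export
photon_wavelength <- function(excitation_energy) {
  stopifnot(is.numeric(excitation_energy))
  if (any(!is.finite(excitation_energy) | excitation_energy <= 0))
    stop("excitation energy must be positive", call. = FALSE)
  2 * .const$nm_eV_product / excitation_energy
}

# peak value of the unit-area lineshape, in inverse atomic units of energy
.lineshape_peak <- function(gamma_eV, lineshape) {
  gamma_au <- gamma_eV / .const$hartree_eV
  switch(lineshape,
         lorentzian = 1 / (pi * gamma_au),
         gaussian   = (2 / gamma_au) * sqrt(log(2) / pi),
         stop(sprintf("unknown lineshape '%s'", lineshape), call. = FALSE))
}

#' Raw two-photon absorption cross section at resonance
#'
#' @param delta rotationally averaged two-photon transition strength, atomic
#'   units; must be non-negative.
#' @param photon_energy_omega photon energy in atomic units (hartree); at
#'   resonance this is half the transition energy.
#' @param gamma broadening parameter (FWHM) in eV; must be positive.
#' @param lineshape \code{"lorentzian"} or \code{"gaussian"} unit-area band
#'   shape, evaluated at its peak.
#' @param N_photons_factor photon-statistics integer: 8 for two distinct
#'   laser sources, 4 for the degenerate single-beam setup.
#' @return Cross section in GM (1 GM = 1e-50 cm^4 s photon^-1). Linear in
#'   \code{delta} and \code{N_photons_factor}, quadratic in the photon
#'   energy.
#' @seealso \code{\link{correct_cross_section}} for the single-beam +
#'   Gaussian-refit correction applied to engine output.
#' @export
raw_cross_section <- function(delta, photon_energy_omega, gamma = 0.1,
                              lineshape = c("lorentzian", "gaussian"),
                              N_photons_factor = 8L) {
  lineshape <- match.arg(lineshape)
  stopifnot(is.numeric(delta), is.numeric(photon_energy_omega),
            is.numeric(gamma), length(gamma) == 1L)
  if (any(delta < 0)) stop("delta must be >= 0", call. = FALSE)
  if (!is.finite(gamma) || gamma <= 0)
    stop("gamma must be positive", call. = FALSE)
  g <- .lineshape_peak(gamma, lineshape)
  sigma_cm4s <- N_photons_factor * pi^3 * .const$fine_structure_alpha *
    .const$bohr_radius_a0^5 * photon_energy_omega^2 /
    .const$speed_of_light_c * delta * g
  sigma_cm4s / .const$GM_unit
}

#' Single-beam degeneracy and Gaussian-lineshape correction
#'
#' Engine conventions assume two distinct laser sources (N = 8) and a
#' Lorentzian band; the common single-beam experiment has two degenerate
#' photons (N = 4, halving the cross section) and is better described by a
#' Gaussian band (multiplying by sqrt(pi ln 2) ~ 1.4757). The combined factor
#' is sqrt(pi ln 2) / 2 ~ 0.7378296, applied exactly.
#'
#' @param sigma_raw raw cross section in GM; must be non-negative.
#' @return Corrected cross section in GM.
#' @examples
#' correct_cross_section(100)  # 73.78 GM
#' @export
correct_cross_section <- function(sigma_raw) {
  stopifnot(is.numeric(sigma_raw))
  if (any(sigma_raw < 0)) stop("sigma_raw must be >= 0", call. = FALSE)
  sigma_raw * sqrt(pi * log(2)) / 2
}

#' Two-photon summary table for one species
#'
#' Fills the derived two-photon columns for a species' transitions: the
#' photon wavelength from the excitation energy and, where a transition
#' strength is available, the raw and corrected cross sections. Cross
#' sections supplied by the dataset (e.g. engine output) are kept.
#'
#' @param species a \code{ps_species}.
#' @param gamma default broadening (eV) for rows that do not carry one.
#' @param lineshape lineshape used for \code{sigma_raw_GM}.
#' @return The species' \code{tpa} data frame with derived columns filled.
#' @export
tpa_table <- function(species, gamma = 0.1,
                      lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  stopifnot(inherits(species, "ps_species"))
  tp <- species$tpa
  if (nrow(tp) == 0L) return(tp)
  tp$photon_wavelength_nm <- photon_wavelength(tp$excitation_energy)
  g <- ifelse(is.na(tp$gamma_broadening), gamma, tp$gamma_broadening)
  for (i in seq_len(nrow(tp))) {
    if (!is.na(tp$delta_TPA_strength[i])) {
      omega_au <- tp$excitation_energy[i] / 2 / .const$hartree_eV
      if (is.na(tp$sigma_raw_GM[i]))
        tp$sigma_raw_GM[i] <- raw_cross_section(
          tp$delta_TPA_strength[i], omega_au, g[i], lineshape)
      if (is.na(tp$sigma_corrected_GM[i]))
        tp$sigma_corrected_GM[i] <- correct_cross_section(tp$sigma_raw_GM[i])
    }
  }
  tp
}
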