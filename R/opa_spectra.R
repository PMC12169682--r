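# One-photon absorption spectrum assembly from vertical excitations.

#' Gaussian-broadened one-photon absorption spectrum
#'
#' Places a unit-area Gaussian (on the energy axis) of the given FWHM at each
#' vertical excitation energy, weighted by its oscillator strength, and
#' evaluates the sum on a wavelength grid. The integral of the spectrum over
#' energy equals the sum of the oscillator strengths, independent of the
#' width, so peak positions rather than absolute intensities are the
#' meaningful output.
#'
#' @param states data frame with columns \code{vertical_energy} (eV) and
#'   \code{oscillator_strength}; rows with \code{multiplicity} other than
#'   "singlet" (if the column is present) are dropped. An empty input yields
#'   an identically zero spectrum.
#' @param fwhm full width at half maximum of the Gaussian band, eV; must be
#'   positive.
#' @param grid strictly increasing wavelength grid in nm.
#' @return An object of class \code{ps_spectrum}: list with
#'   \code{wavelength_nm}, \code{intensity} (arbitrary units, oscillator
#'   strength per eV) and \code{metadata}.
#' @examples
#' s <- data.frame(multiplicity = "singlet", vertical_energy = 2.7255,
#'                 oscillator_strength = 0.354)
#' sp <- broaden_spectrum(s)
#' sp$wavelength_nm[which.max(sp$intensity)]  # ~454.9 nm
#' @export
broaden_spectrum <- function(states, fwhm = 0.4,
                             grid = seq(300, 800, by = 1)) {
  stopifnot(is.numeric(fwhm), length(fwhm) == 1L)
  if (!is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be positive", call. = FALSE)
  stopifnot(is.numeric(grid), length(grid) >= 2L)
  if (is.unsorted(grid, strictly = TRUE))
    stop("wavelength grid must be strictly increasing", call. = FALSE)

  if (!is.null(states) && nrow(states) > 0 && "multiplicity" %in% names(states))
    states <- states[states$multiplicity == "singlet", , drop = FALSE]

  energy <- .const$nm_eV_product / grid
  intensity <- numeric(length(grid))
  if (!is.null(states) && nrow(states) > 0) {
    f <- states$oscillator_strength
    e0 <- states$vertical_energy
    keep <- !is.na(f) & !is.na(e0)
    f <- f[keep]; e0 <- e0[keep]
    if (any(f < 0)) stop("oscillator strengths must be >= 0", call. = FALSE)
    sd <- fwhm / (2 * sqrt(2 * log(2)))
    for (i in seq_along(f))
      intensity <- intensity + f[i] * stats::dnorm(energy, e0[i], sd)
  }
  structure(list(wavelength_nm = grid, intensity = intensity,
                 metadata = list(broadening = "gaussian", fwhm_eV = fwhm)),
            class = "ps_spectrum")
}

#' @export
print.ps_spectrum <- function(x, ...) {
  imax <- which.max(x$intensity)
  cat(sprintf(
    "Spectrum: %d points, %.0f-%.0f nm (%s FWHM %.2f eV), max at %.1f nm\n",
    length(x$wavelength_nm), min(x$wavelength_nm), max(x$wavelength_nm),
    x$metadata$broadening, x$metadata$fwhm_eV, x$wavelength_nm[imax]))
  invisible(x)
}

#' Molar-fraction-weighted mixture of species spectra
#'
#' @param spectra list of \code{ps_spectrum} objects on a common wavelength
#'   grid.
#' @param fractions numeric weights summing to 1 (tolerance 1e-6).
#' @return A \code{ps_spectrum} with the pointwise weighted sum.
#' @export
mixture_spectrum <- function(spectra, fractions) {
  stopifnot(is.list(spectra), length(spectra) >= 1L,
            length(spectra) == length(fractions))
  if (!all(vapply(spectra, inherits, logical(1), "ps_spectrum")))
    stop("'spectra' must be a list of ps_spectrum objects", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("fractions must sum to 1", call. = FALSE)
  g <- spectra[[1]]$wavelength_nm
  for (s in spectra[-1]) {
    if (length(s$wavelength_nm) != length(g) ||
        any(s$wavelength_nm != g))
      stop("all spectra must share the same wavelength grid", call. = FALSE)
  }
  intensity <- numeric(length(g))
  for (i in seq_along(spectra))
    intensity <- intensity + fractions[i] * spectra[[i]]$intensity
  structure(list(wavelength_nm = g, intensity = intensity,
                 metadata = list(broadening = "mixture",
                                 fwhm_eV = spectra[[1]]$metadata$fwhm_eV)),
            class = "ps_spectrum")
}
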