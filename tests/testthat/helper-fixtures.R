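# Shared fixtures and tiny independent oracles.

aloe_path <- function() {
  system.file("extdata", "aloe_emodin.yaml", package = "psphot")
}

aloe <- function() load_dataset(aloe_path())

species_by_label <- function(dataset, label) {
  labs <- vapply(dataset$species, `[[`, character(1), "label")
  dataset$species[[match(label, labs)]]
}

# brute-force speciation oracle: Boltzmann-style weights over the chain
# microstates, each weight the product of Ka/[H+] factors along the chain
fractions_oracle <- function(pka, pH) {
  H <- 10^(-pH)
  Ka <- 10^(-pka)
  w <- numeric(length(pka) + 1)
  w[1] <- 1
  for (k in seq_along(pka)) w[k + 1] <- w[k] * Ka[k] / H
  w / sum(w)
}

# trapezoid integral of a spectrum over the energy axis
energy_integral <- function(spectrum) {
  e <- 1239.841984 / spectrum$wavelength_nm
  o <- order(e)
  e <- e[o]; y <- spectrum$intensity[o]
  sum(diff(e) * (head(y, -1) + tail(y, -1)) / 2)
}

RT_298 <- 1.987204259e-3 * 298.15
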