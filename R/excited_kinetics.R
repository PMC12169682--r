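# Excited-state decay bookkeeping: total ISC rate, triplet quantum yield,
# speciation-weighted apparent yield, triplet lifetime, the Type II
# energy-gap gate, and Jablonski-diagram data assembly.

#' Total intersystem-crossing rate
#'
#' Arithmetic sum of the per-channel ISC rates k(Sn -> Tm), optionally
#' restricted to a subset of channels (the mechanistic-scenario device: e.g.
#' S1-origin channels only versus S1 + S2 channels).
#'
#' @param rates a rate set: list with component \code{isc}, a data frame with
#'   columns \code{singlet_index}, \code{triplet_index}, \code{rate} (s^-1).
#' @param channels optional two-column matrix or data frame of
#'   (singlet_index, triplet_index) pairs selecting channels; all channels
#'   when omitted. A requested channel absent from the rate set is an error.
#' @return Total ISC rate in s^-1 (0 for an empty channel set).
#' @examples
#' rs <- list(isc = data.frame(singlet_index = 1, triplet_index = 1:3,
#'                             rate = c(3.59e8, 1.32e10, 2.15e9)))
#' total_isc_rate(rs)  # 1.5709e10
#' @export
total_isc_rate <- function(rates, channels = NULL) {
  isc <- if (is.data.frame(rates)) rates else rates$isc
  if (is.null(isc) || nrow(isc) == 0L) {
    if (!is.null(channels) && NROW(channels) > 0L)
      stop("requested ISC channels absent from an empty rate set",
           call. = FALSE)
    return(0)
  }
  if (any(!is.na(isc$rate) & isc$rate < 0))
    stop("ISC rates must be >= 0", call. = FALSE)
  if (is.null(channels)) return(sum(isc$rate))
  channels <- as.data.frame(channels)
  names(channels)[1:2] <- c("singlet_index", "triplet_index")
  key <- paste(isc$singlet_index, isc$triplet_index)
  want <- paste(channels$singlet_index, channels$triplet_index)
  miss <- setdiff(want, key)
  if (length(miss))
    stop(sprintf("ISC channel(s) not in rate set: %s",
                 paste0("(S", sub(" ", ",T", miss), ")", collapse = ", ")),
         call. = FALSE)
  sum(isc$rate[match(want, key)])
}

#' Triplet quantum yield
#'
#' Branching ratio of intersystem crossing against the competing S1 decay
#' channels: Phi_T = k'_ISC / (k'_ISC + k_F + k_IC). Invariant under uniform
#' rescaling of all three rates.
#'
#' @param k_prime_ISC total ISC rate, s^-1.
#' @param k_F fluorescence rate, s^-1.
#' @param k_IC internal-conversion rate, s^-1.
#' @return Yield in [0, 1].
#' @examples
#' triplet_quantum_yield(1.57e10, 1.53e8, 1.47e10)  # ~0.51
#' @export
triplet_quantum_yield <- function(k_prime_ISC, k_F, k_IC) {
  rates <- c(k_prime_ISC, k_F, k_IC)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  if (sum(rates) == 0)
    stop("triplet quantum yield undefined when all rates are zero",
         call. = FALSE)
  k_prime_ISC / (k_prime_ISC + k_F + k_IC)
}

#' Speciation-weighted apparent quantum yield
#'
#' @param yields per-species triplet quantum yields.
#' @param fractions matching molar fractions; must sum to 1 (tolerance 1e-6).
#' @return The molar-fraction-weighted mean yield.
#' @examples
#' apparent_quantum_yield(c(0.51, 0.88), c(0.9846, 0.0154))  # ~0.52
#' @export
apparent_quantum_yield <- function(yields, fractions) {
  stopifnot(length(yields) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("molar fractions must sum to 1", call. = FALSE)
  sum(yields * fractions)
}

#' Triplet lifetime from the phosphorescence rate
#'
#' @param k_P phosphorescence rate in s^-1; must be positive.
#' @return Lifetime tau = 1 / k_P in seconds.
#' @examples
#' triplet_lifetime(1 / 26)  # 26 s
#' @export
triplet_lifetime <- function(k_P) {
  stopifnot(is.numeric(k_P))
  if (any(!is.finite(k_P) | k_P <= 0))
    stop("k_P must be positive (k_P = 0 gives an infinite lifetime)",
         call. = FALSE)
  1 / k_P
}

#' Type II feasibility gate on the T1 - S0 energy gap
#'
#' Energy transfer to ground-state molecular oxygen, producing singlet
#' oxygen, requires the photosensitizer's T1 - S0 gap to reach the
#' 3O2 -> 1O2 excitation energy (0.98 eV). The gate is inclusive at the
#' threshold; an exact-threshold gap is additionally flagged as boundary.
#'
#' @param energy_gap_T1_S0 adiabatic T1 - S0 gap in eV; must be >= 0.
#' @param threshold gating energy in eV, default 0.98.
#' @return List with \code{feasible} (logical), \code{margin} (eV,
#'   gap - threshold) and \code{boundary} (logical).
#' @examples
#' type_ii_check(1.80)  # feasible, margin 0.82 eV
#' @export
type_ii_check <- function(energy_gap_T1_S0, threshold = 0.98) {
  stopifnot(is.numeric(energy_gap_T1_S0), length(energy_gap_T1_S0) == 1L)
  if (!is.finite(energy_gap_T1_S0) || energy_gap_T1_S0 < 0)
    stop("T1 - S0 energy gap must be >= 0", call. = FALSE)
  list(feasible = energy_gap_T1_S0 >= threshold,
       margin = energy_gap_T1_S0 - threshold,
       boundary = energy_gap_T1_S0 == threshold)
}

#' Jablonski-diagram data for one species
#'
#' Assembles the state/channel table behind a Jablonski diagram: one row per
#' excited state (adiabatic energy referenced to S0 = 0) and one row per
#' decay channel (each ISC channel annotated with its spin-orbit coupling,
#' plus fluorescence, internal conversion and phosphorescence when present).
#'
#' @param dataset a \code{ps_dataset}.
#' @param species label of the species to export.
#' @return Data frame with columns \code{kind} ("state"/"channel"),
#'   \code{label}, \code{energy_eV}, \code{zeta_cm1}, \code{rate_s1}.
#' @examples
#' d <- load_dataset(system.file("extdata", "aloe_emodin.yaml",
#'                               package = "psphot"))
#' jab <- jablonski_export(d, "AE-")
#' subset(jab, label == "S2->T1")$zeta_cm1  # 29.54
#' @export
jablonski_export <- function(dataset, species) {
  stopifnot(inherits(dataset, "ps_dataset"))
  labs <- vapply(dataset$species, `[[`, character(1), "label")
  i <- match(.normalize_label(species), labs)
  if (is.na(i))
    stop(sprintf("no species labelled '%s' in dataset", species),
         call. = FALSE)
  sp <- dataset$species[[i]]
  st <- sp$states
  rows <- list()
  if (nrow(st)) {
    miss <- is.na(st$adiabatic_energy)
    if (any(miss)) {
      bad <- paste0(ifelse(st$multiplicity[miss] == "singlet", "S", "T"),
                    st$index[miss])
      stop(sprintf("missing adiabatic energy for state(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    rows[[1]] <- data.frame(
      kind = "state",
      label = paste0(ifelse(st$multiplicity == "singlet", "S", "T"), st$index),
      energy_eV = st$adiabatic_energy,
      zeta_cm1 = NA_real_, rate_s1 = NA_real_, stringsAsFactors = FALSE)
  }
  isc <- sp$rates$isc
  if (nrow(isc)) {
    zeta <- rep(NA_real_, nrow(isc))
    if (nrow(sp$soc)) {
      m <- match(paste(isc$singlet_index, isc$triplet_index),
                 paste(sp$soc$singlet_index, sp$soc$triplet_index))
      zeta <- sp$soc$zeta_magnitude[m]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "channel",
      label = sprintf("S%d->T%d", isc$singlet_index, isc$triplet_index),
      energy_eV = NA_real_, zeta_cm1 = zeta, rate_s1 = isc$rate,
      stringsAsFactors = FALSE)
  }
  scalar <- c(F = sp$rates$k_F, IC = sp$rates$k_IC, P = sp$rates$k_P)
  scalar <- scalar[!is.na(scalar)]
  if (length(scalar)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "channel",
      label = names(scalar),
      energy_eV = NA_real_, zeta_cm1 = NA_real_, rate_s1 = unname(scalar),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), label = character(0),
                      energy_eV = numeric(0), zeta_cm1 = numeric(0),
                      rate_s1 = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Kinetics summary for one species
#'
#' Convenience wrapper combining the kinetics operations: total ISC rate
#' (optionally for a channel subset), triplet quantum yield, triplet
#' lifetime, and the Type II gate on the adiabatic T1 - S0 gap.
#'
#' @param species a \code{ps_species}.
#' @param channels optional channel subset passed to
#'   \code{\link{total_isc_rate}}.
#' @return List with \code{k_prime_ISC}, \code{phi_T}, \code{tau_T1},
#'   \code{energy_gap_T1_S0}, \code{type_ii_feasible}, \code{type_ii_margin}.
#' @export
kinetics_summary <- function(species, channels = NULL) {
  stopifnot(inherits(species, "ps_species"))
  k_isc <- total_isc_rate(species$rates, channels)
  phi <- if (!is.na(species$rates$k_F) && !is.na(species$rates$k_IC))
    triplet_quantum_yield(k_isc, species$rates$k_F, species$rates$k_IC)
  else NA_real_
  tau <- if (!is.na(species$rates$k_P) && species$rates$k_P > 0)
    triplet_lifetime(species$rates$k_P) else NA_real_
  st <- species$states
  t1 <- st$adiabatic_energy[st$multiplicity == "triplet" & st$index == 1L]
  gap <- if (length(t1) == 1L && !is.na(t1)) t1 else NA_real_
  gate <- if (!is.na(gap)) type_ii_check(gap)
          else list(feasible = NA, margin = NA_real_, boundary = NA)
  list(k_prime_ISC = k_isc, phi_T = phi, tau_T1 = tau,
       energy_gap_T1_S0 = gap, type_ii_feasible = gate$feasible,
       type_ii_margin = gate$margin)
}
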