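# Seeded synthetic dataset generator. Emits datasets with the statistical
# shape the pipeline assumes -- ordered state manifolds, log-uniform rate
# constants and couplings, energetically consistent (lambda > 0) redox pairs
# with known ground truth, and increasing multi-site pKa chains -- so every
# stage is testable without an electronic-structure run.

.runif_log <- function(n, lo, hi) 10^stats::runif(n, log10(lo), log10(hi))

.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic photosensitizer dataset
#'
#' Deterministic for a fixed seed. Sampling order is fixed (pKa chain first,
#' then per species in list order: states, SOC, rates, TPA, map points,
#' reactions, binding sites) so datasets are stable across runs. Electron
#' transfer reactions are built as dE = lambda + dG from sampled lambda and
#' dG, so the generating reorganization energy is recovered exactly by the
#' Marcus stage.
#'
#' @param n_species number of protonation species (>= 1); the chain carries
#'   \code{n_species - 1} pKa values and all chain states are listed.
#' @param n_singlets,n_triplets states per manifold (>= 1).
#' @param seed integer seed.
#' @param n_reactions electron-transfer reactions per species.
#' @param conditions a \code{\link{ps_conditions}}.
#' @return A valid \code{\link{ps_dataset}} (derived fields unset).
#' @examples
#' d <- generate_dataset(2, 3, 3, seed = 1)
#' nrow(validate_dataset(d)) == 0
#' @export
generate_dataset <- function(n_species = 2L, n_singlets = 4L,
                             n_triplets = 4L, seed = 1L,
                             n_reactions = 5L,
                             conditions = ps_conditions()) {
  if (n_species < 1L || n_singlets < 1L || n_triplets < 1L)
    stop("species and state counts must be >= 1", call. = FALSE)
  .with_seed(seed, {
    chain <- if (n_species > 1L) sort(stats::runif(n_species - 1L, 3, 13))
             else numeric(0)
    species <- lapply(seq_len(n_species), function(i) {
      s_e <- sort(stats::runif(n_singlets, 1.5, 4.5))
      t1 <- stats::runif(1, 1.5, s_e[1])
      t_e <- sort(c(t1, if (n_triplets > 1L)
        stats::runif(n_triplets - 1L, t1, 4.5)))
      shift_s <- stats::runif(n_singlets, 0.05, 0.3)
      shift_t <- stats::runif(n_triplets, 0.05, 0.3)
      states <- data.frame(
        multiplicity = c(rep("singlet", n_singlets), rep("triplet", n_triplets)),
        index = c(seq_len(n_singlets), seq_len(n_triplets)),
        vertical_energy = c(s_e, t_e),
        adiabatic_energy = pmax(c(s_e - shift_s, t_e - shift_t), 0.1),
        oscillator_strength = c(.runif_log(n_singlets, 1e-5, 1),
                                rep(NA_real_, n_triplets)),
        stringsAsFactors = FALSE)
      pairs <- expand.grid(singlet_index = seq_len(n_singlets),
                           triplet_index = seq_len(n_triplets))
      mag <- .runif_log(nrow(pairs), 0.1, 50)
      dir <- matrix(stats::rnorm(3L * nrow(pairs)), ncol = 3L)
      dir <- dir / sqrt(rowSums(dir^2))
      soc <- data.frame(pairs, zeta_x = mag * dir[, 1],
                        zeta_y = mag * dir[, 2], zeta_z = mag * dir[, 3],
                        zeta_magnitude = mag, stringsAsFactors = FALSE)
      rates <- list(
        isc = data.frame(pairs, rate = .runif_log(nrow(pairs), 1e6, 1e12),
                         stringsAsFactors = FALSE),
        k_F = .runif_log(1, 1e6, 1e12),
        k_IC = .runif_log(1, 1e6, 1e12),
        k_P = .runif_log(1, 1e-2, 1e2))
      tpa <- data.frame(
        state_index = seq_len(n_singlets), excitation_energy = s_e,
        photon_wavelength_nm = NA_real_,
        delta_TPA_strength = .runif_log(n_singlets, 10, 1e4),
        gamma_broadening = 0.1, sigma_raw_GM = NA_real_,
        sigma_corrected_GM = NA_real_, stringsAsFactors = FALSE)
      lab <- sprintf("sp%d", i)
      vea0 <- stats::runif(1, -3, 0.5)
      vip0 <- stats::runif(1, 5, 9)
      fedam <- data.frame(
        label = lab, state_tag = c("S0", "T1"),
        VEA = c(vea0, vea0 + t_e[1]), VIP = c(vip0, vip0 - t_e[1]),
        stringsAsFactors = FALSE)
      lam <- stats::runif(n_reactions, 5, 25)
      dG <- stats::runif(n_reactions, -30, 40)
      reactions <- data.frame(
        label = sprintf("r%d", seq_len(n_reactions)),
        delta_E_vertical = lam + dG, delta_G_adiabatic = dG,
        lambda_reorg = NA_real_, delta_G_activation = NA_real_,
        rate_k = NA_real_, stringsAsFactors = FALSE)
      binding <- data.frame(
        label = sprintf("site%d", 1:3),
        delta_G_binding = stats::runif(3, -12, -3), K_b = NA_real_,
        stringsAsFactors = FALSE)
      ps_species(label = lab, net_charge = -(i - 1L),
                 pka = if (i <= length(chain)) chain[i] else NA_real_,
                 states = states, soc = soc, rates = rates, tpa = tpa,
                 fedam = fedam, reactions = reactions,
                 binding_sites = binding)
    })
    ps_dataset(species, conditions)
  })
}

#' Perturb a dataset with seeded noise
#'
#' Applies multiplicative lognormal noise (sdlog = \code{relative_noise}) to
#' every rate constant and additive uniform noise of half-width
#' \code{relative_noise} times the magnitude to every energy (state
#' energies, electron-transfer dE/dG, binding free energies). Derived
#' reaction and binding columns are cleared since they are stale after
#' perturbation. Mimics the effect of printed-value rounding for robustness
#' studies.
#'
#' @param dataset a \code{ps_dataset}.
#' @param relative_noise noise level in [0, 1); 0 is the identity.
#' @param seed integer seed; the same seed gives the same perturbation.
#' @return The perturbed dataset.
#' @export
perturb_dataset <- function(dataset, relative_noise, seed = 1L) {
  stopifnot(inherits(dataset, "ps_dataset"),
            is.numeric(relative_noise), length(relative_noise) == 1L)
  if (relative_noise < 0 || relative_noise >= 1)
    stop("relative_noise must be in [0, 1)", call. = FALSE)
  if (relative_noise == 0) return(dataset)
  .with_seed(seed, {
    jig_e <- function(x) {
      ok <- !is.na(x)
      x[ok] <- x[ok] + stats::runif(sum(ok), -1, 1) * relative_noise * abs(x[ok])
      x
    }
    jig_r <- function(x) {
      ok <- !is.na(x)
      x[ok] <- x[ok] * exp(stats::rnorm(sum(ok), 0, relative_noise))
      x
    }
    for (i in seq_along(dataset$species)) {
      sp <- dataset$species[[i]]
      sp$states$vertical_energy <- jig_e(sp$states$vertical_energy)
      sp$states$adiabatic_energy <- jig_e(sp$states$adiabatic_energy)
      sp$rates$isc$rate <- jig_r(sp$rates$isc$rate)
      for (nm in c("k_F", "k_IC", "k_P")) sp$rates[[nm]] <- jig_r(sp$rates[[nm]])
      if (nrow(sp$reactions)) {
        sp$reactions$delta_E_vertical <- jig_e(sp$reactions$delta_E_vertical)
        sp$reactions$delta_G_adiabatic <- jig_e(sp$reactions$delta_G_adiabatic)
        sp$reactions$lambda_reorg <- NA_real_
        sp$reactions$delta_G_activation <- NA_real_
        sp$reactions$rate_k <- NA_real_
      }
      if (nrow(sp$binding_sites)) {
        sp$binding_sites$delta_G_binding <-
          jig_e(sp$binding_sites$delta_G_binding)
        sp$binding_sites$K_b <- NA_real_
      }
      dataset$species[[i]] <- sp
    }
    dataset
  })
}
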