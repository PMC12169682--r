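# Marcus-theory electron-transfer kinetics: reorganization energy from the
# vertical/adiabatic energy split, the Marcus activation barrier, the Eyring
# (TST) rate constant, and batch completion of a reaction table.

#' Reorganization energy from vertical and adiabatic energetics
#'
#' lambda ~ dE - dG, where dE is the vertical energy difference (products at
#' the reactants' geometry) and dG the adiabatic reaction free energy. A
#' non-positive result leaves the Marcus expression undefined and is an
#' error.
#'
#' @param delta_E vertical energy difference, kcal mol^-1.
#' @param delta_G adiabatic reaction free energy, kcal mol^-1.
#' @return Reorganization energy lambda in kcal mol^-1.
#' @examples
#' reorganization_energy(34.3, 19.9)  # 14.4
#' @export
reorganization_energy <- function(delta_E, delta_G) {
  lambda <- delta_E - delta_G
  if (any(!is.finite(lambda) | lambda <= 0))
    stop("lambda = delta_E - delta_G must be > 0", call. = FALSE)
  lambda
}

#' Marcus activation energy
#'
#' dG_act = (lambda/4) (1 + dG/lambda)^2: a parabola in dG with a barrierless
#' vertex at dG = -lambda; more negative dG beyond the vertex (inverted
#' region) raises the barrier again.
#'
#' @param delta_G adiabatic reaction free energy, kcal mol^-1.
#' @param lambda_reorg reorganization energy, kcal mol^-1; must be positive.
#' @return Activation energy in kcal mol^-1 (always >= 0).
#' @examples
#' activation_energy(-25.0, 12.3)  # 3.3
#' @export
activation_energy <- function(delta_G, lambda_reorg) {
  if (any(!is.finite(lambda_reorg) | lambda_reorg <= 0))
    stop("lambda_reorg must be > 0", call. = FALSE)
  (lambda_reorg / 4) * (1 + delta_G / lambda_reorg)^2
}

#' Eyring (transition-state-theory) rate constant
#'
#' k = (kB T / h) exp(-dG_act / R T). The prefactor at 298.15 K is
#' 6.2124e12 s^-1 and bounds every rate from above.
#'
#' @param delta_G_activation activation energy in kcal mol^-1; must be >= 0.
#' @param conditions a \code{\link{ps_conditions}} (temperature used).
#' @return Rate constant; for the bimolecular electron-transfer reactions
#'   treated here the working unit is M^-1 s^-1.
#' @examples
#' rate_constant(0)    # kB T / h = 6.2124e12
#' rate_constant(1.1)  # ~1e12
#' @export
rate_constant <- function(delta_G_activation, conditions = ps_conditions()) {
  conditions <- .as_conditions(conditions)
  if (any(!is.finite(delta_G_activation) | delta_G_activation < 0))
    stop("delta_G_activation must be >= 0", call. = FALSE)
  eyring_prefactor(conditions$temperature) *
    exp(-delta_G_activation / .RT(conditions))
}

#' Complete an electron-transfer reaction table
#'
#' Fills the derived columns of a reaction table from its (dE, dG) inputs:
#' lambda (from \code{\link{reorganization_energy}}, or kept from the table
#' when \code{lambda = "given"} and present), the Marcus activation energy
#' and the Eyring rate constant. Rows whose lambda is non-positive are
#' recorded as errors in the \code{status} column and left incomplete; the
#' remaining rows are processed. Rates above the diffusion limit are flagged
#' (flag only, value untouched).
#'
#' @param reactions data frame with at least \code{label},
#'   \code{delta_E_vertical} and \code{delta_G_adiabatic} (kcal mol^-1);
#'   typically a species' \code{reactions} table.
#' @param conditions a \code{\link{ps_conditions}}.
#' @param lambda \code{"derived"} (default) recomputes lambda = dE - dG for
#'   every row; \code{"given"} keeps a row's tabulated lambda when present
#'   (useful when reproducing published tables whose lambda column carries
#'   more information than the rounded dE/dG inputs).
#' @param diffusion_limit flag threshold in M^-1 s^-1, default 1e10.
#' @return The completed data frame with added columns
#'   \code{diffusion_limited} and \code{status} ("ok" or the row-level error
#'   message).
#' @examples
#' rx <- data.frame(label = "10b", delta_E_vertical = -12.7,
#'                  delta_G_adiabatic = -25.0)
#' reaction_table(rx)
#' @export
reaction_table <- function(reactions, conditions = ps_conditions(),
                           lambda = c("derived", "given"),
                           diffusion_limit = 1e10) {
  lambda <- match.arg(lambda)
  conditions <- .as_conditions(conditions)
  rx <- .records_to_df(reactions, .schema_reactions)
  rx$diffusion_limited <- logical(nrow(rx))
  rx$status <- rep("ok", nrow(rx))
  if (nrow(rx) == 0L) return(rx)
  for (i in seq_len(nrow(rx))) {
    dE <- rx$delta_E_vertical[i]
    dG <- rx$delta_G_adiabatic[i]
    lam <- if (lambda == "given" && !is.na(rx$lambda_reorg[i]))
      rx$lambda_reorg[i] else dE - dG
    if (!is.finite(lam) || lam <= 0) {
      rx$status[i] <- "lambda <= 0: Marcus expression undefined"
      rx$lambda_reorg[i] <- NA_real_
      rx$delta_G_activation[i] <- NA_real_
      rx$rate_k[i] <- NA_real_
      next
    }
    rx$lambda_reorg[i] <- lam
    rx$delta_G_activation[i] <- activation_energy(dG, lam)
    rx$rate_k[i] <- rate_constant(rx$delta_G_activation[i], conditions)
    rx$diffusion_limited[i] <- rx$rate_k[i] > diffusion_limit
  }
  rx
}
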