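# End-to-end driver assembling the full photophysical report for a dataset.

#' Run the full photophysics pipeline on a dataset
#'
#' Speciates the dataset at the working pH, summarizes excited-state decay
#' for every species (total ISC rate, triplet quantum yield, lifetime,
#' Type II gate), forms the speciation-weighted apparent triplet yield,
#' completes every species' electron-transfer reaction table (Marcus +
#' Eyring) and binding-site table, and derives the two-photon summary
#' tables.
#'
#' @param dataset a \code{\link{ps_dataset}}.
#' @param pH working pH (default: the dataset's conditions).
#' @param lambda passed to \code{\link{reaction_table}}: derive the
#'   reorganization energy from dE - dG (default) or keep tabulated values.
#' @return An object of class \code{ps_analysis}: list with
#'   \code{conditions}, \code{speciation} (label, charge, fraction),
#'   \code{kinetics} (per-species summary rows), \code{phi_apparent},
#'   \code{reactions} (completed tables, one per species),
#'   \code{binding} and \code{tpa} (likewise).
#' @examples
#' d <- load_dataset(system.file("extdata", "aloe_emodin.yaml",
#'                               package = "psphot"))
#' a <- ps_analyze(d)
#' a
#' @export
ps_analyze <- function(dataset, pH = NULL, lambda = c("derived", "given")) {
  lambda <- match.arg(lambda)
  stopifnot(inherits(dataset, "ps_dataset"))
  dataset <- speciate(dataset, pH)
  cond <- dataset$conditions
  labs <- vapply(dataset$species, `[[`, character(1), "label")
  spec <- data.frame(
    label = labs,
    net_charge = vapply(dataset$species, `[[`, integer(1), "net_charge"),
    molar_fraction = vapply(dataset$species, `[[`, numeric(1),
                            "molar_fraction"),
    stringsAsFactors = FALSE)
  kin <- do.call(rbind, lapply(dataset$species, function(sp) {
    s <- kinetics_summary(sp)
    data.frame(label = sp$label, k_prime_ISC = s$k_prime_ISC,
               phi_T = s$phi_T, tau_T1 = s$tau_T1,
               gap_T1_S0_eV = s$energy_gap_T1_S0,
               type_ii_feasible = s$type_ii_feasible,
               type_ii_margin_eV = s$type_ii_margin,
               stringsAsFactors = FALSE)
  }))
  rownames(kin) <- NULL
  ok <- !is.na(kin$phi_T)
  phi_app <- if (any(ok) && abs(sum(spec$molar_fraction[ok]) - 1) <= 1e-3) {
    fr <- spec$molar_fraction[ok] / sum(spec$molar_fraction[ok])
    apparent_quantum_yield(kin$phi_T[ok], fr)
  } else NA_real_
  rx <- lapply(dataset$species, function(sp)
    reaction_table(sp$reactions, cond, lambda = lambda))
  names(rx) <- labs
  bind <- lapply(dataset$species, function(sp)
    site_table(sp$binding_sites, cond))
  names(bind) <- labs
  tpa <- lapply(dataset$species, tpa_table)
  names(tpa) <- labs
  structure(list(conditions = cond, speciation = spec, kinetics = kin,
                 phi_apparent = phi_app, reactions = rx, binding = bind,
                 tpa = tpa),
            class = "ps_analysis")
}

#' @export
print.ps_analysis <- function(x, ...) {
  cat(sprintf("Photophysical analysis at T = %.2f K, pH = %.2f\n\n",
              x$conditions$temperature, x$conditions$pH))
  cat("Speciation (molar fractions):\n")
  sp <- x$speciation
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-8s charge %+d  %7.4f\n", sp$label[i],
                sp$net_charge[i], sp$molar_fraction[i]))
  cat("\nExcited-state kinetics:\n")
  k <- x$kinetics
  for (i in seq_len(nrow(k))) {
    cat(sprintf(
      "  %-8s k'_ISC = %9.3g /s  Phi_T = %s  tau_T1 = %s  Type II: %s\n",
      k$label[i], k$k_prime_ISC[i],
      ifelse(is.na(k$phi_T[i]), "NA", sprintf("%.2f", k$phi_T[i])),
      ifelse(is.na(k$tau_T1[i]), "NA", sprintf("%.2f s", k$tau_T1[i])),
      ifelse(is.na(k$type_ii_feasible[i]), "NA",
             ifelse(k$type_ii_feasible[i],
                    sprintf("feasible (+%.2f eV)", k$type_ii_margin_eV[i]),
                    "infeasible"))))
  }
  if (!is.na(x$phi_apparent))
    cat(sprintf("\nApparent (speciation-weighted) Phi_T = %.2f\n",
                x$phi_apparent))
  n_rx <- sum(vapply(x$reactions, nrow, integer(1)))
  n_b <- sum(vapply(x$binding, nrow, integer(1)))
  cat(sprintf("\n%d electron-transfer reactions and %d binding sites completed",
              n_rx, n_b))
  cat(" (see $reactions, $binding, $tpa)\n")
  invisible(x)
}

#' @export
summary.ps_analysis <- function(object, ...) {
  object
}
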