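# Sequential polyprotic acid-base speciation.
#
# A chain of n pKa values defines n+1 protonation states (index 0 = fully
# protonated). Molar fractions follow the usual partition over cumulative
# deprotonation exponents, evaluated in log space so extreme pH is safe.

#' pKa from a deprotonation free energy
#'
#' Converts the standard free energy of one deprotonation step into its pKa
#' via pKa = dG / (R T ln 10). At 298.15 K, R T ln 10 = 1.36419 kcal mol^-1.
#'
#' @param delta_G_deprot deprotonation free energy in kcal mol^-1.
#' @param conditions a \code{\link{ps_conditions}} object (temperature used).
#' @return pKa (dimensionless), vectorized over \code{delta_G_deprot}.
#' @examples
#' pka_from_free_energy(12.551)  # ~9.20
#' @export
pka_from_free_energy <- function(delta_G_deprot, conditions = ps_conditions()) {
  conditions <- .as_conditions(conditions)
  delta_G_deprot / (.RT(conditions) * log(10))
}

#' Molar fractions of a sequential deprotonation chain
#'
#' For pKa values \eqn{pK_1 < pK_2 < \dots} the fraction of state k
#' (k = 0 is fully protonated) is
#' \deqn{f_k = 10^{\sum_{j \le k} (pH - pK_j)} / \sum_m 10^{\sum_{j \le m} (pH - pK_j)}}
#' with the empty sum equal to zero. Computed in log space for overflow
#' safety; fractions always sum to one.
#'
#' @param pka ordered vector of pKa values, most acidic site first; must be
#'   non-decreasing for a sequential chain.
#' @param pH solution pH.
#' @return Numeric vector of \code{length(pka) + 1} molar fractions, index 1
#'   being the fully protonated state.
#' @examples
#' molar_fractions(c(9.20, 11.41), pH = 7.4)  # ~98.4% neutral, 1.5% anion
#' @export
molar_fractions <- function(pka, pH) {
  stopifnot(is.numeric(pka), length(pka) >= 1L, is.numeric(pH),
            length(pH) == 1L, is.finite(pH))
  if (any(!is.finite(pka))) stop("pKa values must be finite", call. = FALSE)
  if (is.unsorted(pka, strictly = FALSE))
    stop("sequential chain requires non-decreasing pKa values", call. = FALSE)
  expo <- cumsum(c(0, pH - pka))           # log10 weights of each state
  w <- 10^(expo - max(expo))               # stabilized
  w / sum(w)
}

#' Assign molar fractions to the species of a dataset
#'
#' Builds the pKa chain from the per-species \code{pka} entries (in list
#' order; species whose \code{pka} is \code{NA} terminate the chain), falling
#' back to \code{deprotonation_free_energy} via
#' \code{\link{pka_from_free_energy}}. If a species carries both, pKa wins
#' and a warning is emitted. The chain may extend beyond the listed species;
#' unlisted terminal states must then be negligible at the working pH (the
#' fraction-sum invariant is checked by \code{\link{validate_dataset}}).
#'
#' @param dataset a \code{ps_dataset}.
#' @param pH pH at which to speciate; default is the dataset's conditions.
#' @return The dataset with every species' \code{molar_fraction} filled.
#' @examples
#' d <- load_dataset(system.file("extdata", "aloe_emodin.yaml",
#'                               package = "psphot"))
#' d <- speciate(d)
#' vapply(d$species, `[[`, numeric(1), "molar_fraction")
#' @export
speciate <- function(dataset, pH = NULL) {
  stopifnot(inherits(dataset, "ps_dataset"))
  if (is.null(pH)) pH <- dataset$conditions$pH
  pka <- vapply(dataset$species, function(sp) {
    if (!is.na(sp$pka) && !is.na(sp$deprotonation_free_energy)) {
      warning(sprintf(
        "species '%s': both pka and deprotonation_free_energy given; using pka",
        sp$label), call. = FALSE)
      sp$pka
    } else if (!is.na(sp$pka)) {
      sp$pka
    } else if (!is.na(sp$deprotonation_free_energy)) {
      pka_from_free_energy(sp$deprotonation_free_energy, dataset$conditions)
    } else {
      NA_real_
    }
  }, numeric(1))
  # chain = leading run of defined pKa values
  n_chain <- if (anyNA(pka)) which(is.na(pka))[1] - 1L else length(pka)
  if (n_chain == 0L) {
    if (length(dataset$species) == 1L) {
      dataset$species[[1]]$molar_fraction <- 1
      return(dataset)
    }
    stop("no pKa or deprotonation free energy available for speciation",
         call. = FALSE)
  }
  fr <- molar_fractions(pka[seq_len(n_chain)], pH)
  for (i in seq_along(dataset$species)) {
    dataset$species[[i]]$molar_fraction <-
      if (i <= length(fr)) fr[i] else 0
  }
  dataset$conditions$pH <- pH
  dataset
}
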