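# Intercalation thermodynamics: binding free energy to binding constant.

#' Binding constant from a binding free energy
#'
#' K_b = exp(-dG_b / R T); K_b = 1 at dG_b = 0, and every kcal/mol of
#' stabilization multiplies K_b by ~5.4 at 298.15 K, so printed 1-d.p. free
#' energies carry ~10% rate uncertainty.
#'
#' @param delta_G_b binding free energy in kcal mol^-1 (negative = bound).
#' @param conditions a \code{\link{ps_conditions}} (temperature used).
#' @return Binding constant in M^-1, vectorized.
#' @examples
#' binding_constant(-8.2)  # ~1.0e6
#' @export
binding_constant <- function(delta_G_b, conditions = ps_conditions()) {
  conditions <- .as_conditions(conditions)
  stopifnot(is.numeric(delta_G_b))
  exp(-delta_G_b / .RT(conditions))
}

#' Complete and rank a table of binding sites
#'
#' @param sites data frame with columns \code{label} and
#'   \code{delta_G_binding} (kcal mol^-1).
#' @param conditions a \code{\link{ps_conditions}}.
#' @return The table with \code{K_b} filled, sorted by K_b descending.
#' @examples
#' site_table(data.frame(label = c("CG-GC", "AT-TA", "TC-AG"),
#'                       delta_G_binding = c(-6.6, -8.2, -11.6)))
#' @export
site_table <- function(sites, conditions = ps_conditions()) {
  conditions <- .as_conditions(conditions)
  bs <- .records_to_df(sites, .schema_binding)
  if (nrow(bs) == 0L) return(bs)
  bs$label <- .normalize_label(bs$label)
  bs$K_b <- binding_constant(bs$delta_G_binding, conditions)
  bs <- bs[order(-bs$K_b), ]
  rownames(bs) <- NULL
  bs
}
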