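# Full Electron Donor-Acceptor Map (FEDAM): a (VEA, VIP) scatter used to
# screen electron-transfer favorability before any quantitative kinetics.
# The map is a convention-agnostic pass-through of the supplied coordinates:
# VIP > 0 means energy is required to remove an electron, and VEA is plotted
# as supplied on the X-axis.

#' Build a donor-acceptor map table
#'
#' @param points data frame with columns \code{label}, \code{state_tag}
#'   ("S0", "T1" or "target"), \code{VEA} and \code{VIP} (eV). Duplicate
#'   (label, state_tag) pairs or an empty input are errors.
#' @return The coordinate table (X = VEA, Y = VIP), order preserved.
#' @export
build_map <- function(points) {
  pts <- .records_to_df(points, .schema_fedam)
  if (nrow(pts) == 0L) stop("no map points supplied", call. = FALSE)
  pts$label <- .normalize_label(pts$label)
  if (anyDuplicated(pts[c("label", "state_tag")]))
    stop("duplicate (label, state_tag) map points", call. = FALSE)
  pts
}

#' Donor-acceptor electron-transfer gap
#'
#' gap = VIP(donor) - VEA(acceptor): the energy to move an electron from the
#' donor to the acceptor at vertical geometries. Lower (more negative) is
#' more favorable.
#'
#' @param donor,acceptor single-row map points (lists or one-row data frames
#'   with \code{VIP} / \code{VEA}).
#' @return Gap in eV.
#' @export
et_gap <- function(donor, acceptor) {
  vip <- as.numeric(donor$VIP)
  vea <- as.numeric(acceptor$VEA)
  stopifnot(length(vip) == 1L, length(vea) == 1L)
  vip - vea
}

#' Rank donor-acceptor pairs by electron-transfer gap
#'
#' @param donors,acceptors map tables (as from \code{\link{build_map}}).
#' @return Data frame of all donor-acceptor pairs with their gaps, ordered
#'   from most to least favorable (ascending gap; ties broken by donor then
#'   acceptor order).
#' @export
rank_et_pairs <- function(donors, acceptors) {
  donors <- build_map(donors)
  acceptors <- build_map(acceptors)
  grid <- expand.grid(d = seq_len(nrow(donors)), a = seq_len(nrow(acceptors)))
  out <- data.frame(
    donor = donors$label[grid$d], donor_state = donors$state_tag[grid$d],
    acceptor = acceptors$label[grid$a],
    acceptor_state = acceptors$state_tag[grid$a],
    gap_eV = donors$VIP[grid$d] - acceptors$VEA[grid$a],
    stringsAsFactors = FALSE)
  out <- out[order(out$gap_eV, grid$d, grid$a), ]
  rownames(out) <- NULL
  out
}

#' Triplet-triplet interaction metric
#'
#' For a triplet-state map entry, the sum of its X and Y coordinates
#' (VEA + VIP) scores the favorability of triplet-triplet annihilation
#' between two excited molecules of the same species; lower is more
#' favorable under the map's sign convention.
#'
#' @param point a triplet-state map entry (\code{state_tag == "T1"}).
#' @return VEA + VIP in eV.
#' @examples
#' tt_metric(list(state_tag = "T1", VEA = -2.0, VIP = 1.45))  # -0.55
#' @export
tt_metric <- function(point) {
  tag <- as.character(point$state_tag)
  if (!length(tag) || !startsWith(tag, "T"))
    stop("tt_metric is defined for triplet-state map entries only",
         call. = FALSE)
  as.numeric(point$VEA) + as.numeric(point$VIP)
}

#' Ground-state electron affinity from the radical anion's ionization
#'
#' VEA(S0) = -VIP(radical anion): attaching an electron to the neutral is
#' the reverse of ionizing its radical anion.
#'
#' @param vip_radical_anion vertical ionization potential of the radical
#'   anion, eV.
#' @return VEA of the parent species, eV.
#' @export
anion_vea <- function(vip_radical_anion) {
  stopifnot(is.numeric(vip_radical_anion))
  -vip_radical_anion
}
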