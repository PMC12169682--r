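# Dataset containers, validation and text round-trip (YAML / JSON).
#
# A photosensitizer dataset bundles, per protonation species, everything the
# downstream photophysics needs: electronic states, spin-orbit couplings,
# decay rate constants, two-photon transitions, donor-acceptor map points,
# electron-transfer reactions and binding sites. All tabular parts are plain
# data frames; the container is a light S3 list.

# column schemas: name -> storage type ("character", "integer", "double")
.schema_states <- c(multiplicity = "character", index = "integer",
                    vertical_energy = "double", adiabatic_energy = "double",
                    oscillator_strength = "double")
.schema_soc <- c(singlet_index = "integer", triplet_index = "integer",
                 zeta_x = "double", zeta_y = "double", zeta_z = "double",
                 zeta_magnitude = "double")
.schema_isc <- c(singlet_index = "integer", triplet_index = "integer",
                 rate = "double")
.schema_tpa <- c(state_index = "integer", excitation_energy = "double",
                 photon_wavelength_nm = "double", delta_TPA_strength = "double",
                 gamma_broadening = "double", sigma_raw_GM = "double",
                 sigma_corrected_GM = "double")
.schema_fedam <- c(label = "character", state_tag = "character",
                   VEA = "double", VIP = "double")
.schema_reactions <- c(label = "character", delta_E_vertical = "double",
                       delta_G_adiabatic = "double", lambda_reorg = "double",
                       delta_G_activation = "double", rate_k = "double")
.schema_binding <- c(label = "character", delta_G_binding = "double",
                     K_b = "double")

.empty_df <- function(schema) {
  cols <- lapply(schema, function(t) vector(t, 0L))
  as.data.frame(cols, stringsAsFactors = FALSE)
}

# coerce a list of row-records (possibly with missing fields / NULLs) to a
# data frame matching `schema`; NULL/absent -> NA
.records_to_df <- function(records, schema) {
  if (is.null(records) || length(records) == 0L) return(.empty_df(schema))
  if (is.data.frame(records)) records <- .df_to_records(records)
  cols <- lapply(names(schema), function(nm) {
    vals <- lapply(records, function(r) {
      v <- r[[nm]]
      if (is.null(v) || length(v) == 0L) NA else v
    })
    v <- unlist(vals, use.names = FALSE)
    switch(schema[[nm]],
           character = as.character(v),
           integer   = as.integer(v),
           double    = as.numeric(v))
  })
  names(cols) <- names(schema)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

.df_to_records <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    r <- lapply(r, function(v) v[[1]])
    r[!vapply(r, function(v) is.na(v), logical(1))]
  })
}

# labels in the source literature use en-dashes ("AT--TA" variants); normalize
.normalize_label <- function(x) {
  if (is.null(x)) return(x)
  gsub("[‒–—−]", "-", x)
}

#' Construct one protonation species of a photosensitizer
#'
#' @param label species label, e.g. \code{"AE"} or \code{"AE-"}.
#' @param net_charge integer net charge of the species.
#' @param pka pKa of the deprotonation taking this species to the next one in
#'   the chain, or \code{NA} for the terminal species.
#' @param deprotonation_free_energy alternative to \code{pka}: the free energy
#'   of that deprotonation in kcal mol^-1 (converted via
#'   \code{\link{pka_from_free_energy}} at speciation time). When both are
#'   given, \code{pka} wins and a warning is emitted.
#' @param molar_fraction molar fraction in [0, 1], or \code{NA} until
#'   \code{\link{speciate}} fills it.
#' @param states data frame of electronic states with columns
#'   \code{multiplicity} ("singlet"/"triplet"), \code{index},
#'   \code{vertical_energy} (eV), \code{adiabatic_energy} (eV, optional),
#'   \code{oscillator_strength} (singlets only).
#' @param soc data frame of spin-orbit coupling elements with columns
#'   \code{singlet_index}, \code{triplet_index}, \code{zeta_x}, \code{zeta_y},
#'   \code{zeta_z}, \code{zeta_magnitude} (all cm^-1; components optional).
#' @param rates list with components \code{isc} (data frame
#'   \code{singlet_index}, \code{triplet_index}, \code{rate} in s^-1),
#'   \code{k_F}, \code{k_IC}, \code{k_P} (s^-1).
#' @param tpa data frame of two-photon transitions (see
#'   \code{\link{tpa_table}}).
#' @param fedam data frame of donor-acceptor map points with columns
#'   \code{label}, \code{state_tag} ("S0"/"T1"/"target"), \code{VEA},
#'   \code{VIP} (eV).
#' @param reactions data frame of electron-transfer reactions with columns
#'   \code{label}, \code{delta_E_vertical}, \code{delta_G_adiabatic} and the
#'   derived \code{lambda_reorg}, \code{delta_G_activation}, \code{rate_k}.
#' @param binding_sites data frame with columns \code{label},
#'   \code{delta_G_binding} (kcal mol^-1) and derived \code{K_b} (M^-1).
#' @return An object of class \code{ps_species}.
#' @export
ps_species <- function(label, net_charge = 0L, pka = NA_real_,
                       deprotonation_free_energy = NA_real_,
                       molar_fraction = NA_real_,
                       states = NULL, soc = NULL, rates = NULL, tpa = NULL,
                       fedam = NULL, reactions = NULL, binding_sites = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  if (is.null(rates)) rates <- list()
  structure(list(
    label = .normalize_label(label),
    net_charge = as.integer(net_charge),
    pka = as.numeric(pka),
    deprotonation_free_energy = as.numeric(deprotonation_free_energy),
    molar_fraction = as.numeric(molar_fraction),
    states = .records_to_df(states, .schema_states),
    soc = .records_to_df(soc, .schema_soc),
    rates = list(
      isc  = .records_to_df(rates$isc, .schema_isc),
      k_F  = if (is.null(rates$k_F)) NA_real_ else as.numeric(rates$k_F),
      k_IC = if (is.null(rates$k_IC)) NA_real_ else as.numeric(rates$k_IC),
      k_P  = if (is.null(rates$k_P)) NA_real_ else as.numeric(rates$k_P)
    ),
    tpa = .records_to_df(tpa, .schema_tpa),
    fedam = {
      f <- .records_to_df(fedam, .schema_fedam)
      f$label <- .normalize_label(f$label)
      f
    },
    reactions = {
      r <- .records_to_df(reactions, .schema_reactions)
      r$label <- .normalize_label(r$label)
      r
    },
    binding_sites = {
      b <- .records_to_df(binding_sites, .schema_binding)
      b$label <- .normalize_label(b$label)
      b
    }
  ), class = "ps_species")
}

#' Construct a photosensitizer dataset
#'
#' @param species a list of \code{\link{ps_species}} objects, ordered from the
#'   most protonated state onwards along the deprotonation chain.
#' @param conditions a \code{\link{ps_conditions}} object.
#' @return An object of class \code{ps_dataset}.
#' @seealso \code{\link{load_dataset}}, \code{\link{validate_dataset}},
#'   \code{\link{generate_dataset}}
#' @export
ps_dataset <- function(species, conditions = ps_conditions()) {
  stopifnot(is.list(species))
  if (!all(vapply(species, inherits, logical(1), "ps_species")))
    stop("'species' must be a list of ps_species objects", call. = FALSE)
  structure(list(conditions = .as_conditions(conditions), species = species),
            class = "ps_dataset")
}

#' @export
print.ps_dataset <- function(x, ...) {
  cat(sprintf("Photosensitizer dataset: %d species, T = %.2f K, pH = %.2f\n",
              length(x$species), x$conditions$temperature, x$conditions$pH))
  for (sp in x$species) {
    cat(sprintf(
      "  %-8s charge %+d  states %d  ISC channels %d  reactions %d  sites %d\n",
      sp$label, sp$net_charge, nrow(sp$states), nrow(sp$rates$isc),
      nrow(sp$reactions), nrow(sp$binding_sites)))
  }
  invisible(x)
}

## ---- validation -----------------------------------------------------------

.violation <- function(species, field, message) {
  data.frame(species = species, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a photosensitizer dataset
#'
#' Checks every container invariant (positive energies, non-negative
#' oscillator strengths and rates, SOC component/magnitude consistency,
#' unique state indices per multiplicity, molar fractions in [0,1] summing to
#' one once speciation has run, positive binding constants) and reports
#' violations as data, never as errors.
#'
#' @param dataset a \code{ps_dataset}.
#' @param soc_tol relative tolerance for agreement between a SOC magnitude and
#'   the Euclidean norm of its components, when components are present.
#' @return A data frame with columns \code{species}, \code{field},
#'   \code{message}; zero rows iff the dataset is valid.
#' @examples
#' d <- load_dataset(system.file("extdata", "aloe_emodin.yaml",
#'                               package = "psphot"))
#' nrow(validate_dataset(d)) == 0
#' @export
validate_dataset <- function(dataset, soc_tol = 1e-3) {
  stopifnot(inherits(dataset, "ps_dataset"))
  v <- list()
  add <- function(sp, field, msg) v[[length(v) + 1L]] <<- .violation(sp, field, msg)

  if (length(dataset$species) == 0L)
    add("<dataset>", "species", "species list is empty")
  labs <- vapply(dataset$species, `[[`, character(1), "label")
  if (anyDuplicated(labs))
    add("<dataset>", "species", "duplicate species labels")

  for (sp in dataset$species) {
    lab <- sp$label
    if (!is.na(sp$molar_fraction) &&
        (sp$molar_fraction < 0 || sp$molar_fraction > 1))
      add(lab, "molar_fraction", "molar_fraction outside [0, 1]")

    st <- sp$states
    if (nrow(st)) {
      if (!all(st$multiplicity %in% c("singlet", "triplet")))
        add(lab, "states.multiplicity", "multiplicity must be singlet or triplet")
      if (any(!is.finite(st$vertical_energy) | st$vertical_energy <= 0))
        add(lab, "states.vertical_energy", "vertical_energy must be > 0")
      if (any(!is.na(st$adiabatic_energy) & st$adiabatic_energy <= 0))
        add(lab, "states.adiabatic_energy", "adiabatic_energy must be > 0")
      f <- st$oscillator_strength[st$multiplicity == "singlet"]
      if (any(!is.na(f) & f < 0))
        add(lab, "states.oscillator_strength", "oscillator_strength must be >= 0")
      for (m in unique(st$multiplicity)) {
        if (anyDuplicated(st$index[st$multiplicity == m]))
          add(lab, "states.index", sprintf("duplicate %s state indices", m))
      }
    }

    so <- sp$soc
    if (nrow(so)) {
      if (any(!is.na(so$zeta_magnitude) & so$zeta_magnitude < 0))
        add(lab, "soc.zeta_magnitude", "zeta_magnitude must be >= 0")
      has_comp <- !is.na(so$zeta_x) & !is.na(so$zeta_y) & !is.na(so$zeta_z) &
        !is.na(so$zeta_magnitude)
      if (any(has_comp)) {
        norm <- sqrt(so$zeta_x^2 + so$zeta_y^2 + so$zeta_z^2)
        bad <- has_comp &
          abs(norm - so$zeta_magnitude) > soc_tol * pmax(so$zeta_magnitude, 1)
        if (any(bad))
          add(lab, "soc.zeta_magnitude",
              "zeta_magnitude inconsistent with Euclidean norm of components")
      }
    }

    r <- sp$rates
    for (nm in c("k_F", "k_IC", "k_P")) {
      if (!is.na(r[[nm]]) && r[[nm]] < 0)
        add(lab, paste0("rates.", nm), sprintf("%s must be >= 0", nm))
    }
    if (nrow(r$isc) && any(!is.na(r$isc$rate) & r$isc$rate < 0))
      add(lab, "rates.isc", "ISC rates must be >= 0")

    tp <- sp$tpa
    if (nrow(tp)) {
      if (any(!is.na(tp$excitation_energy) & tp$excitation_energy <= 0))
        add(lab, "tpa.excitation_energy", "excitation_energy must be > 0")
      for (nm in c("sigma_raw_GM", "sigma_corrected_GM", "delta_TPA_strength"))
        if (any(!is.na(tp[[nm]]) & tp[[nm]] < 0))
          add(lab, paste0("tpa.", nm), sprintf("%s must be >= 0", nm))
      both <- !is.na(tp$photon_wavelength_nm) & !is.na(tp$excitation_energy)
      if (any(both)) {
        expect <- 2 * .const$nm_eV_product / tp$excitation_energy
        bad <- both & abs(tp$photon_wavelength_nm - expect) >
          1e-3 * pmax(expect, 1)
        if (any(bad))
          add(lab, "tpa.photon_wavelength_nm",
              "photon_wavelength_nm != twice the one-photon wavelength")
      }
    }

    fe <- sp$fedam
    if (nrow(fe)) {
      if (anyDuplicated(fe[c("label", "state_tag")]))
        add(lab, "fedam", "duplicate (label, state_tag) map points")
      if (any(!is.finite(fe$VEA)) || any(!is.finite(fe$VIP)))
        add(lab, "fedam", "VEA/VIP must be finite")
    }

    re <- sp$reactions
    if (nrow(re)) {
      if (any(!is.na(re$lambda_reorg) & re$lambda_reorg <= 0))
        add(lab, "reactions.lambda_reorg", "lambda_reorg must be > 0")
      if (any(!is.na(re$delta_G_activation) & re$delta_G_activation < 0))
        add(lab, "reactions.delta_G_activation", "delta_G_activation must be >= 0")
      kmax <- eyring_prefactor(dataset$conditions$temperature)
      if (any(!is.na(re$rate_k) & re$rate_k > kmax * (1 + 1e-9)))
        add(lab, "reactions.rate_k", "rate_k exceeds the kB*T/h prefactor")
    }

    bs <- sp$binding_sites
    if (nrow(bs) && any(!is.na(bs$K_b) & bs$K_b <= 0))
      add(lab, "binding_sites.K_b", "K_b must be > 0")
  }

  fr <- vapply(dataset$species, `[[`, numeric(1), "molar_fraction")
  if (length(fr) && all(!is.na(fr)) && abs(sum(fr) - 1) > 1e-3)
    add("<dataset>", "molar_fraction",
        sprintf("species molar fractions sum to %.6f, not 1", sum(fr)))

  if (length(v) == 0L)
    return(.violation(character(0), character(0), character(0))[0, ])
  do.call(rbind, v)
}

.assert_valid <- function(dataset) {
  rep <- validate_dataset(dataset)
  if (nrow(rep) > 0L) {
    stop("invalid dataset: ",
         paste(sprintf("[%s] %s: %s", rep$species, rep$field, rep$message),
               collapse = "; "),
         call. = FALSE)
  }
  invisible(dataset)
}

## ---- serialization --------------------------------------------------------

.species_to_plain <- function(sp) {
  out <- list(label = sp$label, net_charge = sp$net_charge)
  if (!is.na(sp$pka)) out$pka <- sp$pka
  if (!is.na(sp$deprotonation_free_energy))
    out$deprotonation_free_energy <- sp$deprotonation_free_energy
  if (!is.na(sp$molar_fraction)) out$molar_fraction <- sp$molar_fraction
  out$states <- .df_to_records(sp$states)
  out$soc <- .df_to_records(sp$soc)
  rates <- list(isc = .df_to_records(sp$rates$isc))
  for (nm in c("k_F", "k_IC", "k_P"))
    if (!is.na(sp$rates[[nm]])) rates[[nm]] <- sp$rates[[nm]]
  out$rates <- rates
  out$tpa <- .df_to_records(sp$tpa)
  out$fedam <- .df_to_records(sp$fedam)
  out$reactions <- .df_to_records(sp$reactions)
  out$binding_sites <- .df_to_records(sp$binding_sites)
  out
}

.species_from_plain <- function(x) {
  ps_species(
    label = x$label,
    net_charge = if (is.null(x$net_charge)) 0L else x$net_charge,
    pka = if (is.null(x$pka)) NA_real_ else x$pka,
    deprotonation_free_energy =
      if (is.null(x$deprotonation_free_energy)) NA_real_
      else x$deprotonation_free_energy,
    molar_fraction = if (is.null(x$molar_fraction)) NA_real_
                     else x$molar_fraction,
    states = x$states, soc = x$soc, rates = x$rates, tpa = x$tpa,
    fedam = x$fedam, reactions = x$reactions, binding_sites = x$binding_sites
  )
}

.dataset_to_plain <- function(dataset) {
  list(
    conditions = list(temperature = dataset$conditions$temperature,
                      pH = dataset$conditions$pH),
    species = lapply(dataset$species, .species_to_plain)
  )
}

.dataset_from_plain <- function(x, where = "<document>") {
  if (is.null(x$conditions))
    stop(sprintf("%s: missing 'conditions'", where), call. = FALSE)
  if (is.null(x$species) || length(x$species) == 0L)
    stop(sprintf("%s: missing or empty 'species'", where), call. = FALSE)
  cond <- ps_conditions(
    temperature = if (is.null(x$conditions$temperature)) 298.15
                  else x$conditions$temperature,
    pH = if (is.null(x$conditions$pH)) 7.4 else x$conditions$pH)
  species <- lapply(x$species, function(s) {
    if (is.null(s$label))
      stop(sprintf("%s: species without 'label'", where), call. = FALSE)
    .species_from_plain(s)
  })
  ps_dataset(species, cond)
}

#' Read a photosensitizer dataset from a YAML or JSON document
#'
#' The format is chosen by file extension (\code{.json} means JSON, anything
#' else is parsed as YAML, of which JSON is a subset). Labels are normalized
#' to ASCII hyphens on load. The loaded dataset is validated; a schema or
#' invariant violation raises an error naming the offending field.
#'
#' @param path path to the document.
#' @return A validated \code{\link{ps_dataset}}.
#' @examples
#' d <- load_dataset(system.file("extdata", "aloe_emodin.yaml",
#'                               package = "psphot"))
#' d
#' @export
load_dataset <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  plain <- if (identical(ext, "json")) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  d <- .dataset_from_plain(plain, where = path)
  rep <- validate_dataset(d)
  if (nrow(rep) > 0L)
    stop(sprintf("%s: validation failed: %s", path,
                 paste(sprintf("[%s] %s: %s", rep$species, rep$field,
                               rep$message), collapse = "; ")),
         call. = FALSE)
  d
}

#' Write a photosensitizer dataset to a YAML or JSON document
#'
#' @param dataset a valid \code{ps_dataset}; an empty species list is an
#'   error.
#' @param path output path; \code{.json} selects JSON, anything else YAML.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{load_dataset}} for the inverse; round trips preserve
#'   all values to text precision (better than 1e-12 relative).
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "ps_dataset"))
  if (length(dataset$species) == 0L)
    stop("refusing to save a dataset with an empty species list", call. = FALSE)
  .assert_valid(dataset)
  plain <- .dataset_to_plain(dataset)
  ext <- tolower(tools::file_ext(path))
  ok <- tryCatch({
    if (identical(ext, "json")) {
      jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                           null = "null")
    } else {
      yaml::write_yaml(plain, path, precision = 17L)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("could not write %s: %s", path, conditionMessage(ok)),
         call. = FALSE)
  invisible(path)
}

#' Compare two datasets up to floating-point serialization tolerance
#'
#' @param a,b \code{ps_dataset} objects.
#' @param tolerance relative tolerance on numeric fields.
#' @return \code{TRUE} or a character vector of differences.
#' @export
datasets_equal <- function(a, b, tolerance = 1e-12) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = tolerance,
                   check.attributes = FALSE))
}
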