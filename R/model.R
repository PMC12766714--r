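#' Constraint-based metabolic model structures
#'
#' A `gem_model` is a lightweight stoichiometric model: a metabolite table, a
#' reaction table with flux bounds and functional tags, and a sparse
#' stoichiometric matrix (metabolites x reactions, negative = consumed).
#' Fluxes are in mmol gDW^-1 h^-1 throughout; exchange fluxes follow the
#' COBRA sign convention (negative = uptake, positive = secretion).
#'
#' Metabolites live in one of three compartments: `cytosol`, `extracellular`,
#' or `pool`. Pool metabolites represent intracellular storage polymers (PHA,
#' glycogen, polyphosphate) whose *amounts* are integrated over time by the
#' cycle simulator; they are excluded from the steady-state mass balance, so
#' a `storage_sink` reaction depositing into a pool carries the instantaneous
#' accumulation rate.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of cytosol/extracellular/pool), `carbon_atoms`, `phosphorus_atoms`,
#'   `role` (one of carbon_substrate, amino_acid, storage_PHA,
#'   storage_glycogen, storage_polyP, gas, ion, generic).
#' @param reactions data.frame with columns `id`, `lower_bound`,
#'   `upper_bound`, and a list-column `tags` of character vectors over
#'   exchange/transport/internal/ETC/maintenance/biomass/storage_sink.
#' @param stoichiometry numeric or `Matrix` sparse matrix, metabolites in
#'   rows, reactions in columns, dimnames matching the id columns.
#' @param biomass_reaction,maintenance_reaction,o2_exchange reaction ids.
#' @param carbon_exchanges character vector of exchange reaction ids whose
#'   extracellular metabolite is a carbon source.
#' @param amino_acid_exchanges named character vector mapping amino-acid
#'   names to exchange reaction ids (at most 20 entries).
#' @param atp_metabolite metabolite id of cytosolic ATP (used to validate
#'   the maintenance reaction); defaults to the first id matching `^atp`.
#' @param o2_uptake_limit most negative oxygen exchange flux allowed under
#'   aerobic conditions (default -1000).
#' @param id model identifier used in screen reports (default "model").
#' @return an object of class `gem_model`.
#' @export
gem_model <- function(metabolites, reactions, stoichiometry,
                      biomass_reaction, maintenance_reaction,
                      o2_exchange = NULL,
                      carbon_exchanges = character(),
                      amino_acid_exchanges = character(),
                      atp_metabolite = NULL,
                      o2_uptake_limit = -1000,
                      id = "model") {
  stoichiometry <- Matrix::Matrix(stoichiometry, sparse = TRUE)
  metabolites$carbon_atoms <- as.integer(metabolites$carbon_atoms)
  metabolites$phosphorus_atoms <- as.integer(metabolites$phosphorus_atoms)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  if (is.null(atp_metabolite)) {
    hit <- grep("^atp", metabolites$id, value = TRUE)
    atp_metabolite <- if (length(hit)) hit[[1]] else NA_character_
  }
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry,
         biomass_reaction = biomass_reaction,
         maintenance_reaction = maintenance_reaction,
         o2_exchange = o2_exchange,
         carbon_exchanges = carbon_exchanges,
         amino_acid_exchanges = amino_acid_exchanges,
         atp_metabolite = atp_metabolite,
         o2_uptake_limit = o2_uptake_limit),
    class = "gem_model")
  validate_gem(m)
  m
}

MET_COMPARTMENTS <- c("cytosol", "extracellular", "pool")
MET_ROLES <- c("carbon_substrate", "amino_acid", "storage_PHA",
               "storage_glycogen", "storage_polyP", "gas", "ion", "generic")
RXN_TAGS <- c("exchange", "transport", "internal", "ETC", "maintenance",
              "biomass", "storage_sink")

#' Validate a gem_model against its structural invariants
#'
#' Checks id uniqueness, compartment/role consistency (ions carry no carbon,
#' storage roles live in the pool compartment), bound ordering, that every
#' exchange touches exactly one extracellular metabolite and every storage
#' sink exactly one pool metabolite, and that the tagged biomass and
#' maintenance reactions exist (the latter consuming ATP with unit
#' stoichiometry).
#'
#' @param model a `gem_model`.
#' @return the model, invisibly; errors describe the first violation found.
#' @export
validate_gem <- function(model) {
  met <- model$metabolites; rxn <- model$reactions; S <- model$stoichiometry
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids")
  if (!all(met$compartment %in% MET_COMPARTMENTS))
    stop("unknown compartment: ",
         paste(setdiff(met$compartment, MET_COMPARTMENTS), collapse = ", "))
  if (!all(met$role %in% MET_ROLES))
    stop("unknown metabolite role: ",
         paste(setdiff(met$role, MET_ROLES), collapse = ", "))
  if (any(met$carbon_atoms < 0) || any(met$phosphorus_atoms < 0))
    stop("negative atom counts")
  bad <- met$role == "ion" & met$carbon_atoms != 0
  if (any(bad)) stop("ion with nonzero carbon: ", met$id[bad][1])
  stor <- grepl("^storage_", met$role)
  if (any(stor & met$compartment != "pool"))
    stop("storage-role metabolite outside pool compartment: ",
         met$id[stor & met$compartment != "pool"][1])
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- which(rxn$lower_bound > rxn$upper_bound)[1]
    stop("lower_bound > upper_bound for reaction ", rxn$id[bad])
  }
  if (!identical(rownames(S), met$id) || !identical(colnames(S), rxn$id))
    stop("stoichiometry dimnames must match metabolite/reaction ids")
  bad_tags <- setdiff(unlist(rxn$tags), RXN_TAGS)
  if (length(bad_tags)) stop("unknown reaction tag: ", bad_tags[1])

  has_tag <- function(tag) vapply(rxn$tags, function(t) tag %in% t, logical(1))
  ext <- met$compartment == "extracellular"
  poolc <- met$compartment == "pool"
  for (j in which(has_tag("exchange"))) {
    touched <- which(S[, j] != 0)
    if (length(touched) != 1L || !ext[touched])
      stop("exchange reaction ", rxn$id[j],
           " must touch exactly one extracellular metabolite")
  }
  for (j in which(has_tag("storage_sink"))) {
    touched <- which(S[, j] != 0 & poolc)
    if (length(touched) != 1L)
      stop("storage_sink reaction ", rxn$id[j],
           " must touch exactly one pool metabolite")
  }

  for (fld in c("biomass_reaction", "maintenance_reaction")) {
    rid <- model[[fld]]
    if (is.null(rid) || !rid %in% rxn$id)
      stop(fld, " '", rid, "' not found in model")
  }
  j_bio <- match(model$biomass_reaction, rxn$id)
  if (!"biomass" %in% rxn$tags[[j_bio]])
    stop("biomass_reaction is not tagged 'biomass'")
  j_mnt <- match(model$maintenance_reaction, rxn$id)
  if (!"maintenance" %in% rxn$tags[[j_mnt]])
    stop("maintenance_reaction is not tagged 'maintenance'")
  if (!is.na(model$atp_metabolite)) {
    coef <- S[model$atp_metabolite, j_mnt]
    if (abs(coef + 1) > 1e-12)
      stop("maintenance reaction must consume ATP with unit stoichiometry")
  }
  if (!is.null(model$o2_exchange) && !model$o2_exchange %in% rxn$id)
    stop("o2_exchange '", model$o2_exchange, "' not found")
  miss <- setdiff(model$carbon_exchanges, rxn$id)
  if (length(miss)) stop("carbon_exchanges not in model: ", miss[1])
  miss <- setdiff(model$amino_acid_exchanges, rxn$id)
  if (length(miss)) stop("amino_acid_exchanges not in model: ", miss[1])
  if (length(model$amino_acid_exchanges) > 20)
    stop("at most 20 amino_acid_exchanges allowed")
  invisible(model)
}

#' Build a gem_model from a list of reaction descriptions
#'
#' Convenience constructor used by the synthetic generator and by tests:
#' each reaction is a list with `id`, `stoich` (named numeric, negative =
#' consumed), `lb`, `ub`, `tags`.
#'
#' @param mets metabolite data.frame (as in [gem_model()]).
#' @param rxns list of reaction descriptions.
#' @param ... passed on to [gem_model()].
#' @return a `gem_model`.
#' @export
gem_from_reactions <- function(mets, rxns, ...) {
  ids <- vapply(rxns, `[[`, character(1), "id")
  S <- Matrix::Matrix(0, nrow = nrow(mets), ncol = length(rxns),
                      dimnames = list(mets$id, ids), sparse = TRUE)
  for (k in seq_along(rxns)) {
    st <- rxns[[k]]$stoich
    if (!all(names(st) %in% mets$id))
      stop("reaction ", ids[k], " references unknown metabolite: ",
           setdiff(names(st), mets$id)[1])
    S[names(st), k] <- unname(st)
  }
  reactions <- data.frame(
    id = ids,
    lower_bound = vapply(rxns, function(r) r$lb %||% 0, numeric(1)),
    upper_bound = vapply(rxns, function(r) r$ub %||% 1000, numeric(1)),
    stringsAsFactors = FALSE)
  reactions$tags <- lapply(rxns, function(r) r$tags %||% "internal")
  gem_model(mets, reactions, S, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set flux bounds on one reaction
#'
#' @param model a `gem_model`.
#' @param rxn reaction id.
#' @param lb,ub new bounds; `NULL` leaves the current value.
#' @return the modified model.
#' @export
set_bounds <- function(model, rxn, lb = NULL, ub = NULL) {
  j <- match(rxn, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", rxn)
  if (!is.null(lb)) model$reactions$lower_bound[j] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[j] <- ub
  if (model$reactions$lower_bound[j] > model$reactions$upper_bound[j])
    stop("lower_bound > upper_bound for reaction ", rxn)
  model
}

#' Get flux bounds of one reaction
#' @inheritParams set_bounds
#' @return numeric of length 2, `c(lb, ub)`.
#' @export
get_bounds <- function(model, rxn) {
  j <- match(rxn, model$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", rxn)
  c(model$reactions$lower_bound[j], model$reactions$upper_bound[j])
}

#' Reaction ids carrying a given tag
#' @param model a `gem_model`.
#' @param tag one of exchange, transport, internal, ETC, maintenance,
#'   biomass, storage_sink.
#' @return character vector of reaction ids.
#' @export
tagged_reactions <- function(model, tag) {
  keep <- vapply(model$reactions$tags, function(t) tag %in% t, logical(1))
  model$reactions$id[keep]
}

#' @export
print.gem_model <- function(x, ...) {
  cat("gem_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions\n")
  cat("  biomass:", x$biomass_reaction,
      " maintenance:", x$maintenance_reaction, "\n")
  cat("  carbon exchanges:", length(x$carbon_exchanges),
      " amino-acid exchanges:", length(x$amino_acid_exchanges), "\n")
  invisible(x)
}
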