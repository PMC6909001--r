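# Core domain types: metabolite, reaction, metabolic_model.
#
# Conventions used throughout the package:
#  * metabolite ids are compartment-suffixed: "glc[c]", "ac[e]", "ac[u]"
#    (cytosol, member extracellular space, shared community pool);
#  * an exchange reaction touches exactly one metabolite in [e] or [u] and is
#    written "EX_x: x ->", so positive flux is secretion and negative flux is
#    uptake;
#  * bounds are in mmol/gDCW/hr with default magnitude `FLUX_BOUND` (1000);
#    a reaction is reversible iff its lower bound is negative.

#' Create a metabolite
#'
#' @param id compartment-suffixed id, e.g. `"glc[c]"`.
#' @param name human-readable name.
#' @param formula Hill-style elemental formula, or `NA` if unknown.
#' @param charge integer charge.
#' @param compartment one of `"c"`, `"e"`, `"u"`; derived from the id suffix
#'   when omitted.
#' @return a `metabolite` list.
#' @export
metabolite <- function(id, name = id, formula = NA_character_, charge = 0L,
                       compartment = NULL) {
  comp <- compartment %||% met_compartment(id)
  if (is.na(comp) || !comp %in% c("c", "e", "u")) {
    stop_fluxcom("metabolite id ", id, " has no valid compartment suffix")
  }
  structure(list(id = id, name = name, formula = formula,
                 charge = as.integer(charge), compartment = comp),
            class = "metabolite")
}

#' Create a reaction
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lb,ub flux bounds in mmol/gDCW/hr. Defaults: `[-FLUX_BOUND,
#'   FLUX_BOUND]` if `reversible`, else `[0, FLUX_BOUND]`.
#' @param reversible logical; must agree with `lb < 0`.
#' @param genes optional character vector of gene ids.
#' @param subsystem optional subsystem label.
#' @param is_exchange,is_transport,is_biomass role flags; auto-detected from
#'   the stoichiometry when `NULL` (biomass is never auto-detected).
#' @return a `reaction` list.
#' @export
reaction <- function(id, stoichiometry, lb = NULL, ub = NULL,
                     reversible = NULL, genes = character(0),
                     subsystem = NA_character_, is_exchange = NULL,
                     is_transport = NULL, is_biomass = FALSE) {
  if (length(stoichiometry) == 0) {
    stop_fluxcom("reaction ", id, " has empty stoichiometry")
  }
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop_fluxcom("reaction ", id, " stoichiometry must be a named vector")
  }
  stoichiometry <- stats::setNames(as.numeric(stoichiometry),
                                   names(stoichiometry))
  if (!is.null(lb)) lb <- as.numeric(lb)
  if (!is.null(ub)) ub <- as.numeric(ub)
  if (is.null(reversible)) reversible <- if (is.null(lb)) FALSE else lb < 0
  lb <- lb %||% (if (reversible) -FLUX_BOUND else 0)
  ub <- ub %||% FLUX_BOUND
  if (lb > ub) stop_fluxcom("reaction ", id, ": lb > ub")
  if (reversible != (lb < 0)) {
    stop_fluxcom("reaction ", id, ": reversible flag disagrees with lb < 0")
  }
  comp <- met_compartment(names(stoichiometry))
  if (is.null(is_exchange)) {
    is_exchange <- length(stoichiometry) == 1 && comp %in% c("e", "u")
  }
  if (is.null(is_transport)) {
    base <- met_base(names(stoichiometry))
    is_transport <- !is_exchange && length(unique(comp)) > 1 &&
      anyDuplicated(base) > 0
  }
  structure(list(id = id, stoichiometry = stoichiometry, lb = lb, ub = ub,
                 reversible = reversible, genes = genes,
                 subsystem = subsystem, is_exchange = is_exchange,
                 is_transport = is_transport, is_biomass = is_biomass),
            class = "reaction")
}

#' Create a metabolic model
#'
#' @param id model (member) id.
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param biomass_reaction_id id of the biomass drain reaction.
#' @param validate run [validate_model()] (default `TRUE`).
#' @return a `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, biomass_reaction_id,
                            validate = TRUE) {
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions,
                      biomass_reaction_id = biomass_reaction_id),
                 class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

#' Validate structural well-formedness of a model
#'
#' Checks id uniqueness, resolvable stoichiometry and biomass references,
#' bound sanity, the reversibility convention, and the exchange-reaction
#' shape (exactly one metabolite, in `[e]` or `[u]`).
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors list all offending ids.
#' @export
validate_model <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  bad <- character(0)
  if (anyDuplicated(met_ids)) {
    bad <- c(bad, paste0("duplicate metabolite ids: ",
                         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(rxn_ids)) {
    bad <- c(bad, paste0("duplicate reaction ids: ",
                         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", ")))
  }
  if (length(model$reactions) == 0) bad <- c(bad, "model has no reactions")
  for (r in model$reactions) {
    missing <- setdiff(names(r$stoichiometry), met_ids)
    if (length(missing) > 0) {
      bad <- c(bad, paste0("reaction ", r$id, " references undeclared ",
                           "metabolites: ", paste(missing, collapse = ", ")))
    }
    if (r$lb > r$ub) bad <- c(bad, paste0("reaction ", r$id, ": lb > ub"))
    if (r$reversible != (r$lb < 0)) {
      bad <- c(bad, paste0("reaction ", r$id,
                           ": reversible flag disagrees with lb < 0"))
    }
    if (isTRUE(r$is_exchange)) {
      comp <- met_compartment(names(r$stoichiometry))
      if (length(r$stoichiometry) != 1 || !comp %in% c("e", "u")) {
        bad <- c(bad, paste0("exchange reaction ", r$id, " must touch exactly ",
                             "one metabolite in [e] or [u]"))
      }
    }
  }
  if (!model$biomass_reaction_id %in% rxn_ids) {
    bad <- c(bad, paste0("biomass_reaction_id ", model$biomass_reaction_id,
                         " does not resolve"))
  }
  if (length(bad) > 0) {
    stop_fluxcom("invalid model ", model$id, ":\n  ",
                 paste(bad, collapse = "\n  "),
                 class = "fluxcom_invalid_model")
  }
  invisible(model)
}

#' Assemble the stoichiometric matrix S
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    S[names(st), j] <- st
  }
  S
}

reaction_ids <- function(model, exchange = NA, biomass = NA) {
  keep <- vapply(model$reactions, function(r) {
    (is.na(exchange) || r$is_exchange == exchange) &&
      (is.na(biomass) || r$is_biomass == biomass)
  }, TRUE)
  names(model$reactions)[keep]
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, ": ", length(x$metabolites),
      " metabolites, ", length(x$reactions), " reactions (",
      sum(vapply(x$reactions, `[[`, TRUE, "is_exchange")), " exchange), ",
      "biomass = ", x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}

#' Find a member's exchange reaction for a metabolite
#'
#' @param model a `metabolic_model`.
#' @param base metabolite base id (no compartment suffix).
#' @return the id of the exchange reaction touching `base[e]`, or `NA`.
#' @export
find_exchange <- function(model, base) {
  for (r in model$reactions) {
    if (!r$is_exchange) next
    sp <- split_met_id(names(r$stoichiometry))
    if (sp$base == base && sp$compartment == "e") return(r$id)
  }
  NA_character_
}

# Add (or replace) reactions / auto-create referenced metabolites.
add_reactions <- function(model, reactions, auto_create_mets = TRUE) {
  for (r in reactions) {
    missing <- setdiff(names(r$stoichiometry), names(model$metabolites))
    if (length(missing) > 0) {
      if (!auto_create_mets) {
        stop_fluxcom("reaction ", r$id, " references unknown metabolites: ",
                     paste(missing, collapse = ", "))
      }
      sp <- split_met_id(missing)
      if (any(is.na(sp$base))) {
        stop_fluxcom("cannot auto-create metabolites without a compartment ",
                     "suffix: ", paste(missing[is.na(sp$base)], collapse = ", "))
      }
      for (mid in missing) model$metabolites[[mid]] <- metabolite(mid)
    }
    model$reactions[[r$id]] <- r
  }
  model
}
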