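# Model curation diagnostics: elemental/charge balance, unbounded reactions
# under closed uptake (the operational signature of thermodynamically
# infeasible cycles), null-basis loop grouping, blocked reactions, and
# duplicate detection.
#
# All diagnostics are report-only: which reaction of a loop group to remove
# or constrain is a curator's decision, so repair is a separate explicit step
# (`constrain_loop_representatives`).

#' Elemental and charge balance report
#'
#' A reaction is balanced iff every element net and the charge net are
#' exactly zero. Reactions touching a metabolite with an unknown formula are
#' reported as unbalanceable (not imbalanced). Exchange and biomass
#' reactions move mass across the system boundary by construction and are
#' excluded.
#'
#' @param model a `metabolic_model`.
#' @return a `balance_report`: `$table` (reaction, status, charge_net),
#'   `$imbalances` (reaction -> named element-net vector), `$imbalanced`,
#'   `$unbalanceable`.
#' @export
check_balance <- function(model) {
  rows <- list(); imbal <- list()
  for (r in model$reactions) {
    if (r$is_exchange || r$is_biomass) {
      rows[[r$id]] <- data.frame(reaction = r$id, status = "excluded",
                                 charge_net = NA_real_)
      next
    }
    mets <- model$metabolites[names(r$stoichiometry)]
    formulas <- lapply(mets, function(m) parse_formula(m$formula))
    if (any(vapply(formulas, is.null, TRUE))) {
      rows[[r$id]] <- data.frame(reaction = r$id, status = "unbalanceable",
                                 charge_net = NA_real_)
      next
    }
    elements <- unique(unlist(lapply(formulas, names)))
    net <- stats::setNames(numeric(length(elements)), elements)
    charge <- 0
    for (k in seq_along(mets)) {
      coef <- r$stoichiometry[[k]]
      f <- formulas[[k]]
      net[names(f)] <- net[names(f)] + coef * f
      charge <- charge + coef * mets[[k]]$charge
    }
    ok <- all(net == 0) && charge == 0
    rows[[r$id]] <- data.frame(reaction = r$id,
                               status = if (ok) "balanced" else "imbalanced",
                               charge_net = charge)
    if (!ok) imbal[[r$id]] <- net[net != 0]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(table = tab, imbalances = imbal,
                 imbalanced = tab$reaction[tab$status == "imbalanced"],
                 unbalanceable = tab$reaction[tab$status == "unbalanceable"]),
            class = "balance_report")
}

#' Suggest a proton-only fix for an imbalanced reaction
#'
#' When a reaction is imbalanced only in hydrogen, and the charge imbalance
#' equals the hydrogen imbalance, the reaction can be repaired by moving
#' protons across the arrow.
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to inspect.
#' @return signed integer proton adjustment for the product side (negative =
#'   remove protons from / add to the reactant side), or `NULL` if the
#'   imbalance is not proton-fixable.
#' @export
suggest_proton_fix <- function(model, reaction_id) {
  rep <- check_balance(model)
  if (!reaction_id %in% rep$imbalanced) return(NULL)
  net <- rep$imbalances[[reaction_id]]
  charge <- rep$table$charge_net[rep$table$reaction == reaction_id]
  other <- net[setdiff(names(net), "H")]
  if (length(other) > 0 && any(other != 0)) return(NULL)
  h <- if ("H" %in% names(net)) net[["H"]] else 0
  if (h == charge && h != 0 && h == round(h)) return(as.integer(-h))
  NULL
}

#' Find unbounded reactions under closed uptake
#'
#' All exchange fluxes are constrained to zero and FVA is run over the
#' remaining reactions; a reaction whose flux still reaches the artificial
#' bound (`|flux| >= threshold * bound`) carries flux around a closed
#' stoichiometric cycle with no thermodynamic driving force.
#'
#' @param model a `metabolic_model`.
#' @param bound the artificial bound constant (default [FLUX_BOUND]).
#' @param threshold fraction of `bound` treated as "hitting the bound"
#'   (default 0.999, absorbing solver round-off near the bound).
#' @return a `loop_report` with `$unbounded`; `$groups` is filled by
#'   [group_loops()].
#' @export
find_unbounded <- function(model, bound = FLUX_BOUND, threshold = 0.999) {
  closed <- model
  for (id in reaction_ids(model, exchange = TRUE)) {
    closed$reactions[[id]]$lb <- 0
    closed$reactions[[id]]$ub <- 0
    closed$reactions[[id]]$reversible <- FALSE
  }
  internal <- reaction_ids(model, exchange = FALSE)
  res <- fva(closed, internal)
  cut <- threshold * bound
  hit <- !is.na(res$ranges$min) &
    (res$ranges$min <= -cut | res$ranges$max >= cut)
  structure(list(unbounded = res$ranges$reaction[hit], groups = list(),
                 blocked = character(0), fva = res),
            class = "loop_report")
}

#' Group unbounded reactions by the null basis of the internal S matrix
#'
#' Each exact rational null-space basis vector of the internal (non-exchange)
#' stoichiometric submatrix defines a candidate cycle; a group is the support
#' of a basis vector intersected with the unbounded set.
#'
#' @param model a `metabolic_model`.
#' @param unbounded character vector of unbounded reaction ids (from
#'   [find_unbounded()], or a `loop_report`).
#' @return a `loop_report` with `$groups`: list of `list(reactions,
#'   coefficients)`, coefficients being the integer null-space vector over
#'   the vector's full support.
#' @export
group_loops <- function(model, unbounded) {
  if (inherits(unbounded, "loop_report")) unbounded <- unbounded$unbounded
  internal <- reaction_ids(model, exchange = FALSE)
  S <- stoich_matrix(model)[, internal, drop = FALSE]
  basis <- rat_nullspace(S)
  groups <- list()
  if (ncol(basis) > 0) {
    for (k in seq_len(ncol(basis))) {
      support <- internal[basis[, k] != 0]
      grp <- intersect(support, unbounded)
      if (length(grp) > 0) {
        groups[[length(groups) + 1]] <-
          list(reactions = grp,
               coefficients = stats::setNames(basis[basis[, k] != 0, k],
                                              support))
      }
    }
  }
  structure(list(unbounded = unbounded, groups = groups,
                 blocked = character(0)),
            class = "loop_report")
}

#' Constrain one representative reaction per loop group
#'
#' Repair helper implementing the curator's choice: the lexicographically
#' first reaction of each group is either turned off or made irreversible.
#' A whitelist excuses reactions that a curator decides to keep (the usual
#' case for nucleotide-degradation loops that do not affect conclusions).
#'
#' @param model a `metabolic_model`.
#' @param groups a `loop_report` (or its `$groups`).
#' @param action `"off"` (lb = ub = 0) or `"irreversible"` (lb = 0).
#' @param whitelist reaction ids never to constrain.
#' @return the modified model; constrained ids in `attr(, "constrained")`.
#' @export
constrain_loop_representatives <- function(model, groups,
                                           action = c("off", "irreversible"),
                                           whitelist = character(0)) {
  action <- match.arg(action)
  if (inherits(groups, "loop_report")) groups <- groups$groups
  constrained <- character(0)
  for (g in groups) {
    cand <- setdiff(sort(g$reactions), c(whitelist, constrained))
    if (length(cand) == 0) next
    rep_id <- cand[[1]]
    model$reactions[[rep_id]]$lb <- 0
    if (action == "off") model$reactions[[rep_id]]$ub <- 0
    model$reactions[[rep_id]]$reversible <- FALSE
    constrained <- c(constrained, rep_id)
  }
  attr(model, "constrained") <- constrained
  model
}

#' Find blocked reactions
#'
#' With all exchange bounds left at their defaults (open), a reaction whose
#' FVA range is (0, 0) within tolerance can never carry flux.
#'
#' @param model a `metabolic_model`.
#' @param tolerance numeric tolerance.
#' @return character vector of blocked reaction ids.
#' @export
find_blocked <- function(model, tolerance = 1e-6) {
  res <- fva(model)
  ok <- !is.na(res$ranges$min)
  blocked <- ok & abs(res$ranges$min) < tolerance & abs(res$ranges$max) < tolerance
  res$ranges$reaction[blocked]
}

stoich_key <- function(st) {
  st <- st[order(names(st))]
  paste(names(st), format(st, scientific = FALSE, trim = TRUE),
        sep = ":", collapse = ";")
}

#' Find duplicate reaction pairs
#'
#' Reports pairs with identical stoichiometry (`orientation = "same"`) or
#' exactly negated stoichiometry (`orientation = "reversed"`). With a
#' cofactor-pair configuration (e.g. NADH <-> NADPH, NAD <-> NADP), pairs
#' that become identical after swapping cofactor base ids are flagged as
#' cofactor variants.
#'
#' @param model a `metabolic_model`.
#' @param cofactor_pairs list of length-2 character vectors of base ids.
#' @return data.frame `rxn1`, `rxn2`, `orientation`, `cofactor_variant`.
#' @export
find_duplicates <- function(model, cofactor_pairs = NULL) {
  rxns <- model$reactions[!vapply(model$reactions, `[[`, TRUE, "is_exchange")]
  ids <- names(rxns)
  key_fwd <- vapply(rxns, function(r) stoich_key(r$stoichiometry), "")
  key_rev <- vapply(rxns, function(r) stoich_key(-r$stoichiometry), "")
  swap_map <- character(0)
  if (!is.null(cofactor_pairs)) {
    for (p in cofactor_pairs) { swap_map[p[[1]]] <- p[[2]]; swap_map[p[[2]]] <- p[[1]] }
  }
  swap_st <- function(st) {
    sp <- split_met_id(names(st))
    nb <- ifelse(sp$base %in% names(swap_map), swap_map[sp$base], sp$base)
    stats::setNames(as.numeric(st), paste0(nb, "[", sp$compartment, "]"))
  }
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      orientation <- NA_character_; variant <- FALSE
      if (key_fwd[[i]] == key_fwd[[j]]) orientation <- "same"
      else if (key_fwd[[i]] == key_rev[[j]]) orientation <- "reversed"
      else if (length(swap_map) > 0) {
        ks <- stoich_key(swap_st(rxns[[i]]$stoichiometry))
        kr <- stoich_key(swap_st(-rxns[[i]]$stoichiometry))
        if (ks == key_fwd[[j]]) { orientation <- "same"; variant <- TRUE }
        else if (kr == key_fwd[[j]]) { orientation <- "reversed"; variant <- TRUE }
      }
      if (!is.na(orientation)) {
        out[[length(out) + 1]] <- data.frame(
          rxn1 = ids[[i]], rxn2 = ids[[j]], orientation = orientation,
          cofactor_variant = variant, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(rxn1 = character(0), rxn2 = character(0),
                      orientation = character(0),
                      cofactor_variant = logical(0)))
  }
  do.call(rbind, out)
}
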