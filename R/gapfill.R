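# GapFind / GapFill mixed-integer programs.
#
# GapFind: maximise the number of metabolites shown producible in a single
# flux distribution, with a binary produced-indicator x_i per metabolite and
# reaction-production coupling binaries w_ij on producing terms
# (eps <= S_ij v_j <= M w_ij). Producibility uses the accumulation-relaxed
# balance sum_j S_ij v_j >= 0 with all exchanges open; the consumption pass
# runs the same program on -S. GapFill then searches a designated reaction
# database for a minimum-cardinality addition restoring production of one
# target metabolite, with alternate optima enumerated by integer cuts.

GAPFILL_EPS <- 1e-3

producing_pairs <- function(S, lbs, ubs) {
  idx <- which(S != 0, arr.ind = TRUE)
  keep <- (S[idx] > 0 & ubs[idx[, 2]] > 0) | (S[idx] < 0 & lbs[idx[, 2]] < 0)
  idx[keep, , drop = FALSE]
}

#' Identify problem metabolites (GapFind)
#'
#' @param model a `metabolic_model`.
#' @param eps minimum production rate counting as "produced" (default 0.001).
#' @param bigM big-M constant (default [FLUX_BOUND]).
#' @return a `gap_report`: `$no_production`, `$no_consumption`, `$root`
#'   (no structural producing term at all), `$downstream`.
#' @export
gapfind <- function(model, eps = GAPFILL_EPS, bigM = FLUX_BOUND) {
  no_prod <- gapfind_direction(model, +1, eps, bigM)
  no_cons <- gapfind_direction(model, -1, eps, bigM)
  S <- stoich_matrix(model)
  lbs <- vapply(model$reactions, `[[`, 0, "lb")
  ubs <- vapply(model$reactions, `[[`, 0, "ub")
  pp <- producing_pairs(S, lbs, ubs)
  has_producer <- rownames(S) %in% rownames(S)[pp[, 1]]
  names(has_producer) <- rownames(S)
  root <- no_prod[!has_producer[no_prod]]
  structure(list(no_production = no_prod, no_consumption = no_cons,
                 root = root, downstream = setdiff(no_prod, root)),
            class = "gap_report")
}

gapfind_direction <- function(model, direction, eps, bigM) {
  S <- direction * stoich_matrix(model)
  met_ids <- rownames(S); n <- ncol(S); m <- nrow(S)
  lbs <- vapply(model$reactions, `[[`, 0, "lb")
  ubs <- vapply(model$reactions, `[[`, 0, "ub")
  pp <- producing_pairs(S, lbs, ubs)
  np <- nrow(pp)
  # columns: v (n) | w (np) | x (m)
  nv <- n + np + m
  ncons <- m + 2 * np + m
  A <- matrix(0, ncons, nv)
  row_lb <- rep(-Inf, ncons); row_ub <- rep(Inf, ncons)
  # balance rows: S v >= 0
  A[seq_len(m), seq_len(n)] <- S
  row_lb[seq_len(m)] <- 0
  # production coupling
  for (p in seq_len(np)) {
    i <- pp[p, 1]; j <- pp[p, 2]
    r1 <- m + 2 * p - 1 # S_ij v_j - M w <= 0
    A[r1, j] <- S[i, j]; A[r1, n + p] <- -bigM
    row_ub[r1] <- 0
    r2 <- m + 2 * p # S_ij v_j + M w >= eps  (i.e. >= eps - M(1-w))
    A[r2, j] <- S[i, j]; A[r2, n + p] <- bigM
    row_lb[r2] <- eps
  }
  # x_i <= sum of its w
  for (i in seq_len(m)) {
    r <- m + 2 * np + i
    A[r, n + np + i] <- 1
    mine <- which(pp[, 1] == i)
    if (length(mine) > 0) A[r, n + mine] <- -1
    row_ub[r] <- 0
  }
  lb <- c(lbs, rep(0, np + m)); ub <- c(ubs, rep(1, np + m))
  obj <- c(rep(0, n + np), rep(1, m))
  intg <- c(rep(0, n), rep(1, np + m))
  res <- solve_lp(obj, A, row_lb, row_ub, lb, ub, integrality = intg,
                  sense = "max")
  if (res$status != "optimal") {
    stop_fluxcom("gapfind MILP not optimal (status ", res$status, ")")
  }
  x <- res$x[n + np + seq_len(m)]
  met_ids[x < 0.5]
}

#' Export a member's reactions as a source database
#'
#' Internal and transport reactions only; exchange and biomass reactions are
#' excluded. Entries are tagged with the member id as source and taxon.
#'
#' @param member a `metabolic_model`.
#' @return a `reaction_db` with `source = member$id`.
#' @export
member_as_db <- function(member) {
  keep <- !vapply(member$reactions, `[[`, TRUE, "is_exchange") &
    !vapply(member$reactions, `[[`, TRUE, "is_biomass")
  entries <- member$reactions[keep]
  entries <- lapply(entries, function(r) { r$taxa <- member$id; r })
  reaction_db(entries, source = member$id)
}

# db entries usable for filling `model`: drop id collisions and entries whose
# stoichiometry already exists in the model.
usable_db_entries <- function(model, db) {
  model_keys <- vapply(model$reactions, function(r) stoich_key(r$stoichiometry), "")
  keep <- vapply(db$entries, function(r) {
    !(r$id %in% names(model$reactions)) &&
      !(stoich_key(r$stoichiometry) %in% model_keys) &&
      !(stoich_key(-r$stoichiometry) %in% model_keys)
  }, TRUE)
  db$entries[keep]
}

#' Find minimal reaction additions restoring a problem metabolite (GapFill)
#'
#' @param model a `metabolic_model`.
#' @param target problem metabolite id (compartment-suffixed).
#' @param db a `reaction_db` of candidate reactions.
#' @param direction `"production"` (for no-production metabolites) or
#'   `"consumption"` (for no-consumption metabolites, solved on -S).
#' @param max_alternates maximum number of solutions returned (first = the
#'   optimum; further solutions obtained by integer cuts).
#' @param cardinality_slack alternates may exceed the optimal cardinality by
#'   at most this much (default 0: only ties are enumerated).
#' @param allow_exchange when a candidate transporter references an
#'   extracellular metabolite absent from the model, open an exchange for it
#'   (community-pool context; the exchange does not count toward
#'   cardinality). Default `TRUE`.
#' @param eps,bigM GapFill constants.
#' @return list of `gapfill_candidate` (possibly empty: "no fill exists in
#'   this database" is a normal outcome). Ties are returned in lexicographic
#'   order of the added-reaction id sets.
#' @export
gapfill <- function(model, target, db,
                    direction = c("production", "consumption"),
                    max_alternates = 5, cardinality_slack = 0,
                    allow_exchange = TRUE, eps = GAPFILL_EPS,
                    bigM = FLUX_BOUND) {
  direction <- match.arg(direction)
  dsign <- if (direction == "production") +1 else -1
  entries <- usable_db_entries(model, db)
  if (length(entries) == 0) return(list())

  # assemble augmented network: model reactions + gated db entries (+ gated
  # exchanges for new extracellular metabolites referenced by transporters)
  aug <- model
  gate <- list() # reaction id -> index of its y binary
  exch_of <- list()
  for (k in seq_along(entries)) {
    r <- entries[[k]]
    aug <- add_reactions(aug, list(r))
    gate[[r$id]] <- k
    if (allow_exchange) {
      sp <- split_met_id(names(r$stoichiometry))
      new_e <- names(r$stoichiometry)[sp$compartment == "e"]
      new_e <- setdiff(new_e, names(model$metabolites))
      for (mid in new_e) {
        ex_id <- paste0("EX_", met_base(mid), "_gf")
        if (!ex_id %in% names(aug$reactions)) {
          aug <- add_reactions(aug, list(
            reaction(ex_id, stats::setNames(-1, mid), lb = -FLUX_BOUND,
                     ub = FLUX_BOUND, reversible = TRUE, is_exchange = TRUE)))
          gate[[ex_id]] <- k
          exch_of[[ex_id]] <- r$id
        }
      }
    }
  }
  if (!target %in% names(aug$metabolites)) {
    stop_fluxcom("gapfill target not in model or db: ", target)
  }
  S <- dsign * stoich_matrix(aug)
  rxn_ids <- colnames(S)
  n <- ncol(S); m <- nrow(S); ndb <- length(entries)
  lbs <- vapply(aug$reactions, `[[`, 0, "lb")
  ubs <- vapply(aug$reactions, `[[`, 0, "ub")
  ti <- match(target, rownames(S))
  # columns: v (n) | y (ndb)
  gated <- names(gate)
  rows <- list(); rlb <- c(); rub <- c()
  add_row <- function(coef_v, coef_y, lo, hi) {
    row <- numeric(n + ndb)
    row[seq_len(n)] <- coef_v
    row[n + seq_len(ndb)] <- coef_y
    rows[[length(rows) + 1]] <<- row
    rlb <<- c(rlb, lo); rub <<- c(rub, hi)
  }
  for (i in seq_len(m)) {
    lo <- if (i == ti) eps else 0
    add_row(S[i, ], numeric(ndb), lo, Inf)
  }
  for (rid in gated) {
    j <- match(rid, rxn_ids); k <- gate[[rid]]
    cv <- numeric(n); cv[j] <- 1
    cy <- numeric(ndb); cy[k] <- -ubs[j]
    add_row(cv, cy, -Inf, 0)           # v_j <= ub_j y_k
    cy2 <- numeric(ndb); cy2[k] <- -lbs[j]
    add_row(cv, cy2, 0, Inf)           # v_j >= lb_j y_k
  }
  A <- do.call(rbind, rows)
  lb <- c(lbs, rep(0, ndb)); ub <- c(ubs, rep(1, ndb))
  intg <- c(rep(0, n), rep(1, ndb))
  card_obj <- c(rep(0, n), rep(1, ndb))
  rank_obj <- c(rep(0, n), rank(names(entries)))

  sol_entries <- function(x) sort(names(entries)[x[n + seq_len(ndb)] > 0.5])
  cuts <- list()
  with_cuts <- function(extra_rows) {
    if (length(cuts) == 0 && length(extra_rows) == 0) {
      return(list(A = A, lo = rlb, hi = rub))
    }
    allr <- c(cuts, extra_rows)
    A2 <- rbind(A, do.call(rbind, lapply(allr, `[[`, "row")))
    list(A = A2, lo = c(rlb, vapply(allr, `[[`, 0, "lo")),
         hi = c(rub, vapply(allr, `[[`, 0, "hi")))
  }
  out <- list()
  best <- NA_real_
  while (length(out) < max_alternates) {
    sys <- with_cuts(list())
    res <- solve_lp(card_obj, sys$A, sys$lo, sys$hi, lb, ub,
                    integrality = intg, sense = "min")
    if (res$status != "optimal") break
    card <- round(res$objective)
    if (is.na(best)) best <- card
    if (card > best + cardinality_slack) break
    # deterministic tie-break: fix the cardinality, minimise lexicographic rank
    fix_row <- numeric(n + ndb); fix_row[n + seq_len(ndb)] <- 1
    sys2 <- with_cuts(list(list(row = fix_row, lo = card, hi = card)))
    res2 <- solve_lp(rank_obj, sys2$A, sys2$lo, sys2$hi, lb, ub,
                     integrality = intg, sense = "min")
    if (res2$status == "optimal") res <- res2
    ids <- sol_entries(res$x)
    out[[length(out) + 1]] <- structure(
      list(target = target, direction = direction, reactions = ids,
           exchanges = names(exch_of)[unlist(exch_of) %in% ids],
           source = db$source, cardinality = length(ids),
           solution_index = length(out) + 1),
      class = "gapfill_candidate")
    if (length(ids) == 0) break # already producible without additions
    cut <- numeric(n + ndb)
    cut[n + match(ids, names(entries))] <- 1
    cuts[[length(cuts) + 1]] <- list(row = cut, lo = -Inf,
                                     hi = length(ids) - 1)
  }
  out
}

#' Apply a gap-fill candidate to a model
#'
#' Adds the candidate's database reactions (duplicates skipped and logged in
#' `attr(, "skipped")`), auto-creating referenced metabolites, plus open
#' exchanges for newly introduced extracellular metabolites when the
#' candidate used them.
#'
#' @param model a `metabolic_model`.
#' @param candidate a `gapfill_candidate`.
#' @param db the `reaction_db` the candidate came from.
#' @return the augmented, re-validated model.
#' @export
apply_candidate <- function(model, candidate, db) {
  skipped <- character(0)
  model_keys <- vapply(model$reactions, function(r) stoich_key(r$stoichiometry), "")
  for (rid in candidate$reactions) {
    r <- db$entries[[rid]]
    if (is.null(r)) stop_fluxcom("candidate reaction not in db: ", rid)
    if (rid %in% names(model$reactions) ||
        stoich_key(r$stoichiometry) %in% model_keys) {
      skipped <- c(skipped, rid)
      next
    }
    sp <- split_met_id(names(r$stoichiometry))
    new_e <- setdiff(names(r$stoichiometry)[sp$compartment == "e"],
                     names(model$metabolites))
    model <- add_reactions(model, list(r))
    for (mid in new_e) {
      ex_id <- paste0("EX_", met_base(mid), "_gf")
      if (!ex_id %in% names(model$reactions)) {
        model <- add_reactions(model, list(
          reaction(ex_id, stats::setNames(-1, mid), lb = -FLUX_BOUND,
                   ub = FLUX_BOUND, reversible = TRUE, is_exchange = TRUE)))
      }
    }
  }
  validate_model(model)
  attr(model, "skipped") <- skipped
  model
}
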