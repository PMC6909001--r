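# Independent oracles and random fixture builders shared across the suite.
# The oracles deliberately avoid the code paths they check: the flux polytope
# is enumerated vertex by vertex, and minimal gap fills are found by
# exhaustive subset search with a plain feasibility LP.

# --- vertex enumeration ---------------------------------------------------
# All vertices of {v : S v = 0, lb <= v <= ub} (bounded polytope). A vertex
# has n - rank(S) variables at a bound; enumerate those choices.
enumerate_vertices <- function(S, lb, ub, tol = 1e-7) {
  n <- ncol(S)
  qrS <- qr(S)
  r <- qrS$rank
  nfix <- n - r
  verts <- list()
  push <- function(v) {
    if (all(v >= lb - tol & v <= ub + tol) &&
        max(abs(S %*% v)) < tol) {
      verts[[length(verts) + 1]] <<- pmin(pmax(v, lb), ub)
    }
  }
  if (nfix == 0) {
    v <- tryCatch(qr.solve(S, rep(0, nrow(S))), error = function(e) NULL)
    if (!is.null(v)) push(v)
  } else {
    fixed_sets <- utils::combn(n, nfix, simplify = FALSE)
    for (Tset in fixed_sets) {
      B <- setdiff(seq_len(n), Tset)
      SB <- S[, B, drop = FALSE]
      if (qr(SB)$rank < length(B)) next
      for (pat in seq_len(2^nfix) - 1L) {
        at_ub <- as.logical(bitwAnd(pat, 2^(seq_len(nfix) - 1L)) > 0)
        vT <- ifelse(at_ub, ub[Tset], lb[Tset])
        rhs <- -S[, Tset, drop = FALSE] %*% vT
        vB <- tryCatch(qr.solve(SB, rhs), error = function(e) NULL)
        if (is.null(vB)) next
        v <- numeric(n)
        v[Tset] <- vT; v[B] <- vB
        push(v)
      }
    }
  }
  verts
}

# oracle FBA optimum by vertex enumeration (max of c'v over vertices)
oracle_lp_max <- function(S, lb, ub, obj) {
  verts <- enumerate_vertices(S, lb, ub)
  if (length(verts) == 0) return(NA_real_)
  max(vapply(verts, function(v) sum(obj * v), 0))
}

# random small network with integer stoichiometry and bounds; always
# feasible (0 is interior) and bounded.
random_network <- function(n_met = 3, n_rxn = 5) {
  repeat {
    S <- matrix(sample(-2:2, n_met * n_rxn, replace = TRUE,
                       prob = c(.1, .2, .4, .2, .1)), n_met, n_rxn)
    if (all(colSums(abs(S)) > 0)) break
  }
  lb <- sample(-3:0, n_rxn, replace = TRUE)
  ub <- sample(0:5, n_rxn, replace = TRUE)
  list(S = S, lb = as.numeric(lb), ub = as.numeric(ub))
}

# wrap a raw (S, lb, ub) network as a metabolic_model (all cytosolic)
network_as_model <- function(net, id = "rand") {
  n_met <- nrow(net$S); n_rxn <- ncol(net$S)
  mets <- lapply(seq_len(n_met), function(i)
    metabolite(paste0("m", i, "[c]")))
  rxns <- lapply(seq_len(n_rxn), function(j) {
    st <- net$S[, j]
    names(st) <- paste0("m", seq_len(n_met), "[c]")
    st <- st[st != 0]
    reaction(paste0("r", j), st, lb = net$lb[j], ub = net$ub[j],
             reversible = net$lb[j] < 0)
  })
  metabolic_model(id, mets, rxns, "r1")
}

# --- exhaustive gap-fill oracle ------------------------------------------
# Production feasibility of `target` in `model` + an explicit reaction set,
# under the accumulation-relaxed balance (S v >= 0; -S for consumption).
producible_with <- function(model, target, extra = list(), direction = "production",
                            eps = 1e-3, allow_exchange = TRUE) {
  aug <- model
  for (r in extra) {
    if (r$id %in% names(aug$reactions)) next
    sp <- split_met_id(names(r$stoichiometry))
    new_e <- setdiff(names(r$stoichiometry)[sp$compartment == "e"],
                     names(model$metabolites))
    aug <- fluxcom:::add_reactions(aug, list(r))
    if (allow_exchange) {
      for (mid in new_e) {
        ex_id <- paste0("EXO_", fluxcom:::met_base(mid))
        if (!ex_id %in% names(aug$reactions)) {
          aug <- fluxcom:::add_reactions(aug, list(
            reaction(ex_id, stats::setNames(-1, mid), lb = -1000, ub = 1000,
                     reversible = TRUE, is_exchange = TRUE)))
        }
      }
    }
  }
  if (!target %in% names(aug$metabolites)) return(FALSE)
  dsign <- if (direction == "production") 1 else -1
  S <- dsign * stoich_matrix(aug)
  ti <- match(target, rownames(S))
  lbs <- vapply(aug$reactions, `[[`, 0, "lb")
  ubs <- vapply(aug$reactions, `[[`, 0, "ub")
  obj <- S[ti, ]
  res <- solve_lp(obj, S, rep(0, nrow(S)),
                  rep(Inf, nrow(S)), lbs, ubs, sense = "max")
  res$status == "optimal" && res$objective >= eps - 1e-9
}

# minimal fill cardinality by exhaustive subset search (sizes 0..kmax)
oracle_min_fill <- function(model, target, db, direction = "production",
                            kmax = 3, eps = 1e-3) {
  entries <- fluxcom:::usable_db_entries(model, db)
  ids <- names(entries)
  for (k in 0:min(kmax, length(ids))) {
    subsets <- if (k == 0) list(integer(0)) else
      utils::combn(seq_along(ids), k, simplify = FALSE)
    for (ss in subsets) {
      if (producible_with(model, target, entries[ss], direction, eps)) {
        return(k)
      }
    }
  }
  Inf
}

# --- random gap-fill instance --------------------------------------------
# A chain model with a planted no-production gap plus a database in which
# the minimal fill has cardinality 1 or 2 (or no fill exists).
random_gapfill_instance <- function() {
  rs <- list(
    rxn_("EX_a", "a[e] ->", lb = -10),
    rxn_("T_a", "a[e] -> a[c]"),
    rxn_("R1", "a[c] -> b[c]"),
    rxn_("R2", "b[c] -> c[c]"),
    rxn_("BIO", "c[c] ->", biomass = TRUE),
    rxn_("GU", "g[c] -> b[c]"))
  mets <- unique(unlist(lapply(rs, function(r) names(r$stoichiometry))))
  model <- metabolic_model("gm", lapply(mets, metabolite), rs, "BIO")
  kind <- sample(c("one", "two", "none"), 1)
  entries <- list()
  if (kind == "one") {
    entries <- c(entries, list(rxn_("F1", "a[c] -> g[c]")))
  } else if (kind == "two") {
    entries <- c(entries, list(rxn_("F1", "a[c] -> p[c]"),
                               rxn_("F2", "p[c] -> g[c]")))
  }
  n_noise <- sample(3:9, 1)
  for (i in seq_len(n_noise)) {
    entries <- c(entries, list(
      rxn_(sprintf("N%02d", i), sprintf("q%d[c] -> q%d[c]", i, i + 1))))
  }
  entries <- entries[sample(seq_along(entries))]
  db <- reaction_db(entries, "universal")
  expected <- switch(kind, one = 1, two = 2, none = Inf)
  list(model = model, target = "g[c]", db = db, expected = expected)
}

# shorthand reaction-from-equation used by fixtures
rxn_ <- function(id, eq, lb = NULL, ub = NULL, biomass = FALSE) {
  p <- parse_equation(eq)
  if (is.null(lb)) lb <- if (p$reversible) -1000 else 0
  if (is.null(ub)) ub <- 1000
  reaction(id, p$stoichiometry, lb = lb, ub = ub, reversible = lb < 0,
           is_biomass = biomass)
}

# simple linear chain model: EX_A -(uptake<=cap)-> A -> B -> biomass
chain_model <- function(cap = 10) {
  rs <- list(rxn_("EX_A", "A[e] ->", lb = -cap),
             rxn_("TA", "A[e] -> A[c]"),
             rxn_("AB", "A[c] -> B[c]"),
             rxn_("BIO", "B[c] ->", biomass = TRUE))
  mets <- unique(unlist(lapply(rs, function(r) names(r$stoichiometry))))
  metabolic_model("chain", lapply(mets, metabolite), rs, "BIO")
}
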