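# Bilevel community model with a shared extracellular metabolite pool.
#
# Each member k solves an inner FBA problem (max own biomass) whose shared
# uptake/export fluxes are fixed by outer allocation variables r_uptake[i,k]
# and r_export[i,k] >= 0. The outer problem optimises a community-level
# objective subject to a pool mass balance for every shared metabolite i:
#
#   sum_k r_export[i,k] + pool_in[i]  =  sum_k r_uptake[i,k] + pool_out[i]
#
# where pool_in is the community uptake from the environment (bounded by the
# diet) and pool_out the community release. The bilevel program is solved as
# a single-level MILP by replacing each inner LP with its KKT conditions
# (stationarity, primal/dual feasibility, complementary slackness linearised
# with big-M binaries); the allocations enter only inner right-hand sides,
# so the reformulation stays linear. A "joint" single-LP fallback (no inner
# optimality) is provided for cross-checking.

#' Build a community model
#'
#' @param members list of `metabolic_model`s (distinct ids).
#' @param shared character vector of shared metabolite base ids (each must
#'   have an `[e]` exchange in at least one member).
#' @param diet named numeric vector: base metabolite id -> maximum community
#'   uptake `pool_in` (mmol/gDCW/hr). Metabolites absent from the diet get a
#'   cap of 0. Diet bounds apply to the pool only, never to member variables.
#' @param id community id.
#' @return a `community_model`.
#' @export
build_community <- function(members, shared, diet = numeric(0),
                            id = "community") {
  names(members) <- vapply(members, `[[`, "", "id")
  if (anyDuplicated(names(members))) stop_fluxcom("duplicate member ids")
  ex_map <- list()
  for (s in shared) {
    hits <- vapply(members, find_exchange, "", base = s)
    hits <- hits[!is.na(hits)]
    if (length(hits) == 0) {
      stop_fluxcom("shared metabolite ", s, " absent from all members")
    }
    ex_map[[s]] <- hits
  }
  structure(list(id = id, members = members, shared = shared,
                 diet = diet, ex_map = ex_map),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", x$id, ": ", length(x$members), " members (",
      paste(names(x$members), collapse = ", "), "), ",
      length(x$shared), " shared pool metabolites\n", sep = "")
  invisible(x)
}

#' Community-level objective
#'
#' @param name label.
#' @param sense `"max"` or `"min"`.
#' @param terms data.frame with columns `type` (`"biomass"`, `"pool_out"`,
#'   `"pool_in"`, `"exchange"`), `member` (member id or `NA`), `id`
#'   (metabolite base id, reaction id, or `NA`), `weight`. `NULL` terms with
#'   `name = "growth"` default to the unweighted sum of member biomasses.
#' @param weights optional named member weights for the growth objective
#'   (abundance weighting); default all 1.
#' @return a `community_objective`.
#' @export
community_objective <- function(name = "growth", sense = c("max", "min"),
                                terms = NULL, weights = NULL) {
  sense <- match.arg(sense)
  if (is.null(terms)) {
    if (!identical(name, "growth")) {
      stop_fluxcom("terms required for objective ", name)
    }
    terms <- data.frame(type = "biomass", member = NA_character_,
                        id = NA_character_, weight = 1,
                        stringsAsFactors = FALSE)
  }
  if (nrow(terms) == 0) stop_fluxcom("objective needs a non-empty term set")
  structure(list(name = name, sense = sense, terms = terms,
                 weights = weights), class = "community_objective")
}

# ---- internal: variable layout and primal rows --------------------------

community_system <- function(cm) {
  vars <- character(0); lb <- numeric(0); ub <- numeric(0)
  members <- cm$members
  info <- list()
  off <- 0
  for (k in names(members)) {
    mdl <- members[[k]]
    rids <- names(mdl$reactions)
    lbs <- vapply(mdl$reactions, `[[`, 0, "lb")
    ubs <- vapply(mdl$reactions, `[[`, 0, "ub")
    # shared-met exchanges are governed by the allocations: widen their bounds
    for (s in cm$shared) {
      exr <- cm$ex_map[[s]][k]
      if (!is.na(exr) && nzchar(exr)) {
        j <- match(exr, rids)
        lbs[j] <- -FLUX_BOUND; ubs[j] <- FLUX_BOUND
      }
    }
    info[[k]] <- list(offset = off, n = length(rids), rxn_ids = rids,
                      S = stoich_matrix(mdl), lbs = lbs, ubs = ubs,
                      bio = match(mdl$biomass_reaction_id, rids))
    vars <- c(vars, paste0(k, ":", rids))
    lb <- c(lb, lbs); ub <- c(ub, ubs)
    off <- off + length(rids)
  }
  alloc <- list()
  for (s in cm$shared) {
    for (k in names(cm$ex_map[[s]])) {
      exr <- cm$ex_map[[s]][[k]]
      if (is.na(exr)) next
      for (kind in c("r_up", "r_ex")) {
        key <- paste0(kind, ":", s, ":", k)
        alloc[[key]] <- off
        vars <- c(vars, key); lb <- c(lb, 0); ub <- c(ub, FLUX_BOUND)
        off <- off + 1
      }
    }
  }
  pool <- list()
  for (s in cm$shared) {
    cap <- if (s %in% names(cm$diet)) cm$diet[[s]] else 0
    pool[[paste0("pool_in:", s)]] <- off
    vars <- c(vars, paste0("pool_in:", s)); lb <- c(lb, 0); ub <- c(ub, cap)
    off <- off + 1
    pool[[paste0("pool_out:", s)]] <- off
    vars <- c(vars, paste0("pool_out:", s)); lb <- c(lb, 0)
    ub <- c(ub, FLUX_BOUND)
    off <- off + 1
  }
  N <- off
  rows <- list(); rlb <- numeric(0); rub <- numeric(0)
  rtag <- character(0)
  add_row <- function(idx, coef, lo, hi, tag) {
    row <- numeric(N); row[idx] <- coef
    rows[[length(rows) + 1]] <<- row
    rlb <<- c(rlb, lo); rub <<- c(rub, hi); rtag <<- c(rtag, tag)
  }
  for (k in names(members)) {
    ik <- info[[k]]
    for (i in seq_len(nrow(ik$S))) {
      nz <- which(ik$S[i, ] != 0)
      add_row(ik$offset + nz, ik$S[i, nz], 0, 0, paste0("mass:", k, ":", i))
    }
  }
  link <- list()
  for (s in cm$shared) {
    for (k in names(cm$ex_map[[s]])) {
      exr <- cm$ex_map[[s]][[k]]
      if (is.na(exr)) next
      j <- info[[k]]$offset + match(exr, info[[k]]$rxn_ids)
      iu <- alloc[[paste0("r_up:", s, ":", k)]]
      ie <- alloc[[paste0("r_ex:", s, ":", k)]]
      # v_EX = r_export - r_uptake
      add_row(c(j, ie + 1, iu + 1), c(1, -1, 1), 0, 0,
              paste0("link:", s, ":", k))
      link[[paste0(s, ":", k)]] <- list(vj = j, member = k, shared = s)
    }
  }
  for (s in cm$shared) {
    row <- numeric(N)
    for (k in names(cm$ex_map[[s]])) {
      if (is.na(cm$ex_map[[s]][[k]])) next
      row[alloc[[paste0("r_ex:", s, ":", k)]] + 1] <- 1
      row[alloc[[paste0("r_up:", s, ":", k)]] + 1] <- -1
    }
    row[pool[[paste0("pool_in:", s)]] + 1] <- 1
    row[pool[[paste0("pool_out:", s)]] + 1] <- -1
    rows[[length(rows) + 1]] <- row
    rlb <- c(rlb, 0); rub <- c(rub, 0); rtag <- c(rtag, paste0("pool:", s))
  }
  list(vars = vars, lb = lb, ub = ub, N = N,
       A = do.call(rbind, rows), row_lb = rlb, row_ub = rub, row_tag = rtag,
       info = info, alloc = alloc, pool = pool, link = link)
}

objective_vector <- function(cm, sys, objective) {
  obj <- numeric(sys$N)
  for (t in seq_len(nrow(objective$terms))) {
    tm <- objective$terms[t, ]
    if (tm$type == "biomass") {
      ks <- if (is.na(tm$member)) names(cm$members) else tm$member
      for (k in ks) {
        w <- tm$weight
        if (!is.null(objective$weights) && k %in% names(objective$weights)) {
          w <- w * objective$weights[[k]]
        }
        obj[sys$info[[k]]$offset + sys$info[[k]]$bio] <-
          obj[sys$info[[k]]$offset + sys$info[[k]]$bio] + w
      }
    } else if (tm$type %in% c("pool_out", "pool_in")) {
      key <- paste0(tm$type, ":", tm$id)
      if (!key %in% names(sys$pool)) {
        stop_fluxcom("objective references unknown pool metabolite: ", tm$id)
      }
      obj[sys$pool[[key]] + 1] <- obj[sys$pool[[key]] + 1] + tm$weight
    } else if (tm$type == "exchange") {
      ik <- sys$info[[tm$member]]
      j <- match(tm$id, ik$rxn_ids)
      if (is.na(j)) stop_fluxcom("objective references unknown reaction ",
                                 tm$id, " of member ", tm$member)
      obj[ik$offset + j] <- obj[ik$offset + j] + tm$weight
    } else {
      stop_fluxcom("unknown objective term type: ", tm$type)
    }
  }
  obj
}

# Append KKT blocks (duals, stationarity, complementary slackness) for each
# member's inner problem to the primal system. Returns the extended system
# plus the integrality vector.
kkt_system <- function(cm, sys, bigM_dual = FLUX_BOUND) {
  A <- sys$A; rlb <- sys$row_lb; rub <- sys$row_ub; rtag <- sys$row_tag
  lb <- sys$lb; ub <- sys$ub; vars <- sys$vars
  N0 <- sys$N
  # new variables appended after the primal block
  newv <- list() # name -> list(lb, ub, int)
  addv <- function(name, lo, hi, int = FALSE) {
    newv[[name]] <<- list(lb = lo, ub = hi, int = int)
    N0 + length(newv)
  }
  extra_rows <- list()
  addr <- function(idx, coef, lo, hi, tag) {
    extra_rows[[length(extra_rows) + 1]] <<-
      list(idx = idx, coef = coef, lo = lo, hi = hi, tag = tag)
  }
  for (k in names(cm$members)) {
    ik <- sys$info[[k]]
    m_k <- nrow(ik$S); n_k <- ik$n
    lam <- vapply(seq_len(m_k), function(i)
      addv(paste0("lam:", k, ":", i), -Inf, Inf), 0)
    links_k <- Filter(function(l) l$member == k, sys$link)
    pi_idx <- stats::setNames(
      vapply(names(links_k), function(nm)
        addv(paste0("pi:", k, ":", links_k[[nm]]$shared), -Inf, Inf), 0),
      vapply(links_k, function(l) l$shared, ""))
    mup <- vapply(seq_len(n_k), function(j)
      addv(paste0("mup:", k, ":", j), 0, bigM_dual), 0)
    mun <- vapply(seq_len(n_k), function(j)
      addv(paste0("mun:", k, ":", j), 0, bigM_dual), 0)
    for (j in seq_len(n_k)) {
      # stationarity: c_j - (S' lam)_j - (E' pi)_j - mup_j + mun_j = 0
      cj <- as.numeric(j == ik$bio)
      nzi <- which(ik$S[, j] != 0)
      idx <- c(lam[nzi], mup[j], mun[j])
      coef <- c(-ik$S[nzi, j], -1, 1)
      exr_shared <- NULL
      for (l in sys$link) {
        if (l$member == k && l$vj == ik$offset + j) exr_shared <- l$shared
      }
      if (!is.null(exr_shared)) {
        idx <- c(idx, pi_idx[[exr_shared]])
        coef <- c(coef, -1)
      }
      addr(idx, coef, -cj, -cj, paste0("stat:", k, ":", j))
      # complementary slackness (skip fixed variables)
      if (ik$ubs[j] - ik$lbs[j] > 1e-12) {
        gap <- ik$ubs[j] - ik$lbs[j]
        zp <- addv(paste0("zp:", k, ":", j), 0, 1, int = TRUE)
        zn <- addv(paste0("zn:", k, ":", j), 0, 1, int = TRUE)
        vj <- ik$offset + j
        addr(c(mup[j], zp), c(1, -bigM_dual), -Inf, 0, "cs")  # mup <= M zp
        # ub_j - v_j <= gap (1 - zp)   <=>   v_j - gap zp >= ub_j - gap
        addr(c(vj, zp), c(1, -gap), ik$ubs[j] - gap, Inf, "cs")
        addr(c(mun[j], zn), c(1, -bigM_dual), -Inf, 0, "cs")  # mun <= M zn
        # v_j - lb_j <= gap (1 - zn)   <=>   v_j + gap zn <= lb_j + gap
        addr(c(vj, zn), c(1, gap), -Inf, ik$lbs[j] + gap, "cs")
      }
    }
  }
  nN <- N0 + length(newv)
  lb2 <- c(lb, vapply(newv, `[[`, 0, "lb"))
  ub2 <- c(ub, vapply(newv, `[[`, 0, "ub"))
  intg <- c(rep(0, N0), as.numeric(vapply(newv, `[[`, TRUE, "int")))
  vars2 <- c(vars, names(newv))
  A2 <- cbind(A, matrix(0, nrow(A), length(newv)))
  if (length(extra_rows) > 0) {
    ER <- matrix(0, length(extra_rows), nN)
    elo <- numeric(length(extra_rows)); ehi <- numeric(length(extra_rows))
    for (r in seq_along(extra_rows)) {
      er <- extra_rows[[r]]
      ER[r, er$idx] <- er$coef
      elo[r] <- er$lo; ehi[r] <- er$hi
    }
    A2 <- rbind(A2, ER)
    rlb <- c(rlb, elo); rub <- c(rub, ehi)
    rtag <- c(rtag, vapply(extra_rows, `[[`, "", "tag"))
  }
  list(vars = vars2, lb = lb2, ub = ub2, N = nN, A = A2,
       row_lb = rlb, row_ub = rub, row_tag = rtag, integrality = intg,
       info = sys$info, alloc = sys$alloc, pool = sys$pool, link = sys$link,
       n_primal = sys$N)
}

#' Solve the bilevel community problem
#'
#' @param cm a `community_model`.
#' @param objective a [community_objective()].
#' @param method `"kkt"` (single-level MILP reformulation enforcing inner
#'   optimality; default) or `"joint"` (one LP without inner optimality, for
#'   cross-checks and speed).
#' @param verify re-solve each member's inner LP with the allocations fixed
#'   and check the member's biomass is inner-optimal (default `TRUE`).
#' @param bigM_dual big-M bound on inner dual variables. If a dual presses
#'   against it the solution is flagged (`dual_bound_hit`).
#' @return a `community_solution`.
#' @export
solve_optcom <- function(cm, objective = community_objective("growth"),
                         method = c("kkt", "joint"), verify = TRUE,
                         bigM_dual = FLUX_BOUND) {
  method <- match.arg(method)
  sys <- community_system(cm)
  obj <- objective_vector(cm, sys, objective)
  if (method == "joint") {
    full <- sys
    intg <- NULL
    obj_full <- obj
  } else {
    full <- kkt_system(cm, sys, bigM_dual)
    intg <- full$integrality
    obj_full <- c(obj, numeric(full$N - sys$N))
  }
  res <- solve_lp(obj_full, full$A, full$row_lb, full$row_ub, full$lb,
                  full$ub, integrality = intg, sense = objective$sense)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective = objective,
                          method = method, objective_value = NA_real_),
                     class = "community_solution"))
  }
  x <- res$x
  member_biomass <- vapply(names(cm$members), function(k) {
    ik <- sys$info[[k]]; x[ik$offset + ik$bio]
  }, 0)
  fluxes <- lapply(names(cm$members), function(k) {
    ik <- sys$info[[k]]
    stats::setNames(x[ik$offset + seq_len(ik$n)], ik$rxn_ids)
  })
  names(fluxes) <- names(cm$members)
  pool <- do.call(rbind, lapply(cm$shared, function(s) {
    up <- 0; exv <- 0
    for (k in names(cm$ex_map[[s]])) {
      if (is.na(cm$ex_map[[s]][[k]])) next
      up <- up + x[sys$alloc[[paste0("r_up:", s, ":", k)]] + 1]
      exv <- exv + x[sys$alloc[[paste0("r_ex:", s, ":", k)]] + 1]
    }
    pin <- x[sys$pool[[paste0("pool_in:", s)]] + 1]
    pout <- x[sys$pool[[paste0("pool_out:", s)]] + 1]
    data.frame(metabolite = s, member_uptake = up, member_export = exv,
               pool_in = pin, pool_out = pout,
               residual = exv + pin - up - pout, stringsAsFactors = FALSE)
  }))
  transactions <- do.call(rbind, lapply(cm$shared, function(s) {
    do.call(rbind, lapply(names(cm$ex_map[[s]]), function(k) {
      if (is.na(cm$ex_map[[s]][[k]])) return(NULL)
      data.frame(metabolite = s, member = k,
                 r_uptake = x[sys$alloc[[paste0("r_up:", s, ":", k)]] + 1],
                 r_export = x[sys$alloc[[paste0("r_ex:", s, ":", k)]] + 1],
                 stringsAsFactors = FALSE)
    }))
  }))
  dual_bound_hit <- FALSE
  if (method == "kkt") {
    mu_idx <- grep("^mu[pn]:", full$vars)
    if (length(mu_idx) > 0) {
      dual_bound_hit <- any(x[mu_idx] > 0.99 * bigM_dual)
    }
  }
  sol <- structure(list(
    objective_value = res$objective, status = "optimal",
    member_biomass = member_biomass, fluxes = fluxes, pool = pool,
    transactions = transactions, method = method, objective = objective,
    dual_bound_hit = dual_bound_hit, inner_check = NULL),
    class = "community_solution")
  if (verify) sol$inner_check <- check_inner_optimality(cm, sol)
  sol
}

#' Post-hoc inner-optimality check
#'
#' Fixes each member's shared-metabolite exchange fluxes at the solution's
#' allocations and re-solves the member's own FBA problem; the member's
#' biomass in the community solution must equal that optimum.
#'
#' @param cm a `community_model`.
#' @param solution a `community_solution`.
#' @param tolerance comparison tolerance.
#' @return data.frame `member`, `biomass`, `inner_optimum`, `ok`.
#' @export
check_inner_optimality <- function(cm, solution, tolerance = 1e-5) {
  out <- lapply(names(cm$members), function(k) {
    mdl <- cm$members[[k]]
    for (s in cm$shared) {
      exr <- cm$ex_map[[s]][k]
      if (is.na(exr) || !nzchar(exr)) next
      tr <- solution$transactions
      v <- tr$r_export[tr$metabolite == s & tr$member == k] -
        tr$r_uptake[tr$metabolite == s & tr$member == k]
      mdl$reactions[[exr]]$lb <- v - 1e-9
      mdl$reactions[[exr]]$ub <- v + 1e-9
      mdl$reactions[[exr]]$reversible <- mdl$reactions[[exr]]$lb < 0
    }
    opt <- fba(mdl)
    data.frame(member = k, biomass = solution$member_biomass[[k]],
               inner_optimum = opt$objective_value,
               ok = opt$status == "optimal" &&
                 abs(opt$objective_value - solution$member_biomass[[k]]) <=
                   tolerance * (1 + abs(opt$objective_value)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.community_solution <- function(x, ...) {
  cat("<community_solution> status ", x$status, ", ", x$objective$name,
      " = ", format(x$objective_value), "\n", sep = "")
  if (x$status == "optimal") {
    cat("member biomass:",
        paste(names(x$member_biomass),
              format(round(x$member_biomass, 4)), sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Flux variability at a fixed community optimum
#'
#' Pins the outer objective at (a fraction of) its optimum and reports
#' min/max for each queried quantity. With `method = "kkt"` inner optimality
#' is enforced in every scan; `"joint"` scans the relaxed pooled LP.
#'
#' @param cm a `community_model`.
#' @param objective a [community_objective()].
#' @param queries character keys: `"<member>:<reaction>"`,
#'   `"r_up:<met>:<member>"`, `"r_ex:<met>:<member>"`, `"pool_in:<met>"`,
#'   `"pool_out:<met>"`. Default: all allocation and pool variables.
#' @param opt_value outer optimum to pin; solved if `NULL`.
#' @param fraction pin as equality if 1 (within a 1e-6 band), else require
#'   `>= fraction * optimum` (maximisation; reversed for minimisation).
#' @param method `"kkt"` or `"joint"`.
#' @return an `fva_result` whose `$ranges$reaction` holds the query keys.
#' @export
community_fva <- function(cm, objective = community_objective("growth"),
                          queries = NULL, opt_value = NULL, fraction = 1,
                          method = c("kkt", "joint")) {
  method <- match.arg(method)
  sys <- community_system(cm)
  obj <- objective_vector(cm, sys, objective)
  if (is.null(opt_value)) {
    sol <- solve_optcom(cm, objective, method = method, verify = FALSE)
    if (sol$status != "optimal") {
      stop_fluxcom("community optimum unavailable: status ", sol$status)
    }
    opt_value <- sol$objective_value
  }
  full <- if (method == "joint") sys else kkt_system(cm, sys)
  intg <- if (method == "joint") NULL else full$integrality
  obj_full <- c(obj, numeric(full$N - sys$N))
  band <- 1e-6 * (1 + abs(opt_value))
  if (fraction >= 1) {
    lo <- opt_value - band; hi <- opt_value + band
  } else if (objective$sense == "max") {
    lo <- fraction * opt_value; hi <- Inf
  } else {
    lo <- -Inf; hi <- fraction * opt_value
  }
  A <- rbind(full$A, obj_full)
  row_lb <- c(full$row_lb, lo); row_ub <- c(full$row_ub, hi)
  ctx <- lp_context(A, row_lb, row_ub, full$lb, full$ub, integrality = intg)
  queries <- queries %||% c(names(sys$alloc), names(sys$pool))
  out <- data.frame(reaction = queries, min = NA_real_, max = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (q in seq_along(queries)) {
    key <- queries[[q]]
    vec <- numeric(full$N)
    if (key %in% names(sys$alloc)) {
      vec[sys$alloc[[key]] + 1] <- 1
    } else if (key %in% names(sys$pool)) {
      vec[sys$pool[[key]] + 1] <- 1
    } else {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !parts[[1]] %in% names(sys$info)) {
        stop_fluxcom("unknown community fva query: ", key)
      }
      ik <- sys$info[[parts[[1]]]]
      j <- match(parts[[2]], ik$rxn_ids)
      if (is.na(j)) stop_fluxcom("unknown reaction in query: ", key)
      vec[ik$offset + j] <- 1
    }
    lohi <- lapply(c("min", "max"), function(sn) solve_in_context(ctx, vec, sn))
    if (lohi[[1]]$status != "optimal" || lohi[[2]]$status != "optimal") {
      out$status[[q]] <- paste0("min:", lohi[[1]]$status,
                                ",max:", lohi[[2]]$status)
    }
    out$min[[q]] <- lohi[[1]]$objective
    out$max[[q]] <- lohi[[2]]$objective
  }
  swap <- !is.na(out$min) & !is.na(out$max) & out$min > out$max
  if (any(swap)) {
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid; out$max[swap] <- mid
  }
  structure(list(ranges = out,
                 config = list(objective = objective$name,
                               opt_value = opt_value, fraction = fraction,
                               method = method)),
            class = "fva_result")
}

#' Shared-metabolite transaction table with flux ranges
#'
#' Min-max ranges of every member's pool uptake and export allocation at the
#' community optimum, mirroring the min/max presentation of community flux
#' maps.
#'
#' @inheritParams community_fva
#' @return data.frame `metabolite`, `member`, `uptake_min`, `uptake_max`,
#'   `export_min`, `export_max`.
#' @export
transaction_table <- function(cm, objective = community_objective("growth"),
                              method = c("kkt", "joint")) {
  method <- match.arg(method)
  res <- community_fva(cm, objective, method = method)
  rg <- res$ranges
  keys <- rg$reaction[grepl("^r_(up|ex):", rg$reaction)]
  parts <- strsplit(keys, ":", fixed = TRUE)
  tab <- data.frame(
    kind = vapply(parts, `[[`, "", 1),
    metabolite = vapply(parts, `[[`, "", 2),
    member = vapply(parts, `[[`, "", 3),
    min = rg$min[match(keys, rg$reaction)],
    max = rg$max[match(keys, rg$reaction)], stringsAsFactors = FALSE)
  ups <- tab[tab$kind == "r_up", ]
  exs <- tab[tab$kind == "r_ex", ]
  out <- merge(ups[, c("metabolite", "member", "min", "max")],
               exs[, c("metabolite", "member", "min", "max")],
               by = c("metabolite", "member"),
               suffixes = c("_uptake", "_export"))
  names(out) <- c("metabolite", "member", "uptake_min", "uptake_max",
                  "export_min", "export_max")
  out[order(out$metabolite, out$member), ]
}
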