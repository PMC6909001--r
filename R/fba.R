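# Flux balance analysis and flux variability analysis for a single model.
#
# FBA:  max (or min) v_obj  s.t.  S v = 0,  LB <= v <= UB.
# FVA:  per-reaction min and max of v_j over the same polytope, optionally
#       with the objective flux pinned to (a fraction of) a threshold value.

#' Flux balance analysis
#'
#' @param model a `metabolic_model`.
#' @param objective objective reaction id (default: the biomass reaction).
#' @param sense `"max"` or `"min"`.
#' @return an `fba_result`: `objective_value`, named `fluxes`, `status`.
#'   Infeasibility and unboundedness are reported in `status`, never as
#'   silent zeros.
#' @export
fba <- function(model, objective = model$biomass_reaction_id,
                sense = c("max", "min")) {
  sense <- match.arg(sense)
  S <- stoich_matrix(model)
  rxn_ids <- colnames(S)
  if (!objective %in% rxn_ids) {
    stop_fluxcom("objective reaction not in model: ", objective)
  }
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  obj <- as.numeric(rxn_ids == objective)
  res <- solve_lp(obj, S, rep(0, nrow(S)), rep(0, nrow(S)), lb, ub,
                  sense = sense)
  fluxes <- if (res$status == "optimal") stats::setNames(res$x, rxn_ids) else
    stats::setNames(rep(NA_real_, length(rxn_ids)), rxn_ids)
  structure(list(objective_value = res$objective, fluxes = fluxes,
                 status = res$status, objective_reaction = objective,
                 sense = sense),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> ", x$sense, " ", x$objective_reaction, ": status ",
      x$status, ", objective ", format(x$objective_value), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis configuration
#'
#' @param objective optional reaction id to constrain while scanning.
#' @param value threshold value for the constrained objective; if `NULL` it is
#'   computed by [fba()] at call time.
#' @param fraction fraction f in `[0,1]`; `f = 1` (default) pins the objective
#'   to the threshold as an equality, `f < 1` requires `>= f * value`.
#' @param tolerance reporting tolerance.
#' @return an `fva_config`.
#' @export
fva_config <- function(objective = NULL, value = NULL, fraction = 1,
                       tolerance = 1e-6) {
  if (fraction < 0 || fraction > 1) stop_fluxcom("fraction must be in [0,1]")
  structure(list(objective = objective, value = value, fraction = fraction,
                 tolerance = tolerance), class = "fva_config")
}

#' Flux variability analysis
#'
#' @param model a `metabolic_model`.
#' @param reactions reaction ids to scan (default: all).
#' @param config an [fva_config()].
#' @return an `fva_result` with `$ranges`: data.frame `reaction`, `min`,
#'   `max`, `status`. Per-reaction LP failures are recorded and the scan
#'   continues.
#' @export
fva <- function(model, reactions = NULL, config = fva_config()) {
  S <- stoich_matrix(model)
  rxn_ids <- colnames(S)
  reactions <- reactions %||% rxn_ids
  stopifnot(all(reactions %in% rxn_ids))
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  A <- S
  row_lb <- rep(0, nrow(S))
  row_ub <- rep(0, nrow(S))
  if (!is.null(config$objective)) {
    if (!config$objective %in% rxn_ids) {
      stop_fluxcom("fva objective not in model: ", config$objective)
    }
    value <- config$value
    if (is.null(value)) {
      opt <- fba(model, config$objective, "max")
      if (opt$status != "optimal") {
        stop_fluxcom("cannot fix objective: FBA status ", opt$status)
      }
      value <- opt$objective_value
    }
    row <- as.numeric(rxn_ids == config$objective)
    A <- rbind(A, row)
    if (config$fraction >= 1) {
      row_lb <- c(row_lb, value); row_ub <- c(row_ub, value)
    } else {
      row_lb <- c(row_lb, config$fraction * value); row_ub <- c(row_ub, Inf)
    }
  }
  ctx <- lp_context(A, row_lb, row_ub, lb, ub)
  out <- data.frame(reaction = reactions, min = NA_real_, max = NA_real_,
                    status = "optimal", stringsAsFactors = FALSE)
  for (i in seq_along(reactions)) {
    obj <- as.numeric(rxn_ids == reactions[[i]])
    lo <- solve_in_context(ctx, obj, "min")
    hi <- solve_in_context(ctx, obj, "max")
    if (lo$status != "optimal" || hi$status != "optimal") {
      out$status[[i]] <- paste0("min:", lo$status, ",max:", hi$status)
    }
    out$min[[i]] <- lo$objective
    out$max[[i]] <- hi$objective
  }
  swap <- !is.na(out$min) & !is.na(out$max) & out$min > out$max
  if (any(swap)) { # solver round-off on degenerate point ranges
    mid <- (out$min[swap] + out$max[swap]) / 2
    out$min[swap] <- mid; out$max[swap] <- mid
  }
  structure(list(ranges = out, config = config), class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat("<fva_result> ", nrow(x$ranges), " reactions\n", sep = "")
  print(utils::head(x$ranges, 10))
  invisible(x)
}

# named lookup helpers
fva_min <- function(res, id) res$ranges$min[match(id, res$ranges$reaction)]
fva_max <- function(res, id) res$ranges$max[match(id, res$ranges$reaction)]
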