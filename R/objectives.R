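# Community behaviour under alternative community-level objectives, and
# robustness statistics of the resulting flux ranges.
#
# The five canonical community fitness criteria are: (i) growth, (ii) SCFA
# production, (iii) feed utilisation, (iv) methane + CO2 release
# (minimised), and (v) small-sugar production. Which exchange fluxes count
# as SCFAs, feed, gases or sugars is a configuration: the generator emits
# defaults alongside its models.

#' Build the five standard community objective specifications
#'
#' @param scfa pool metabolite base ids counted as short-chain fatty acids.
#' @param feed pool metabolite base ids counted as plant feed (uptakes).
#' @param gases pool metabolite base ids for greenhouse-gas release
#'   (default `c("ch4", "co2")`); this objective is minimised.
#' @param sugars pool metabolite base ids for small-sugar production.
#' @param sugar_exchanges optional data.frame `member`, `reaction` of
#'   member-local sugar export exchanges (for sugars that are not pooled).
#' @return named list of five [community_objective()]s.
#' @export
standard_objectives <- function(scfa, feed, gases = c("ch4", "co2"),
                                sugars = character(0),
                                sugar_exchanges = NULL) {
  pool_terms <- function(type, mets) {
    if (length(mets) == 0) {
      return(data.frame(type = character(0), member = character(0),
                        id = character(0), weight = numeric(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(type = type, member = NA_character_, id = mets, weight = 1,
               stringsAsFactors = FALSE)
  }
  sugar_terms <- pool_terms("pool_out", sugars)
  if (!is.null(sugar_exchanges) && nrow(sugar_exchanges) > 0) {
    sugar_terms <- rbind(sugar_terms,
                         data.frame(type = "exchange",
                                    member = sugar_exchanges$member,
                                    id = sugar_exchanges$reaction, weight = 1,
                                    stringsAsFactors = FALSE))
  }
  list(
    growth = community_objective("growth", "max"),
    scfa_production = community_objective("scfa_production", "max",
                                          pool_terms("pool_out", scfa)),
    feed_utilization = community_objective("feed_utilization", "max",
                                           pool_terms("pool_in", feed)),
    methane_co2_release = community_objective("methane_co2_release", "min",
                                              pool_terms("pool_out", gases)),
    sugar_production = community_objective("sugar_production", "max",
                                           sugar_terms)
  )
}

#' Solve and scan the community under a suite of objectives
#'
#' For each objective: [solve_optcom()] followed by [community_fva()] at the
#' fixed optimum over a common query set. Per-objective failures are
#' recorded and the suite continues. All runs share the community's one diet
#' so differences are attributable to the objective alone.
#'
#' @param cm a `community_model`.
#' @param specs list of [community_objective()]s (default the unqualified
#'   growth objective only).
#' @param queries query keys for [community_fva()]; default: every member
#'   reaction plus all allocation and pool variables.
#' @param method `"kkt"` or `"joint"`.
#' @return an `objective_suite_result`: per spec, `objective`, `solution`,
#'   `fva` (or `error`).
#' @export
run_objective_suite <- function(cm, specs = list(community_objective("growth")),
                                queries = NULL, method = c("kkt", "joint")) {
  method <- match.arg(method)
  if (is.null(queries)) {
    queries <- unlist(lapply(names(cm$members), function(k)
      paste0(k, ":", names(cm$members[[k]]$reactions))))
    sys <- community_system(cm)
    queries <- c(queries, names(sys$alloc), names(sys$pool))
  }
  runs <- lapply(specs, function(spec) {
    tryCatch({
      sol <- solve_optcom(cm, spec, method = method, verify = FALSE)
      if (sol$status != "optimal") {
        return(list(objective = spec, error = paste("status", sol$status)))
      }
      fv <- community_fva(cm, spec, queries = queries,
                          opt_value = sol$objective_value, method = method)
      list(objective = spec, solution = sol, fva = fv)
    }, error = function(e) list(objective = spec,
                                error = conditionMessage(e)))
  })
  names(runs) <- vapply(specs, `[[`, "", "name")
  structure(list(runs = runs, queries = queries, method = method),
            class = "objective_suite_result")
}

#' Robustness statistics of flux ranges across objectives
#'
#' Per reaction (query key), the standard deviation of the minimum flux and
#' of the maximum flux across the runs. The population SD (n in the
#' denominator) is the default: the objectives studied are the whole set of
#' conditions, not a sample.
#'
#' @param results list of `fva_result`s over identical query sets, or an
#'   `objective_suite_result`.
#' @param members member ids used to aggregate per-member fractions
#'   (default: inferred from `"member:"` key prefixes).
#' @param sample use the sample SD (n-1) instead of the population SD.
#' @param tol SD below which a reaction counts as unchanged.
#' @return a `robustness_report`: `$table` (key, member, sd_min, sd_max,
#'   nonzero), `$summary` (per-member fraction of reactions with non-zero
#'   SD), `$mean_sd`, `$sd_range` over the pooled min/max SDs.
#' @export
robustness_stats <- function(results, members = NULL, sample = FALSE,
                             tol = 1e-9) {
  if (inherits(results, "objective_suite_result")) {
    results <- lapply(Filter(function(r) is.null(r$error), results$runs),
                      `[[`, "fva")
  }
  if (length(results) < 2) stop_fluxcom("need at least two result sets")
  keys <- results[[1]]$ranges$reaction
  for (r in results[-1]) {
    if (!identical(sort(r$ranges$reaction), sort(keys))) {
      stop_fluxcom("mismatched reaction sets across results")
    }
  }
  sdfun <- if (sample) function(x) stats::sd(x) else sd_pop
  mins <- vapply(results, function(r)
    r$ranges$min[match(keys, r$ranges$reaction)], numeric(length(keys)))
  maxs <- vapply(results, function(r)
    r$ranges$max[match(keys, r$ranges$reaction)], numeric(length(keys)))
  sd_min <- apply(mins, 1, sdfun)
  sd_max <- apply(maxs, 1, sdfun)
  member_of <- function(key) {
    p <- strsplit(key, ":", fixed = TRUE)[[1]][[1]]
    if (!is.null(members)) {
      if (p %in% members) p else "community"
    } else if (p %in% c("r_up", "r_ex", "pool_in", "pool_out")) {
      "community"
    } else p
  }
  tab <- data.frame(key = keys,
                    member = vapply(keys, member_of, ""),
                    sd_min = sd_min, sd_max = sd_max,
                    nonzero = sd_min > tol | sd_max > tol,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  frac <- tapply(tab$nonzero, tab$member, mean)
  pooled <- c(tab$sd_min, tab$sd_max)
  structure(list(table = tab,
                 summary = data.frame(member = names(frac),
                                      fraction_nonzero = as.numeric(frac),
                                      stringsAsFactors = FALSE),
                 mean_sd = mean(pooled), sd_range = range(pooled),
                 sample = sample),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report> ", nrow(x$table), " quantities; mean SD ",
      format(x$mean_sd), ", range [", format(x$sd_range[1]), ", ",
      format(x$sd_range[2]), "]\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Gaussian-kernel density of SD values
#'
#' The density-plot companion of [robustness_stats()]: a Gaussian smoothing
#' kernel whose bandwidth defaults to Silverman's rule of thumb.
#'
#' @param sds numeric vector (non-empty) of standard deviations.
#' @param bandwidth numeric bandwidth; `NULL` for Silverman's rule.
#' @param n_grid number of grid points.
#' @return data.frame `x`, `density`; the bandwidth used is in
#'   `attr(, "bandwidth")`. The trapezoid integral over the grid is 1 within
#'   1e-3.
#' @export
density_summary <- function(sds, bandwidth = NULL, n_grid = 512) {
  if (length(sds) == 0) stop_fluxcom("sds must be non-empty")
  d <- stats::density(sds, bw = bandwidth %||% "nrd0", kernel = "gaussian",
                      n = n_grid, cut = 4)
  out <- data.frame(x = d$x, density = d$y)
  attr(out, "bandwidth") <- d$bw
  out
}
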