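# Low-level LP/MILP interface.
#
# All optimisation problems in the package are expressed in one canonical
# form and handed to the HiGHS solver (via scipy.optimize.milp through
# reticulate):
#
#   max/min  c'x
#   s.t.     row_lb <= A x <= row_ub
#            lb <= x <= ub,   x_j integer where integrality[j] == 1

scipy_optimize <- function() {
  if (is.null(.fluxcom$scipy_opt)) {
    if (!reticulate::py_available(initialize = TRUE)) {
      stop_fluxcom("no python interpreter available for the HiGHS backend")
    }
    .fluxcom$scipy_opt <- reticulate::import("scipy.optimize", delay_load = FALSE)
    .fluxcom$np <- reticulate::import("numpy", delay_load = FALSE)
    wr <- reticulate::import("warnings", delay_load = FALSE)
    wr$filterwarnings("ignore", message = "Unrecognized options")
  }
  .fluxcom$scipy_opt
}

# HiGHS tolerances, fixed for reproducibility: 1e-9 feasibility (primal,
# dual, and integrality), exact MIP gap. Chosen so that big-M constructions
# (M = 1000) cannot leak through the integrality tolerance at the 1e-3
# production threshold.
highs_options <- function() {
  reticulate::dict(mip_rel_gap = 0,
                   mip_feasibility_tolerance = 1e-9,
                   primal_feasibility_tolerance = 1e-9,
                   dual_feasibility_tolerance = 1e-9)
}

#' Solve a linear or mixed-integer linear program
#'
#' Canonical interface to the HiGHS solver. Used by every optimisation in the
#' package; not normally called directly by users.
#'
#' @param obj objective coefficient vector.
#' @param A constraint matrix (dense), possibly with zero rows.
#' @param row_lb,row_ub row activity bounds (use `-Inf`/`Inf` for one-sided).
#' @param lb,ub variable bounds.
#' @param integrality 0/1 vector (1 = integer variable); `NULL` for a pure LP.
#' @param sense `"max"` or `"min"`.
#' @return list with `status` (one of `"optimal"`, `"infeasible"`,
#'   `"unbounded"`, `"error"`), `objective`, and the solution vector `x`.
#' @export
solve_lp <- function(obj, A, row_lb, row_ub, lb, ub,
                     integrality = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  so <- scipy_optimize()
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  cvec <- if (sense == "max") -obj else obj
  cons <- list()
  if (!is.null(A) && nrow(A) > 0) {
    cons <- list(so$LinearConstraint(A, row_lb, row_ub))
  }
  intg <- if (is.null(integrality)) .fluxcom$np$zeros(as.integer(n)) else
    as.numeric(integrality)
  res <- so$milp(cvec,
                 constraints = cons,
                 integrality = intg,
                 bounds = so$Bounds(as.numeric(lb), as.numeric(ub)),
                 options = highs_options())
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible", "3" = "unbounded",
                   "error")
  x <- tryCatch(as.numeric(res$x), error = function(e) rep(NA_real_, n))
  if (is.null(x) || length(x) != n) x <- rep(NA_real_, n)
  objective <- if (status == "optimal") {
    if (sense == "max") -res$fun else res$fun
  } else NA_real_
  list(status = status, objective = objective, x = x)
}

# A reusable LP context: the constraint set is built once, objectives vary.
# This is what makes FVA (2 solves per reaction) cheap.
lp_context <- function(A, row_lb, row_ub, lb, ub, integrality = NULL) {
  so <- scipy_optimize()
  n <- length(lb)
  cons <- list()
  if (!is.null(A) && nrow(A) > 0) {
    cons <- list(so$LinearConstraint(A, row_lb, row_ub))
  }
  list(so = so, cons = cons, n = n,
       bounds = so$Bounds(as.numeric(lb), as.numeric(ub)),
       integrality = if (is.null(integrality)) .fluxcom$np$zeros(as.integer(n))
                     else as.numeric(integrality))
}

solve_in_context <- function(ctx, obj, sense = c("max", "min")) {
  sense <- match.arg(sense)
  cvec <- if (sense == "max") -obj else obj
  res <- ctx$so$milp(cvec, constraints = ctx$cons,
                     integrality = ctx$integrality, bounds = ctx$bounds,
                     options = highs_options())
  status <- switch(as.character(res$status),
                   "0" = "optimal", "2" = "infeasible", "3" = "unbounded",
                   "error")
  x <- tryCatch(as.numeric(res$x), error = function(e) rep(NA_real_, ctx$n))
  if (is.null(x) || length(x) != ctx$n) x <- rep(NA_real_, ctx$n)
  objective <- if (status == "optimal") {
    if (sense == "max") -res$fun else res$fun
  } else NA_real_
  list(status = status, objective = objective, x = x)
}
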