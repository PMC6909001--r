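# Shared constants and small helpers.

#' Default flux bound (mmol/gDCW/hr)
#'
#' One constant serves as the default reversible bound magnitude and as the
#' big-M value in all mixed-integer formulations.
#' @export
FLUX_BOUND <- 1000

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_fluxcom <- function(..., class = "fluxcom_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Split a suffixed metabolite id into base id and compartment
#'
#' Metabolite ids carry their compartment as a suffix, e.g. `"glc[c]"`,
#' `"ac[e]"`, `"ac[u]"`.
#' @param id character vector of metabolite ids.
#' @return data.frame with columns `base` and `compartment`.
#' @export
split_met_id <- function(id) {
  m <- regmatches(id, regexec("^(.*)\\[([a-z])\\]$", id))
  base <- vapply(m, function(x) if (length(x) == 3) x[2] else NA_character_, "")
  comp <- vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_, "")
  data.frame(base = base, compartment = comp, stringsAsFactors = FALSE)
}

met_base <- function(id) split_met_id(id)$base
met_compartment <- function(id) split_met_id(id)$compartment

#' Parse a Hill-style elemental formula
#'
#' @param formula a formula string such as `"C6H12O6"`. `NA` or `""` denote
#'   an unknown formula.
#' @return named integer vector of element counts, or `NULL` if unknown.
#' @examples
#' parse_formula("C6H12O6")
#' @export
parse_formula <- function(formula) {
  if (is.null(formula) || length(formula) == 0 || is.na(formula) ||
      !nzchar(formula)) {
    return(NULL)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop_fluxcom("cannot parse formula: ", formula)
  }
  counts <- integer(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

# population standard deviation (n in the denominator)
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
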