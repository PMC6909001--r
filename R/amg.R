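# Viral auxiliary metabolic genes (AMGs): augmenting a host model with
# phage-encoded reactions and quantifying the resulting flux-space shifts.
#
# AMG reaction lists are an input contract: identifying them (alignment of
# viral proteomes, e-value filtering) happens upstream and only the e-value
# is carried along as metadata.

AMG_EVALUE_CUTOFF <- 1e-34

#' Create an AMG reaction set
#'
#' @param member host member id.
#' @param reactions list of [reaction()] objects.
#' @param phage optional phage name(s).
#' @param evalue optional alignment e-value(s); when present each must fall
#'   below `1e-34` (the input-preparation contract).
#' @return an `amg_set`.
#' @export
amg_set <- function(member, reactions, phage = NA_character_,
                    evalue = NULL) {
  if (!is.null(evalue) && any(evalue >= AMG_EVALUE_CUTOFF)) {
    stop_fluxcom("AMG e-values must be < 1e-34; offending: ",
                 paste(format(evalue[evalue >= AMG_EVALUE_CUTOFF]),
                       collapse = ", "))
  }
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  structure(list(member = member, reactions = reactions, phage = phage,
                 evalue = evalue), class = "amg_set")
}

#' Augment a host model with an AMG reaction set
#'
#' Reactions duplicating an existing reaction (by id or by stoichiometry,
#' in either orientation) are skipped and logged in `attr(, "skipped")`.
#' Referenced metabolites absent from the model are auto-created from their
#' compartment-suffixed ids (formula unknown).
#'
#' @param model host `metabolic_model` (its id must equal `amg$member`).
#' @param amg an `amg_set`.
#' @return the augmented, re-validated model.
#' @export
apply_amg <- function(model, amg) {
  if (!identical(amg$member, model$id)) {
    stop_fluxcom("AMG set targets member ", amg$member, ", not ", model$id)
  }
  skipped <- character(0)
  keys <- vapply(model$reactions, function(r) stoich_key(r$stoichiometry), "")
  rkeys <- vapply(model$reactions, function(r) stoich_key(-r$stoichiometry), "")
  for (r in amg$reactions) {
    if (r$id %in% names(model$reactions) ||
        stoich_key(r$stoichiometry) %in% c(keys, rkeys)) {
      skipped <- c(skipped, r$id)
      next
    }
    model <- add_reactions(model, list(r))
    keys <- c(keys, stoich_key(r$stoichiometry))
    rkeys <- c(rkeys, stoich_key(-r$stoichiometry))
  }
  validate_model(model)
  attr(model, "skipped") <- skipped
  model
}

#' Flux-range shifts between a pre- and post-augmentation model
#'
#' Compares FVA results computed for both models under the same objective
#' contexts (typically the five community objectives). The reported range is
#' the envelope over contexts (elementwise min of minima, max of maxima). A
#' reaction is "widened" when its post envelope contains the pre envelope
#' with at least one strictly wider side; since augmentation only enlarges
#' the flux polytope, no reaction can narrow. Significance follows the
#' standard-deviation rule: SD of the minimum or of the maximum flux across
#' the context simulations above `sd_threshold`; with a single context an
#' absolute-delta rule (`delta_threshold`) is used instead.
#'
#' @param pre,post lists of `fva_result`s (equal length, same contexts),
#'   for the pre- and post-augmentation model respectively.
#' @param sd_threshold SD significance cutoff (default 1).
#' @param delta_threshold absolute-delta cutoff for single-context runs.
#' @param tolerance strictness tolerance (default 1e-6).
#' @return a `flux_shift_report` with `$table`, `$widened`, `$significant`,
#'   `$added` (reactions only present post), and `$summary` counts.
#' @export
flux_shift <- function(pre, post, sd_threshold = 1, delta_threshold = 1e-3,
                       tolerance = 1e-6) {
  if (inherits(pre, "fva_result")) pre <- list(pre)
  if (inherits(post, "fva_result")) post <- list(post)
  if (length(pre) != length(post) || length(pre) == 0) {
    stop_fluxcom("pre and post must be non-empty lists of equal length")
  }
  keys_pre <- Reduce(union, lapply(pre, function(r) r$ranges$reaction))
  keys_post <- Reduce(union, lapply(post, function(r) r$ranges$reaction))
  added <- setdiff(keys_post, keys_pre)
  keys <- intersect(keys_pre, keys_post)
  col <- function(results, key, what) {
    vapply(results, function(r) {
      i <- match(key, r$ranges$reaction)
      if (is.na(i)) NA_real_ else r$ranges[[what]][[i]]
    }, 0)
  }
  rows <- lapply(keys, function(key) {
    pmin_v <- col(pre, key, "min"); pmax_v <- col(pre, key, "max")
    qmin_v <- col(post, key, "min"); qmax_v <- col(post, key, "max")
    pre_min <- min(pmin_v, na.rm = TRUE); pre_max <- max(pmax_v, na.rm = TRUE)
    post_min <- min(qmin_v, na.rm = TRUE); post_max <- max(qmax_v, na.rm = TRUE)
    widened <- post_min <= pre_min + tolerance &&
      post_max >= pre_max - tolerance &&
      (pre_min - post_min > tolerance || post_max - pre_max > tolerance)
    if (length(post) > 1) {
      sd_min <- sd_pop(qmin_v); sd_max <- sd_pop(qmax_v)
      significant <- isTRUE(sd_min > sd_threshold || sd_max > sd_threshold)
    } else {
      sd_min <- NA_real_; sd_max <- NA_real_
      significant <- isTRUE((pre_min - post_min) > delta_threshold ||
                              (post_max - pre_max) > delta_threshold)
    }
    data.frame(reaction = key, pre_min = pre_min, pre_max = pre_max,
               post_min = post_min, post_max = post_max, widened = widened,
               sd_min = sd_min, sd_max = sd_max, significant = significant,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(table = tab, widened = tab$reaction[tab$widened],
                 significant = tab$reaction[tab$significant], added = added,
                 summary = c(n_reactions = nrow(tab),
                             n_widened = sum(tab$widened),
                             n_significant = sum(tab$significant),
                             n_added = length(added))),
            class = "flux_shift_report")
}

#' @export
print.flux_shift_report <- function(x, ...) {
  cat("<flux_shift_report> ", x$summary[["n_widened"]], "/",
      x$summary[["n_reactions"]], " reactions widened, ",
      x$summary[["n_significant"]], " significant, ",
      x$summary[["n_added"]], " added\n", sep = "")
  invisible(x)
}
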