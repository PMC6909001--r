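# Gap-fill-driven discovery of inter-species metabolite exchanges.
#
# Every gap-fill candidate is routed through a fixed sequence of checks
# (cheapest first): transport plausibility against a transporter-evidence
# knowledgebase, taxonomic likelihood for non-transport fills, and a
# thermodynamically-infeasible-cycle check by tentative addition. The
# outcome is always a classification, never an error:
#   * de_novo_interaction - an uptake transporter with evidence of at least
#     ortholog level whose substrate another member can export (> eps by FVA);
#   * accepted_fill       - a plausible network repair without a cross-member
#     pairing;
#   * rejected            - failed a gate (reason recorded in the evidence
#     trail).

EVIDENCE_LEVELS <- c(none = 0, ortholog = 1, experimental = 2)

interaction_record <- function(metabolite, donor, receiver, transport_reaction,
                               evidence, status, phase = "pre_AMG",
                               source = NA_character_, ambiguous = FALSE) {
  structure(list(metabolite = metabolite, donor = donor, receiver = receiver,
                 transport_reaction = transport_reaction, evidence = evidence,
                 status = status, phase = phase, source = source,
                 ambiguous = ambiguous),
            class = "interaction_record")
}

#' Turn interaction records into a table
#' @param records list of `interaction_record`s.
#' @return data.frame, one row per record.
#' @export
interaction_table <- function(records) {
  if (length(records) == 0) {
    return(data.frame(metabolite = character(0), donor = character(0),
                      receiver = character(0),
                      transport_reaction = character(0), status = character(0),
                      phase = character(0), source = character(0),
                      ambiguous = logical(0), evidence = character(0)))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(metabolite = r$metabolite, donor = r$donor %||% NA_character_,
               receiver = r$receiver,
               transport_reaction = r$transport_reaction %||% NA_character_,
               status = r$status, phase = r$phase, source = r$source,
               ambiguous = r$ambiguous,
               evidence = paste(names(r$evidence), unlist(r$evidence),
                                sep = "=", collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

# does the candidate contain a transporter moving the target's base
# metabolite between [e] and [c]? Returns its id or NA.
candidate_transporter <- function(candidate, db, base) {
  for (rid in candidate$reactions) {
    r <- db$entries[[rid]]
    if (is.null(r) || !r$is_transport) next
    sp <- split_met_id(names(r$stoichiometry))
    if (base %in% sp$base[sp$compartment == "c"] &&
        base %in% sp$base[sp$compartment == "e"]) {
      return(rid)
    }
  }
  NA_character_
}

# taxonomic likelihood: best (lowest) rank of any candidate taxon in the
# member's ranked relatedness list.
taxonomy_rank <- function(taxa, member_id, tax) {
  ranked <- tax$ranks[[member_id]]
  if (is.null(ranked) || length(taxa) == 0) return(Inf)
  hits <- match(taxa, ranked)
  if (all(is.na(hits))) Inf else min(hits, na.rm = TRUE)
}

# max standalone export rate of `base` by `model` (NA if no exchange)
max_export <- function(model, base) {
  exr <- find_exchange(model, base)
  if (is.na(exr)) return(NA_real_)
  res <- fba(model, exr, "max")
  if (res$status != "optimal") return(NA_real_)
  res$objective_value
}

#' Classify one gap-fill candidate
#'
#' @param candidate a `gapfill_candidate`.
#' @param member the target member's `metabolic_model`.
#' @param others named list of the other members' models.
#' @param kb a `transporter_kb`.
#' @param tax a `taxonomy_config`.
#' @param db the `reaction_db` the candidate came from.
#' @param eps minimum donor export rate for a cross-feed pairing.
#' @param baseline_unbounded precomputed [find_unbounded()] ids for `member`
#'   (computed on the fly if `NULL`).
#' @param phase record phase tag.
#' @return list of `interaction_record`s (one per qualifying donor for
#'   de novo interactions, else length 1).
#' @export
classify_candidate <- function(candidate, member, others, kb, tax, db,
                               eps = GAPFILL_EPS, baseline_unbounded = NULL,
                               phase = "pre_AMG") {
  base <- met_base(candidate$target)
  trail <- list()
  rec <- function(status, donor = NA_character_, transporter = NA_character_,
                  ambiguous = FALSE) {
    list(interaction_record(base, donor, member$id, transporter, trail,
                            status, phase, candidate$source, ambiguous))
  }
  transporter <- candidate_transporter(candidate, db, base)
  tic_ok <- function() {
    if (is.null(baseline_unbounded)) {
      baseline_unbounded <- find_unbounded(member)$unbounded
    }
    tent <- apply_candidate(member, candidate, db)
    new_ub <- setdiff(find_unbounded(tent)$unbounded, baseline_unbounded)
    trail$new_infeasible_cycles <<- length(new_ub)
    length(new_ub) == 0
  }
  if (!is.na(transporter)) {
    trail$check <- "transport"
    ev <- kb_evidence(kb, member$id, base)
    trail$transporter_evidence <- ev
    if (EVIDENCE_LEVELS[[ev]] < EVIDENCE_LEVELS[["ortholog"]]) {
      trail$reason <- "no transporter evidence"
      return(rec("rejected", transporter = transporter))
    }
    if (!tic_ok()) {
      trail$reason <- "creates thermodynamically infeasible cycle"
      return(rec("rejected", transporter = transporter))
    }
    if (candidate$direction == "production") {
      donors <- names(others)[vapply(others, function(o) {
        mx <- max_export(o, base)
        !is.na(mx) && mx > eps
      }, TRUE)]
      trail$donors <- paste(donors, collapse = ",")
      if (length(donors) > 0) {
        return(unlist(lapply(donors, function(d)
          rec("de_novo_interaction", donor = d, transporter = transporter,
              ambiguous = length(donors) > 1)), recursive = FALSE))
      }
    }
    trail$reason <- "transport fill without cross-member pairing"
    return(rec("accepted_fill", transporter = transporter))
  }
  trail$check <- "taxonomy"
  taxa <- unique(unlist(lapply(candidate$reactions, function(rid)
    db$entries[[rid]]$taxa %||% character(0))))
  rk <- taxonomy_rank(taxa, member$id, tax)
  trail$taxonomy_rank <- if (is.finite(rk)) rk else NA
  if (!is.finite(rk) || rk > tax$threshold) {
    trail$reason <- "taxonomic likelihood below threshold"
    return(rec("rejected"))
  }
  if (!tic_ok()) {
    trail$reason <- "creates thermodynamically infeasible cycle"
    return(rec("rejected"))
  }
  trail$reason <- "network fix accepted"
  rec("accepted_fill")
}

#' Discover inter-species interactions for a whole community
#'
#' For every member, problem metabolites are identified with [gapfind()] and
#' gap-filled against each other member's reaction set and against the
#' universal database; every candidate is classified and duplicate records
#' (same metabolite, donor, receiver, status) are collapsed.
#'
#' @param cm a `community_model`.
#' @param kb a `transporter_kb`.
#' @param tax a `taxonomy_config`.
#' @param db_universal universal `reaction_db`.
#' @param max_alternates alternates per gap-fill call.
#' @param eps production threshold.
#' @param phase record phase tag.
#' @return data.frame (see [interaction_table()]); the raw records are in
#'   `attr(, "records")`.
#' @export
discover_interactions <- function(cm, kb, tax, db_universal,
                                  max_alternates = 3, eps = GAPFILL_EPS,
                                  phase = "pre_AMG") {
  records <- list()
  members <- cm$members
  for (k in names(members)) {
    member <- members[[k]]
    others <- members[setdiff(names(members), k)]
    gaps <- gapfind(member, eps = eps)
    baseline <- find_unbounded(member)$unbounded
    dbs <- c(lapply(others, member_as_db), list(universal = db_universal))
    targets <- rbind(
      if (length(gaps$no_production) > 0)
        data.frame(met = gaps$no_production, dir = "production"),
      if (length(gaps$no_consumption) > 0)
        data.frame(met = gaps$no_consumption, dir = "consumption"))
    if (is.null(targets)) next
    for (t in seq_len(nrow(targets))) {
      for (db in dbs) {
        cands <- gapfill(member, targets$met[[t]], db,
                         direction = targets$dir[[t]],
                         max_alternates = max_alternates, eps = eps)
        for (cand in cands) {
          if (cand$cardinality == 0) next
          records <- c(records,
                       classify_candidate(cand, member, others, kb, tax, db,
                                          eps = eps,
                                          baseline_unbounded = baseline,
                                          phase = phase))
        }
      }
    }
  }
  # collapse duplicates on (metabolite, donor, receiver, status)
  keys <- vapply(records, function(r)
    paste(r$metabolite, r$donor %||% "", r$receiver, r$status, sep = "|"), "")
  records <- records[!duplicated(keys)]
  tab <- interaction_table(records)
  attr(tab, "records") <- records
  tab
}

#' Compare interaction sets before and after a perturbation
#'
#' De novo records are keyed by (metabolite, donor, receiver).
#'
#' @param pre,post interaction tables (from [discover_interactions()]).
#' @return list with data.frames `retained`, `lost`, `gained`.
#' @export
diff_interactions <- function(pre, post) {
  dn <- function(tab) {
    tab <- tab[tab$status == "de_novo_interaction", , drop = FALSE]
    tab$key <- paste(tab$metabolite, tab$donor, tab$receiver, sep = "|")
    tab
  }
  a <- dn(pre); b <- dn(post)
  list(retained = a[a$key %in% b$key, setdiff(names(a), "key"), drop = FALSE],
       lost = a[!a$key %in% b$key, setdiff(names(a), "key"), drop = FALSE],
       gained = b[!b$key %in% a$key, setdiff(names(b), "key"), drop = FALSE])
}
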