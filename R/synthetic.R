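# Synthetic toy communities with planted, machine-readable ground truth.
#
# The fixed TOY3 fixture mirrors the three functional guilds of the rumen:
# a polysaccharide degrader (X), a secondary consumer (Y) and a
# hydrogenotrophic methanogen (Z). Planted features and their truth tables:
#   * cross-feed: X exports acetate; Y consumes cytosolic acetate but its
#     transporter T_ac is withheld, so ac[c] is a planted no-production gap
#     whose discovered fill is the planted X -> Y interaction;
#   * further gaps: x1[c] (X, no production), x2[c] (X, no consumption),
#     vb[c] (Z, no production);
#   * one thermodynamically infeasible 3-cycle CYC1-3 in X;
#   * a 2-reaction dead-end branch P2a/P2b in X (blocked);
#   * a capacity bottleneck: Z's methanogenesis is capped at 5 and its AMG
#     set provides an uncapped 2-step formate bypass.
# Chemistry is real where it matters for balance checking (glucose
# fermentation, methanogenesis); lumped metabolites (aa, vb, x1, x2) have
# unknown formulas.

rxn <- function(id, eq, lb = NULL, ub = NULL, biomass = FALSE) {
  p <- parse_equation(eq)
  if (is.null(lb)) lb <- if (p$reversible) -FLUX_BOUND else 0
  if (is.null(ub)) ub <- FLUX_BOUND
  reaction(id, p$stoichiometry, lb = lb, ub = ub, reversible = lb < 0,
           is_biomass = biomass)
}

mets_from <- function(reactions, formulas = character(0)) {
  ids <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
  lapply(ids, function(id) {
    b <- met_base(id)
    metabolite(id, formula = if (b %in% names(formulas)) formulas[[b]]
                             else NA_character_)
  })
}

toy3_formulas <- c(glc = "C6H12O6", triose = "C3H6O3", ac = "C2H4O2",
                   h2 = "H2", co2 = "CO2", h2o = "H2O", ch4 = "CH4",
                   c1 = "CH2O", c2 = "CH2O", c3 = "CH2O", forA = "CH2O2")

#' Build the TOY3 fixture bundle
#'
#' A deterministic three-member community (degrader X, consumer Y,
#' methanogen Z) with planted gaps, one cross-feed, one infeasible cycle, a
#' dead-end branch and an AMG bypass, plus its diet, transporter
#' knowledgebase, taxonomy configuration, universal reaction database,
#' per-member AMG sets, objective defaults and exact truth tables.
#'
#' @return a `synthetic_bundle` list: `members`, `shared`, `diet`, `kb`,
#'   `tax`, `db_universal`, `amg`, `objectives`, `truth`.
#' @export
make_toy3 <- function() {
  X_rxns <- list(
    rxn("EX_glc", "glc[e] ->", lb = -10),
    rxn("T_glc", "glc[e] -> glc[c]"),
    rxn("GLY", "glc[c] -> 2 triose[c]"),
    rxn("BIO_X", "triose[c] ->", biomass = TRUE),
    rxn("T_triose", "triose[c] -> triose[e]"),
    rxn("EX_triose", "triose[e] ->"),
    rxn("GLF", "glc[c] + 2 h2o[c] -> 2 ac[c] + 2 co2[c] + 4 h2[c]"),
    rxn("T_ac", "ac[c] <=> ac[e]"),
    rxn("EX_ac", "ac[e] ->"),
    rxn("T_h2", "h2[c] -> h2[e]"),
    rxn("EX_h2", "h2[e] ->"),
    rxn("T_co2", "co2[c] -> co2[e]"),
    rxn("EX_co2", "co2[e] ->"),
    rxn("T_h2o", "h2o[e] -> h2o[c]"),
    rxn("EX_h2o", "h2o[e] <=>"),
    rxn("CYC1", "c1[c] <=> c2[c]"),
    rxn("CYC2", "c2[c] <=> c3[c]"),
    rxn("CYC3", "c3[c] <=> c1[c]"),
    rxn("P2a", "triose[c] -> x2a[c]"),
    rxn("P2b", "x2a[c] -> x2[c]"),
    rxn("X1U", "x1[c] -> co2[c]")
  )

  build <- function(id, reactions, biomass) {
    mets <- mets_from(reactions, toy3_formulas)
    metabolic_model(id, mets, reactions, biomass)
  }
  X <- build("X", X_rxns, "BIO_X")

  Y <- build("Y", list(
    rxn("EX_glc", "glc[e] ->", lb = -10),
    rxn("T_glc", "glc[e] -> glc[c]"),
    rxn("GAA", "glc[c] -> 2 aa[c]"),
    rxn("BIO_Y", "aa[c] ->", biomass = TRUE),
    rxn("ACAA", "ac[c] -> aa[c]"),
    rxn("EX_ac", "ac[e] ->", lb = -FLUX_BOUND)
  ), "BIO_Y")

  Z <- build("Z", list(
    rxn("EX_h2", "h2[e] ->", lb = -FLUX_BOUND),
    rxn("T_h2", "h2[e] -> h2[c]"),
    rxn("EX_co2", "co2[e] ->", lb = -FLUX_BOUND),
    rxn("T_co2", "co2[e] -> co2[c]"),
    rxn("MGEN", "co2[c] + 4 h2[c] -> ch4[c] + 2 h2o[c]", ub = 5),
    rxn("BIO_Z", "ch4[c] ->", biomass = TRUE),
    rxn("T_ch4", "ch4[c] -> ch4[e]"),
    rxn("EX_ch4", "ch4[e] ->"),
    rxn("T_h2o", "h2o[c] -> h2o[e]"),
    rxn("EX_h2o", "h2o[e] ->"),
    rxn("VBU", "vb[c] -> co2[c]")
  ), "BIO_Z")

  db_rxn <- function(id, eq, taxa) {
    r <- rxn(id, eq)
    r$taxa <- taxa
    r
  }
  db_universal <- reaction_db(list(
    db_rxn("T_ac_u", "ac[e] <=> ac[c]", c("Y", "X")),
    db_rxn("R_x1", "triose[c] -> x1[c]", "RelOrgX"),
    db_rxn("VBS", "co2[c] + 3 h2[c] -> vb[c]", "RelOrgZ"),
    db_rxn("T_vb", "vb[e] <=> vb[c]", "FarOrg"),
    db_rxn("T_x2", "x2[c] -> x2[e]", "X"),
    db_rxn("REV_GLY", "2 triose[c] -> glc[c]", "RelOrgX"),
    db_rxn("U01", "u1[c] -> u2[c]", "FarOrg"),
    db_rxn("U02", "u2[c] -> u3[c]", "FarOrg"),
    db_rxn("U03", "u3[c] <=> u4[c]", "RelOrgX"),
    db_rxn("U04", "u4[c] -> u5[c]", "RelOrgZ"),
    db_rxn("U05", "u5[e] <=> u5[c]", "FarOrg"),
    db_rxn("U06", "u6[c] + u7[c] -> u8[c]", "FarOrg"),
    db_rxn("U07", "u8[c] -> u6[c] + u7[c]", "FarOrg"),
    db_rxn("U08", "glc[c] -> u9[c]", "FarOrg"),
    db_rxn("U09", "u9[c] -> u10[c]", "FarOrg")
  ), source = "universal")

  kb <- transporter_kb(data.frame(
    member = c("Y", "X", "X"),
    metabolite = c("ac", "x2", "ac"),
    evidence = c("experimental", "experimental", "experimental"),
    citation = c("synthetic truth", "synthetic truth", "synthetic truth"),
    stringsAsFactors = FALSE))

  tax <- taxonomy_config(list(
    X = c("RelOrgX", "Y", "Z"),
    Y = c("X", "Z", "RelOrgX"),
    Z = c("RelOrgZ", "X", "Y")
  ), threshold = 2L)

  amg <- list(
    X = amg_set("X", list(rxn("GLY_V", "glc[c] -> 2 triose[c]")),
                phage = "phiX-syn", evalue = 1e-40),
    Y = amg_set("Y", list(rxn("GAC_V", "glc[c] -> 3 ac[c]")),
                phage = "phiY-syn", evalue = 1e-45),
    Z = amg_set("Z", list(
      rxn("FDH_V", "co2[c] + h2[c] -> forA[c]"),
      rxn("FMR_V", "forA[c] + 3 h2[c] -> ch4[c] + 2 h2o[c]")),
      phage = "phiZ-syn", evalue = c(1e-38, 1e-36))
  )

  objectives <- standard_objectives(
    scfa = "ac", feed = "glc", gases = c("ch4", "co2"), sugars = "triose")

  truth <- list(
    gaps = data.frame(
      member = c("X", "Y", "Z", "X"),
      metabolite = c("x1[c]", "ac[c]", "vb[c]", "x2[c]"),
      direction = c("production", "production", "production", "consumption"),
      stringsAsFactors = FALSE),
    crossfeeds = data.frame(
      donor = "X", receiver = "Y", metabolite = "ac", transporter = "T_ac_u",
      stringsAsFactors = FALSE),
    cycles = list(list(member = "X",
                       reactions = c("CYC1", "CYC2", "CYC3"))),
    blocked = data.frame(
      member = c("X", "X", "X", "Y", "Y", "Z"),
      reaction = c("P2a", "P2b", "X1U", "ACAA", "EX_ac", "VBU"),
      stringsAsFactors = FALSE),
    deadend_branch = c("P2a", "P2b"),
    amg = data.frame(member = "Z", bottleneck = "MGEN",
                     widened_expect = "BIO_Z", stringsAsFactors = FALSE))

  structure(list(
    spec = list(seed = NA_integer_, n_members = 3L, fixture = "TOY3"),
    members = list(X = X, Y = Y, Z = Z),
    shared = c("glc", "ac", "h2", "co2", "ch4", "triose"),
    diet = c(glc = 10),
    kb = kb, tax = tax, db_universal = db_universal, amg = amg,
    objectives = objectives, truth = truth),
    class = "synthetic_bundle")
}

#' Bridge the planted cross-feed gaps with their planted transporters
#'
#' Applies each truth-table transporter (from the universal database) to its
#' receiver member, producing the gap-filled members used for community
#' simulation.
#'
#' @param bundle a `synthetic_bundle`.
#' @return the bundle with filled members.
#' @export
apply_planted_fills <- function(bundle) {
  cf <- bundle$truth$crossfeeds
  for (i in seq_len(nrow(cf))) {
    r <- bundle$db_universal$entries[[cf$transporter[[i]]]]
    recv <- bundle$members[[cf$receiver[[i]]]]
    if (!stoich_key(r$stoichiometry) %in%
        vapply(recv$reactions, function(q) stoich_key(q$stoichiometry), "")) {
      recv <- add_reactions(recv, list(r))
    }
    bundle$members[[cf$receiver[[i]]]] <- validate_model(recv)
  }
  bundle
}

#' Build the community model of a bundle
#'
#' @param bundle a `synthetic_bundle`.
#' @param filled bridge planted cross-feed gaps first (default `TRUE`).
#' @return a `community_model`.
#' @export
bundle_community <- function(bundle, filled = TRUE) {
  if (filled) bundle <- apply_planted_fills(bundle)
  build_community(bundle$members, bundle$shared, bundle$diet,
                  id = "toy-community")
}

#' Synthetic community specification
#'
#' @param seed RNG seed (determinism contract: same spec, same bundle).
#' @param n_members number of members.
#' @param pathway_length internal pathway length per member.
#' @param n_deadends dead-end branches (each plants one no-consumption gap
#'   and two blocked reactions).
#' @param n_crossfeeds donor-exporter / receiver-transporter pairs (each
#'   plants one no-production gap in the receiver).
#' @param n_cycles reversible 3-cycles (thermodynamically infeasible).
#' @param n_amg_bypasses members given a capacity bottleneck plus an AMG
#'   bypass.
#' @param uptake substrate uptake bound per member.
#' @param bounds_scale multiplies all uptake bounds.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_members = 3L, pathway_length = 3L,
                           n_deadends = 1L, n_crossfeeds = 1L, n_cycles = 1L,
                           n_amg_bypasses = 1L, uptake = 10,
                           bounds_scale = 1) {
  if (n_crossfeeds > 0 && n_members < 2) {
    stop_fluxcom("cross-feeds require at least 2 members")
  }
  structure(list(seed = as.integer(seed), n_members = as.integer(n_members),
                 pathway_length = as.integer(pathway_length),
                 n_deadends = as.integer(n_deadends),
                 n_crossfeeds = as.integer(n_crossfeeds),
                 n_cycles = as.integer(n_cycles),
                 n_amg_bypasses = as.integer(n_amg_bypasses),
                 uptake = uptake * bounds_scale,
                 bounds_scale = bounds_scale),
            class = "synthetic_spec")
}

#' Generate a random toy community with planted ground truth
#'
#' Members are linear catabolic pathways (substrate uptake, 2-fold
#' conversion, chain, biomass drain) onto which the requested features are
#' planted: dead-end branches, donor/receiver cross-feeding pairs (receiver
#' transporter withheld and recorded in the knowledgebase), reversible
#' 3-cycles, and capacity bottlenecks with AMG bypass sets. Every member is
#' individually feasible under the emitted diet; gaps sit on branches whose
#' removal does not zero biomass.
#'
#' @param spec a [synthetic_spec()].
#' @return a `synthetic_bundle` (same shape as [make_toy3()]).
#' @export
generate_community <- function(spec = synthetic_spec()) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  K <- spec$n_members
  ids <- paste0("M", seq_len(K))
  L <- max(2L, spec$pathway_length)
  members <- list()
  truth_gaps <- list(); truth_blocked <- list()
  feature_members <- function(n) ids[(seq_len(n) - 1L) %% K + 1L]

  for (k in seq_len(K)) {
    id <- ids[[k]]
    sub <- paste0("sub", k)
    chain <- paste0("m", k, "_", seq_len(L))
    rs <- list(
      rxn(paste0("EX_", sub), paste0(sub, "[e] ->"), lb = -spec$uptake),
      rxn(paste0("T_", sub), paste0(sub, "[e] -> ", sub, "[c]")),
      rxn(paste0("CONV_", id), paste0(sub, "[c] -> 2 ", chain[[1]], "[c]")))
    for (i in seq_len(L - 1)) {
      rs <- c(rs, list(rxn(paste0("C", i, "_", id),
                           paste0(chain[[i]], "[c] -> ", chain[[i + 1]], "[c]"))))
    }
    rs <- c(rs, list(rxn(paste0("BIO_", id), paste0(chain[[L]], "[c] ->"),
                         biomass = TRUE)))
    members[[id]] <- rs
  }

  # dead-end branches: chain[1] -> d1 -> d2, d2 never consumed
  de_members <- feature_members(spec$n_deadends)
  for (i in seq_along(de_members)) {
    id <- de_members[[i]]
    k <- match(id, ids)
    d1 <- paste0("d", i, "a"); d2 <- paste0("d", i, "b")
    r1 <- paste0("DE", i, "a_", id); r2 <- paste0("DE", i, "b_", id)
    members[[id]] <- c(members[[id]], list(
      rxn(r1, paste0("m", k, "_1[c] -> ", d1, "[c]")),
      rxn(r2, paste0(d1, "[c] -> ", d2, "[c]"))))
    truth_gaps[[length(truth_gaps) + 1]] <-
      data.frame(member = id, metabolite = paste0(d2, "[c]"),
                 direction = "consumption", stringsAsFactors = FALSE)
    truth_blocked[[length(truth_blocked) + 1]] <-
      data.frame(member = id, reaction = c(r1, r2), stringsAsFactors = FALSE)
  }

  # cross-feeds
  cf_rows <- list(); kb_rows <- list(); db_entries <- list()
  pairs <- list()
  for (i in seq_len(spec$n_crossfeeds)) {
    donor <- ids[(i - 1L) %% K + 1L]
    receiver <- ids[i %% K + 1L]
    pairs[[i]] <- c(donor, receiver)
  }
  for (i in seq_along(pairs)) {
    donor <- pairs[[i]][[1]]; receiver <- pairs[[i]][[2]]
    xm <- paste0("xf", i)
    kd <- match(donor, ids); kr <- match(receiver, ids)
    t_id <- paste0("T_", xm)
    members[[donor]] <- c(members[[donor]], list(
      rxn(paste0("XP", i, "_", donor),
          paste0("m", kd, "_1[c] -> ", xm, "[c]")),
      rxn(t_id, paste0(xm, "[c] <=> ", xm, "[e]")),
      rxn(paste0("EX_", xm), paste0(xm, "[e] ->"))))
    members[[receiver]] <- c(members[[receiver]], list(
      rxn(paste0("XU", i, "_", receiver),
          paste0(xm, "[c] -> m", kr, "_", L, "[c]")),
      rxn(paste0("EX_", xm), paste0(xm, "[e] ->"), lb = -FLUX_BOUND)))
    db_entry <- rxn(t_id, paste0(xm, "[e] <=> ", xm, "[c]"))
    db_entry$taxa <- receiver
    db_entries[[t_id]] <- db_entry
    cf_rows[[i]] <- data.frame(donor = donor, receiver = receiver,
                               metabolite = xm, transporter = t_id,
                               stringsAsFactors = FALSE)
    kb_rows[[i]] <- data.frame(member = receiver, metabolite = xm,
                               evidence = "ortholog",
                               citation = "synthetic truth",
                               stringsAsFactors = FALSE)
    truth_gaps[[length(truth_gaps) + 1]] <-
      data.frame(member = receiver, metabolite = paste0(xm, "[c]"),
                 direction = "production", stringsAsFactors = FALSE)
    truth_blocked[[length(truth_blocked) + 1]] <-
      data.frame(member = receiver,
                 reaction = c(paste0("XU", i, "_", receiver),
                              paste0("EX_", xm)),
                 stringsAsFactors = FALSE)
  }

  # cycles
  cyc_list <- list()
  cy_members <- feature_members(spec$n_cycles)
  for (i in seq_along(cy_members)) {
    id <- cy_members[[i]]
    ms <- paste0("y", i, "_", 1:3)
    rids <- paste0("CY", i, c("a", "b", "c"), "_", id)
    members[[id]] <- c(members[[id]], list(
      rxn(rids[[1]], paste0(ms[[1]], "[c] <=> ", ms[[2]], "[c]")),
      rxn(rids[[2]], paste0(ms[[2]], "[c] <=> ", ms[[3]], "[c]")),
      rxn(rids[[3]], paste0(ms[[3]], "[c] <=> ", ms[[1]], "[c]"))))
    cyc_list[[i]] <- list(member = id, reactions = rids)
  }

  # AMG bypasses: cap the first chain conversion, provide a 2-step bypass
  amg <- list()
  amg_rows <- list()
  ab_members <- feature_members(spec$n_amg_bypasses)
  for (i in seq_along(ab_members)) {
    id <- ab_members[[i]]
    k <- match(id, ids)
    cap_id <- paste0("C1_", id)
    members[[id]] <- lapply(members[[id]], function(r) {
      if (r$id == cap_id) { r$ub <- spec$uptake / 2 }
      r
    })
    bm <- paste0("byp", i)
    amg[[id]] <- amg_set(id, list(
      rxn(paste0("V1_", id), paste0("m", k, "_1[c] -> ", bm, "[c]")),
      rxn(paste0("V2_", id), paste0(bm, "[c] -> m", k, "_2[c]"))),
      phage = paste0("phi-", id), evalue = 1e-50)
    amg_rows[[i]] <- data.frame(member = id, bottleneck = cap_id,
                                widened_expect = paste0("BIO_", id),
                                stringsAsFactors = FALSE)
  }

  # distractor db entries
  for (i in 1:3) {
    did <- paste0("DIS", i)
    e <- rxn(did, paste0("q", i, "[c] -> q", i + 1, "[c]"))
    e$taxa <- "FarOrg"
    db_entries[[did]] <- e
  }

  models <- lapply(ids, function(id) {
    metabolic_model(id, mets_from(members[[id]]), members[[id]],
                    paste0("BIO_", id))
  })
  names(models) <- ids

  shared <- c(paste0("sub", seq_len(K)),
              vapply(cf_rows, function(r) r$metabolite, character(1)))
  diet <- stats::setNames(rep(spec$uptake, K), paste0("sub", seq_len(K)))

  kb <- transporter_kb(if (length(kb_rows) > 0) do.call(rbind, kb_rows)
                       else data.frame(member = character(0),
                                       metabolite = character(0),
                                       evidence = character(0),
                                       citation = character(0)))
  tax <- taxonomy_config(stats::setNames(lapply(ids, function(id)
    c(setdiff(ids, id), paste0("RelOrg_", id))), ids),
    threshold = max(1L, K - 1L))

  cf_met <- if (length(cf_rows) > 0) cf_rows[[1]]$metabolite else "sub1"
  objectives <- standard_objectives(
    scfa = cf_met, feed = paste0("sub", seq_len(K)), gases = cf_met,
    sugars = cf_met)

  truth <- list(
    gaps = if (length(truth_gaps) > 0) do.call(rbind, truth_gaps)
           else data.frame(member = character(0), metabolite = character(0),
                           direction = character(0)),
    crossfeeds = if (length(cf_rows) > 0) do.call(rbind, cf_rows)
                 else data.frame(donor = character(0), receiver = character(0),
                                 metabolite = character(0),
                                 transporter = character(0)),
    cycles = cyc_list,
    blocked = if (length(truth_blocked) > 0) do.call(rbind, truth_blocked)
              else data.frame(member = character(0), reaction = character(0)),
    amg = if (length(amg_rows) > 0) do.call(rbind, amg_rows)
          else data.frame(member = character(0), bottleneck = character(0),
                          widened_expect = character(0)))

  structure(list(spec = spec, members = models, shared = shared, diet = diet,
                 kb = kb, tax = tax,
                 db_universal = reaction_db(db_entries, "universal"),
                 amg = amg, objectives = objectives, truth = truth),
            class = "synthetic_bundle")
}

#' Write a bundle to disk in the native formats
#'
#' Models as native JSON under `models/`, the universal database and
#' knowledgebase as TSV, taxonomy/diet/shared as YAML, AMG sets as JSON,
#' and the truth table as JSON.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  for (m in bundle$members) {
    write_model(m, file.path(dir, "models", paste0(m$id, ".json")))
  }
  write_reaction_db(bundle$db_universal, file.path(dir, "db_universal.tsv"))
  utils::write.table(as.data.frame(unclass(bundle$kb)),
                     file.path(dir, "transporter_kb.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(members = bundle$tax$ranks,
                        threshold = bundle$tax$threshold),
                   file.path(dir, "taxonomy.yaml"))
  yaml::write_yaml(as.list(bundle$diet), file.path(dir, "diet.yaml"))
  yaml::write_yaml(list(shared = as.list(bundle$shared)),
                   file.path(dir, "shared.yaml"))
  dir.create(file.path(dir, "amg"), showWarnings = FALSE)
  for (a in bundle$amg) {
    doc <- list(member = a$member, phage = a$phage, evalue = a$evalue,
                reactions = lapply(unname(a$reactions), function(r)
                  list(id = r$id,
                       equation = format_equation(r$stoichiometry,
                                                  r$reversible),
                       lb = r$lb, ub = r$ub)))
    writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(dir, "amg", paste0(a$member, ".json")))
  }
  writeLines(jsonlite::toJSON(bundle$truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#' @param dir bundle directory.
#' @return a `synthetic_bundle` (objectives rebuilt from the truth table are
#'   not restored; `NULL`).
#' @export
read_bundle <- function(dir) {
  model_files <- sort(list.files(file.path(dir, "models"),
                                 full.names = TRUE))
  members <- lapply(model_files, read_model)
  names(members) <- vapply(members, `[[`, "", "id")
  tax <- read_taxonomy_config(file.path(dir, "taxonomy.yaml"))
  diet <- read_diet(file.path(dir, "diet.yaml"))
  shared <- unlist(yaml::read_yaml(file.path(dir, "shared.yaml"))$shared)
  amg_files <- list.files(file.path(dir, "amg"), full.names = TRUE)
  amg <- lapply(amg_files, function(f) {
    doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    amg_set(doc$member,
            lapply(doc$reactions, function(r) {
              p <- parse_equation(r$equation)
              reaction(r$id, p$stoichiometry, lb = r$lb, ub = r$ub,
                       reversible = r$lb < 0)
            }),
            phage = doc$phage, evalue = unlist(doc$evalue))
  })
  names(amg) <- vapply(amg, `[[`, "", "member")
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  structure(list(spec = NULL, members = members, shared = shared,
                 diet = diet,
                 kb = read_transporter_kb(file.path(dir, "transporter_kb.tsv")),
                 tax = tax,
                 db_universal = read_reaction_db(file.path(dir,
                                                           "db_universal.tsv")),
                 amg = amg, objectives = NULL, truth = truth),
            class = "synthetic_bundle")
}
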