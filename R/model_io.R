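# Model and table I/O.
#
# The native model dialect is JSON (schema in the README): it round-trips
# every field exactly, including member tags and flags that SBML level 2
# cannot carry without lossy annotations. SBML L2 is read-only.

#' Write a model in the native JSON dialect
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  doc <- list(
    id = model$id,
    biomass_reaction_id = model$biomass_reaction_id,
    metabolites = lapply(unname(model$metabolites), function(m) {
      list(id = m$id, name = m$name, formula = m$formula,
           charge = m$charge, compartment = m$compartment)
    }),
    reactions = lapply(unname(model$reactions), function(r) {
      list(id = r$id, stoichiometry = as.list(r$stoichiometry),
           lb = r$lb, ub = r$ub, reversible = r$reversible,
           genes = as.list(r$genes), subsystem = r$subsystem,
           is_exchange = r$is_exchange, is_transport = r$is_transport,
           is_biomass = r$is_biomass)
    })
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null", pretty = TRUE),
             path)
  invisible(path)
}

#' Read a member model
#'
#' @param path path to a native JSON model or an SBML level 2 document.
#' @param dialect `"native"` or `"sbml2"`.
#' @return a validated `metabolic_model`.
#' @export
read_model <- function(path, dialect = c("native", "sbml2")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fluxcom("file not found: ", path)
  if (dialect == "native") read_model_native(path) else read_model_sbml2(path)
}

read_model_native <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(m$id, m$name %||% m$id, m$formula %||% NA_character_,
               m$charge %||% 0L, m$compartment %||% NULL)
  })
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    st <- stats::setNames(as.numeric(st), names(st))
    reaction(r$id, st, lb = as.numeric(r$lb), ub = as.numeric(r$ub),
             reversible = r$reversible,
             genes = as.character(unlist(r$genes)),
             subsystem = r$subsystem %||% NA_character_,
             is_exchange = r$is_exchange, is_transport = r$is_transport,
             is_biomass = isTRUE(r$is_biomass))
  })
  metabolic_model(doc$id, mets, rxns, doc$biomass_reaction_id)
}

# SBML level 2 reader. Species ids follow the usual flattening convention
# "M_<base>_<comp>"; reaction ids may carry an "R_" prefix. Formula and
# charge are taken from COBRA-style notes lines "FORMULA: ..." / "CHARGE: ...".
read_model_sbml2 <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(model_node)) stop_fluxcom("no <model> element in ", path)
  model_id <- xml2::xml_attr(model_node, "id") %||% "model"

  species <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp_ids <- xml2::xml_attr(species, "id")
  mets <- list()
  id_map <- character(0)
  for (i in seq_along(species)) {
    sid <- sp_ids[[i]]
    comp <- xml2::xml_attr(species[[i]], "compartment")
    base <- sub("^M_", "", sid)
    base <- sub(paste0("_", comp, "$"), "", base)
    mid <- paste0(base, "[", comp, "]")
    note_lines <- xml2::xml_text(xml2::xml_find_all(species[[i]],
                                                    ".//notes//p"))
    formula <- NA_character_
    charge <- 0L
    for (line in note_lines) {
      fm <- regmatches(line, regexec("FORMULA:\\s*(\\S+)", line))[[1]]
      if (length(fm) == 2) formula <- fm[[2]]
      ch <- regmatches(line, regexec("CHARGE:\\s*(-?[0-9]+)", line))[[1]]
      if (length(ch) == 2) charge <- as.integer(ch[[2]])
    }
    ca <- xml2::xml_attr(species[[i]], "charge")
    if (!is.na(ca)) charge <- as.integer(ca)
    mets[[mid]] <- metabolite(mid, xml2::xml_attr(species[[i]], "name") %||% mid,
                              formula, charge, comp)
    id_map[[sid]] <- mid
  }

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- list()
  for (rn in rnodes) {
    rid <- sub("^R_", "", xml2::xml_attr(rn, "id"))
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rn, paste0("./", side, "/speciesReference"))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        if (!sid %in% names(id_map)) {
          stop_fluxcom("reaction ", rid, " cites undeclared species: ", sid)
        }
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
        if (is.na(coef)) coef <- 1
        sign <- if (side == "listOfReactants") -1 else 1
        mid <- id_map[[sid]]
        st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + sign * coef
      }
    }
    lb <- NULL; ub <- NULL
    pars <- xml2::xml_find_all(rn, ".//kineticLaw//parameter")
    for (p in pars) {
      pid <- xml2::xml_attr(p, "id")
      val <- as.numeric(xml2::xml_attr(p, "value"))
      if (identical(pid, "LOWER_BOUND")) lb <- val
      if (identical(pid, "UPPER_BOUND")) ub <- val
    }
    lb <- lb %||% (if (rev) -FLUX_BOUND else 0)
    ub <- ub %||% FLUX_BOUND
    rxns[[rid]] <- reaction(rid, st, lb = lb, ub = ub, reversible = lb < 0)
  }
  biomass <- grep("biomass|^BIO", names(rxns), ignore.case = TRUE, value = TRUE)
  if (length(biomass) == 0) biomass <- names(rxns)[[length(rxns)]]
  for (b in biomass) rxns[[b]]$is_biomass <- TRUE
  metabolic_model(model_id, unname(mets), unname(rxns), biomass[[1]])
}

#' Parse a reaction equation string
#'
#' Equations use compartment-suffixed metabolite ids, `+` separators and an
#' arrow: `"<=>"` (reversible) or `"->"` (irreversible), e.g.
#' `"glc[c] + 2 h2o[c] -> 2 ac[c] + 2 co2[c] + 4 h2[c]"`.
#'
#' @param equation equation string.
#' @return list with `stoichiometry` (named numeric) and `reversible`.
#' @export
parse_equation <- function(equation) {
  arrow <- if (grepl("<=>", equation, fixed = TRUE)) "<=>"
    else if (grepl("-->", equation, fixed = TRUE)) "-->"
    else if (grepl("->", equation, fixed = TRUE)) "->"
    else stop_fluxcom("malformed equation (no arrow): ", equation)
  pos <- regexpr(arrow, equation, fixed = TRUE)
  sides <- c(substr(equation, 1, pos - 1),
             substr(equation, pos + attr(pos, "match.length"),
                    nchar(equation)))
  if (grepl(arrow, sides[[2]], fixed = TRUE)) {
    stop_fluxcom("malformed equation: ", equation)
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    st <- numeric(0)
    for (term in trimws(strsplit(side, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) stop_fluxcom("malformed equation term in: ", equation)
      m <- regmatches(term, regexec("^([0-9.]+\\s+)?(\\S+)$", term))[[1]]
      if (length(m) != 3) stop_fluxcom("malformed equation term: ", term)
      coef <- if (nzchar(trimws(m[[2]]))) as.numeric(m[[2]]) else 1
      mid <- m[[3]]
      if (is.na(met_compartment(mid))) {
        stop_fluxcom("metabolite without compartment suffix in equation: ", mid)
      }
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + sign * coef
    }
    st
  }
  lhs <- parse_side(sides[[1]], -1)
  rhs <- parse_side(sides[[2]], +1)
  st <- lhs
  for (mid in names(rhs)) st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + rhs[[mid]]
  st <- st[st != 0]
  list(stoichiometry = st, reversible = arrow == "<=>")
}

#' Format a stoichiometry as an equation string
#' @param stoichiometry named numeric vector.
#' @param reversible logical.
#' @return equation string.
#' @export
format_equation <- function(stoichiometry, reversible) {
  fmt <- function(v) {
    paste(vapply(names(v), function(m) {
      coef <- abs(v[[m]])
      if (coef == 1) m else paste(format(coef, scientific = FALSE), m)
    }, ""), collapse = " + ")
  }
  lhs <- fmt(stoichiometry[stoichiometry < 0])
  rhs <- fmt(stoichiometry[stoichiometry > 0])
  paste(lhs, if (reversible) "<=>" else "->", rhs)
}

#' Read a reaction database table
#'
#' Tab-separated with columns `id`, `equation`, `reversibility`
#' (`reversible`/`irreversible`), `taxa` (semicolon-separated organism
#' labels; may be empty).
#'
#' @param path TSV path.
#' @param source source tag stored on the database (e.g. `"universal"`).
#' @return a `reaction_db`.
#' @export
read_reaction_db <- function(path, source = "universal") {
  if (!file.exists(path)) stop_fluxcom("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "equation", "reversibility", "taxa")
  if (!all(need %in% names(tab))) {
    stop_fluxcom("reaction db must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$id)) {
    stop_fluxcom("duplicate reaction db ids: ",
                 paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  entries <- list()
  errors <- character(0)
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch({
      eq <- parse_equation(tab$equation[[i]])
      rev <- identical(tolower(tab$reversibility[[i]]), "reversible")
      if (rev != eq$reversible) rev <- rev || eq$reversible
      r <- reaction(tab$id[[i]], eq$stoichiometry,
                    lb = if (rev) -FLUX_BOUND else 0, ub = FLUX_BOUND,
                    reversible = rev)
      r$taxa <- if (nzchar(tab$taxa[[i]] %||% "")) {
        trimws(strsplit(tab$taxa[[i]], ";", fixed = TRUE)[[1]])
      } else character(0)
      r
    }, fluxcom_error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0("row ", i, " (", tab$id[[i]], "): ",
                                 conditionMessage(res)))
    } else {
      entries[[res$id]] <- res
    }
  }
  if (length(errors) > 0) {
    stop_fluxcom("reaction db parse errors:\n  ", paste(errors, collapse = "\n  "))
  }
  reaction_db(entries, source)
}

#' Construct a reaction database from reaction objects
#' @param entries named list of `reaction`s (each may carry a `taxa` field).
#' @param source source tag.
#' @return a `reaction_db`.
#' @export
reaction_db <- function(entries, source = "universal") {
  names(entries) <- vapply(entries, `[[`, "", "id")
  if (anyDuplicated(names(entries))) {
    stop_fluxcom("duplicate reaction db ids: ",
                 paste(unique(names(entries)[duplicated(names(entries))]),
                       collapse = ", "))
  }
  structure(list(entries = entries, source = source), class = "reaction_db")
}

#' Write a reaction database as TSV
#' @param db a `reaction_db`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_reaction_db <- function(db, path) {
  tab <- data.frame(
    id = names(db$entries),
    equation = vapply(db$entries, function(r)
      format_equation(r$stoichiometry, r$reversible), ""),
    reversibility = vapply(db$entries, function(r)
      if (r$reversible) "reversible" else "irreversible", ""),
    taxa = vapply(db$entries, function(r)
      paste(r$taxa %||% character(0), collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transporter-evidence knowledgebase
#'
#' TSV with columns `member`, `metabolite` (base id, no compartment),
#' `evidence` (`experimental`, `ortholog`, `none`), `citation`.
#' @param path TSV path.
#' @return a `transporter_kb` data.frame.
#' @export
read_transporter_kb <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("member", "metabolite", "evidence", "citation")
  if (!all(need %in% names(tab))) {
    stop_fluxcom("transporter kb must have columns: ",
                 paste(need, collapse = ", "))
  }
  transporter_kb(tab)
}

#' Construct a transporter knowledgebase
#' @param table data.frame with `member`, `metabolite`, `evidence`, `citation`.
#' @return a `transporter_kb`.
#' @export
transporter_kb <- function(table = data.frame(member = character(0),
                                              metabolite = character(0),
                                              evidence = character(0),
                                              citation = character(0))) {
  stopifnot(all(table$evidence %in% c("experimental", "ortholog", "none")))
  structure(table, class = c("transporter_kb", "data.frame"))
}

#' Look up transporter evidence for (member, metabolite)
#' @param kb a `transporter_kb`.
#' @param member member id.
#' @param metabolite base metabolite id.
#' @return `"experimental"`, `"ortholog"`, or `"none"`.
#' @export
kb_evidence <- function(kb, member, metabolite) {
  hit <- kb$evidence[kb$member == member & kb$metabolite == metabolite]
  if (length(hit) == 0) return("none")
  lev <- c(none = 0, ortholog = 1, experimental = 2)
  names(which.max(lev[hit]))
}

#' Read a taxonomy configuration (YAML)
#'
#' Schema: `threshold: <int>` and `members: {<member>: [taxon, ...]}` where
#' each member's list is ordered from most to least related.
#' @param path YAML path.
#' @return a `taxonomy_config`.
#' @export
read_taxonomy_config <- function(path) {
  doc <- yaml::read_yaml(path)
  taxonomy_config(doc$members, doc$threshold %||% 2L)
}

#' Construct a taxonomy configuration
#' @param ranks named list member -> ranked character vector of taxa.
#' @param threshold acceptance rank threshold (1-based).
#' @return a `taxonomy_config`.
#' @export
taxonomy_config <- function(ranks, threshold = 2L) {
  depth <- max(c(1L, vapply(ranks, length, 1L)))
  if (threshold < 1 || threshold > depth) {
    stop_fluxcom("taxonomy threshold must lie within list depth")
  }
  structure(list(ranks = ranks, threshold = as.integer(threshold)),
            class = "taxonomy_config")
}

#' Read a community diet configuration (YAML)
#'
#' Mapping base metabolite id -> maximum community uptake (mmol/gDCW/hr).
#' @param path YAML path.
#' @return named numeric vector.
#' @export
read_diet <- function(path) {
  doc <- yaml::read_yaml(path)
  unlist(doc)
}
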