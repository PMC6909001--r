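test_that("native JSON model is transcribed with an exact S matrix", {
  mets <- lapply(c("a[c]", "b[c]", "x[e]"), metabolite)
  rxns <- list(
    reaction("r1", c("a[c]" = -1, "b[c]" = 2), lb = 0, ub = 1000),
    reaction("r2", c("x[e]" = -1), lb = -5, ub = 5, reversible = TRUE))
  m <- metabolic_model("mini", mets, rxns, "r1")
  S <- stoich_matrix(m)
  expect_equal(dim(S), c(3, 2))
  expect_equal(S["a[c]", "r1"], -1)
  expect_equal(S["b[c]", "r1"], 2)
  expect_equal(S["x[e]", "r2"], -1)
  expect_equal(sum(S != 0), 3)
})

test_that("model invariants are enforced with offending ids named", {
  mets <- list(metabolite("a[c]"))
  expect_error(
    metabolic_model("bad", mets,
                    list(reaction("r1", c("ghost[c]" = 1))), "r1"),
    "ghost")
  expect_error(
    metabolic_model("bad", mets, list(reaction("r1", c("a[c]" = 1))),
                    "nope"),
    "biomass_reaction_id")
  expect_error(reaction("r", numeric(0)), "empty stoichiometry")
  expect_error(reaction("r", c("a[c]" = 1), lb = -1, ub = 1,
                        reversible = FALSE), "reversible")
  # exchange reactions touch exactly one metabolite in [e] or [u]
  expect_error(
    metabolic_model("bad", mets,
                    list(reaction("EX", c("a[c]" = -1), is_exchange = TRUE)),
                    "EX"),
    "exchange")
})

test_that("write/read round-trip is the identity on TOY3 and random models", {
  toy <- make_toy3()
  for (m in toy$members) {
    f <- withr::local_tempfile(fileext = ".json")
    write_model(m, f)
    expect_identical(read_model(f), m)
  }
  set.seed(41)
  for (i in 1:50) {
    net <- random_network(n_met = sample(2:4, 1), n_rxn = sample(2:6, 1))
    m <- network_as_model(net, paste0("rand", i))
    f <- withr::local_tempfile(fileext = ".json")
    write_model(m, f)
    expect_identical(read_model(f), m)
  }
})

test_that("writing an invalid model is refused", {
  m <- chain_model()
  m$reactions <- list()
  expect_error(write_model(m, tempfile()), "no reactions")
})

test_that("reversibility is serialized from the bounds convention", {
  m <- chain_model()
  m$reactions[["AB"]]$lb <- -1000
  m$reactions[["AB"]]$reversible <- TRUE
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_true(m2$reactions[["AB"]]$reversible)
  expect_equal(m2$reactions[["AB"]]$lb, -1000)
})

test_that("SBML level 2 documents are read, bad species refs are named", {
  sbml_lines <- function(extra_rxn = "") c(
    "<?xml version=\"1.0\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level2\" level=\"2\" version=\"1\">",
    "<model id=\"mini\"><listOfSpecies>",
    paste0("<species id=\"M_glc_e\" compartment=\"e\"><notes>",
           "<body xmlns=\"http://www.w3.org/1999/xhtml\">",
           "<p>FORMULA: C6H12O6</p><p>CHARGE: 0</p></body></notes></species>"),
    "<species id=\"M_glc_c\" compartment=\"c\"/>",
    "</listOfSpecies><listOfReactions>",
    paste0("<reaction id=\"R_EX_glc\" reversible=\"true\">",
           "<listOfReactants><speciesReference species=\"M_glc_e\"/>",
           "</listOfReactants><kineticLaw><math/><listOfParameters>",
           "<parameter id=\"LOWER_BOUND\" value=\"-10\"/>",
           "<parameter id=\"UPPER_BOUND\" value=\"1000\"/>",
           "</listOfParameters></kineticLaw></reaction>"),
    paste0("<reaction id=\"R_biomass\" reversible=\"false\">",
           "<listOfReactants><speciesReference species=\"M_glc_c\"/>",
           "</listOfReactants></reaction>"),
    extra_rxn,
    "</listOfReactions></model></sbml>")
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_lines(), f)
  m <- read_model(f, dialect = "sbml2")
  expect_s3_class(m, "metabolic_model")
  expect_equal(m$metabolites[["glc[e]"]]$formula, "C6H12O6")
  expect_true(m$reactions[["EX_glc"]]$reversible)
  expect_equal(m$reactions[["EX_glc"]]$lb, -10)

  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml_lines(paste0(
    "<reaction id=\"R_bad\" reversible=\"false\"><listOfReactants>",
    "<speciesReference species=\"M_ghost_c\"/></listOfReactants>",
    "</reaction>")), f2)
  expect_error(read_model(f2, dialect = "sbml2"), "M_ghost_c")
})

test_that("reaction database TSV parsing handles transport rows and errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\treversibility\ttaxa",
               "rxnT1\tac[e] <=> ac[c]\treversible\tPrevotella",
               "rxnI1\ta[c] -> b[c]\tirreversible\tOrgA;OrgB"), f)
  db <- read_reaction_db(f)
  expect_length(db$entries, 2)
  expect_true(db$entries[["rxnT1"]]$is_transport)
  expect_true(db$entries[["rxnT1"]]$reversible)
  expect_equal(db$entries[["rxnI1"]]$taxa, c("OrgA", "OrgB"))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\treversibility\ttaxa",
               "dup\ta[c] -> b[c]\tirreversible\t",
               "dup\tb[c] -> a[c]\tirreversible\t"), f2)
  expect_error(read_reaction_db(f2), "dup")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tequation\treversibility\ttaxa",
               "bad\ta[c] + \tirreversible\t"), f3)
  expect_error(read_reaction_db(f3), "bad")
})

test_that("equation strings round-trip through format/parse", {
  eqs <- c("glc[c] + 2 h2o[c] -> 2 ac[c] + 2 co2[c] + 4 h2[c]",
           "ac[e] <=> ac[c]", "a[c] ->")
  for (eq in eqs) {
    p <- parse_equation(eq)
    p2 <- parse_equation(format_equation(p$stoichiometry, p$reversible))
    expect_equal(sort(names(p$stoichiometry)), sort(names(p2$stoichiometry)))
    expect_equal(p$stoichiometry[sort(names(p$stoichiometry))],
                 p2$stoichiometry[sort(names(p2$stoichiometry))])
    expect_equal(p$reversible, p2$reversible)
  }
})

test_that("formula parsing is Hill-exact and flags unknowns", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
  expect_equal(parse_formula("H"), c(H = 1L))
  expect_equal(parse_formula("C10H12N5O7P"),
               c(C = 10L, H = 12L, N = 5L, O = 7L, P = 1L))
  expect_null(parse_formula(NA))
  expect_null(parse_formula(""))
  expect_error(parse_formula("C6#H12"), "cannot parse")
})
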