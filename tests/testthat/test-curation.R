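balanced_toy <- function() {
  rs <- list(
    rxn_("EX_glc", "glc[e] ->", lb = -10),
    rxn_("T", "glc[e] -> glc[c]"),
    rxn_("SPLIT", "glc[c] -> 2 triose[c]"),
    rxn_("BIO", "triose[c] ->", biomass = TRUE))
  mets <- lapply(unique(unlist(lapply(rs, function(r) names(r$stoichiometry)))),
                 function(id) metabolite(id, formula = c(glc = "C6H12O6",
                                                         triose = "C3H6O3")[[
                   fluxcom:::met_base(id)]]))
  metabolic_model("bal", mets, rs, "BIO")
}

test_that("balance checking is exact integer accounting", {
  m <- balanced_toy()
  rep <- check_balance(m)
  expect_equal(rep$table$status[rep$table$reaction == "SPLIT"], "balanced")
  expect_length(rep$imbalanced, 0)

  # glc -> 2 ethanol loses 2 CO2: net {C:-2, O:-4}
  m2 <- m
  m2$metabolites[["etoh[c]"]] <- metabolite("etoh[c]", formula = "C2H6O")
  m2$reactions[["FERM"]] <- reaction("FERM", c("glc[c]" = -1, "etoh[c]" = 2),
                                     lb = 0, ub = 1000)
  rep2 <- check_balance(m2)
  expect_equal(rep2$imbalances[["FERM"]][["C"]], -2)
  expect_equal(rep2$imbalances[["FERM"]][["O"]], -4)

  # unknown formula makes a reaction unbalanceable, not imbalanced
  m3 <- m
  m3$metabolites[["mys[c]"]] <- metabolite("mys[c]")
  m3$reactions[["MYS"]] <- reaction("MYS", c("glc[c]" = -1, "mys[c]" = 1),
                                    lb = 0, ub = 1000)
  rep3 <- check_balance(m3)
  expect_true("MYS" %in% rep3$unbalanceable)
  expect_false("MYS" %in% rep3$imbalanced)
})

test_that("balanced models conserve every element across the reaction set", {
  m <- make_toy3()$members$X
  rep <- check_balance(m)
  bal <- rep$table$reaction[rep$table$status == "balanced"]
  for (rid in bal) {
    st <- m$reactions[[rid]]$stoichiometry
    nets <- numeric(0)
    for (mid in names(st)) {
      f <- parse_formula(m$metabolites[[mid]]$formula)
      for (el in names(f)) {
        prev <- if (el %in% names(nets)) nets[[el]] else 0
        nets[el] <- prev + st[[mid]] * f[[el]]
      }
    }
    expect_true(all(nets == 0))
  }
})

test_that("proton-only imbalances get a signed proton fix", {
  m <- balanced_toy()
  m$metabolites[["h[c]"]] <- metabolite("h[c]", formula = "H", charge = 1L)
  m$metabolites[["ax[c]"]] <- metabolite("ax[c]", formula = "C6H13O6",
                                         charge = 1L)
  # glc -> ax: one H and one charge too many on the product side
  m$reactions[["PR"]] <- reaction("PR", c("glc[c]" = -1, "ax[c]" = 1),
                                  lb = 0, ub = 1000)
  expect_equal(suggest_proton_fix(m, "PR"), -1L)

  m$metabolites[["ax2[c]"]] <- metabolite("ax2[c]", formula = "C6H14O6",
                                          charge = 2L)
  m$reactions[["PR2"]] <- reaction("PR2", c("glc[c]" = -1, "ax2[c]" = 1),
                                   lb = 0, ub = 1000)
  expect_equal(suggest_proton_fix(m, "PR2"), -2L)

  # carbon imbalance is not proton-fixable
  m$metabolites[["cx[c]"]] <- metabolite("cx[c]", formula = "C7H12O6")
  m$reactions[["PR3"]] <- reaction("PR3", c("glc[c]" = -1, "cx[c]" = 1),
                                   lb = 0, ub = 1000)
  expect_null(suggest_proton_fix(m, "PR3"))
  expect_null(suggest_proton_fix(m, "SPLIT"))
})

test_that("closed-uptake FVA finds exactly the planted cycle", {
  toy <- make_toy3()
  rep <- find_unbounded(toy$members$X)
  expect_setequal(rep$unbounded, c("CYC1", "CYC2", "CYC3"))
  # a linear pathway has no unbounded reactions
  expect_length(find_unbounded(chain_model())$unbounded, 0)
  expect_length(find_unbounded(toy$members$Z)$unbounded, 0)
})

test_that("null-basis grouping recovers cycle supports and coefficients", {
  toy <- make_toy3()
  lr <- group_loops(toy$members$X, c("CYC1", "CYC2", "CYC3"))
  expect_length(lr$groups, 1)
  expect_setequal(lr$groups[[1]]$reactions, c("CYC1", "CYC2", "CYC3"))
  expect_equal(unname(lr$groups[[1]]$coefficients[c("CYC1", "CYC2", "CYC3")]),
               c(1, 1, 1))

  # duplicated reversible reaction pair: support of 2, coefficients (1, -1)
  m <- chain_model()
  m$reactions[["AB"]]$lb <- -1000
  m$reactions[["AB"]]$reversible <- TRUE
  m$reactions[["AB2"]] <- reaction("AB2", c("A[c]" = -1, "B[c]" = 1),
                                   lb = -1000, ub = 1000, reversible = TRUE)
  ub <- find_unbounded(m)
  expect_setequal(ub$unbounded, c("AB", "AB2"))
  lr2 <- group_loops(m, ub)
  expect_length(lr2$groups, 1)
  expect_setequal(lr2$groups[[1]]$reactions, c("AB", "AB2"))
  expect_setequal(unname(lr2$groups[[1]]$coefficients), c(1, -1))

  # two disjoint planted cycles give two groups with disjoint supports
  m2 <- make_toy3()$members$X
  for (r in list(rxn_("CYD1", "w1[c] <=> w2[c]"),
                 rxn_("CYD2", "w2[c] <=> w1[c]"))) {
    m2 <- fluxcom:::add_reactions(m2, list(r))
  }
  ub2 <- find_unbounded(m2)
  lr3 <- group_loops(m2, ub2)
  expect_length(lr3$groups, 2)
  sup <- lapply(lr3$groups, `[[`, "reactions")
  expect_length(intersect(sup[[1]], sup[[2]]), 0)
})

test_that("null-space basis is exact: S n = 0 with integer coefficients", {
  toy <- make_toy3()
  internal <- setdiff(names(toy$members$X$reactions),
                      c("EX_glc", "EX_triose", "EX_ac", "EX_h2", "EX_co2",
                        "EX_h2o"))
  S <- stoich_matrix(toy$members$X)[, internal]
  basis <- rat_nullspace(S)
  expect_gt(ncol(basis), 0)
  expect_true(all(S %*% basis == 0))       # exact, not within tolerance
  expect_true(all(basis == round(basis)))  # integer-scaled
})

test_that("constraining one representative per group clears the loops", {
  toy <- make_toy3()
  X <- toy$members$X
  ub <- find_unbounded(X)
  lr <- group_loops(X, ub)
  X2 <- constrain_loop_representatives(X, lr)
  expect_length(find_unbounded(X2)$unbounded, 0)
  expect_lt(length(find_unbounded(X2)$unbounded), length(ub$unbounded))
  # whitelisted reactions are never touched
  X3 <- constrain_loop_representatives(X, lr,
                                       whitelist = c("CYC1", "CYC2", "CYC3"))
  expect_length(attr(X3, "constrained"), 0)
})

test_that("blocked reactions are exactly the planted dead branches", {
  toy <- make_toy3()
  truth <- toy$truth$blocked
  for (k in names(toy$members)) {
    expect_setequal(find_blocked(toy$members[[k]]),
                    truth$reaction[truth$member == k])
  }
  expect_false("BIO_X" %in% find_blocked(toy$members$X))
})

test_that("duplicate detection sees exact, reversed, and cofactor variants", {
  m <- chain_model()
  m$reactions[["AB_dup"]] <- reaction("AB_dup", c("A[c]" = -1, "B[c]" = 1),
                                      lb = 0, ub = 1000)
  m$reactions[["AB_rev"]] <- reaction("AB_rev", c("A[c]" = 1, "B[c]" = -1),
                                      lb = 0, ub = 1000)
  d <- find_duplicates(m)
  key <- paste(d$rxn1, d$rxn2, d$orientation)
  expect_true("AB AB_dup same" %in% key)
  expect_true("AB AB_rev reversed" %in% key)

  m2 <- chain_model()
  for (mid in c("nadh[c]", "nad[c]", "nadph[c]", "nadp[c]")) {
    m2$metabolites[[mid]] <- metabolite(mid)
  }
  m2$reactions[["DH1"]] <- reaction("DH1", c("A[c]" = -1, "nad[c]" = -1,
                                             "B[c]" = 1, "nadh[c]" = 1),
                                    lb = 0, ub = 1000)
  m2$reactions[["DH2"]] <- reaction("DH2", c("A[c]" = -1, "nadp[c]" = -1,
                                             "B[c]" = 1, "nadph[c]" = 1),
                                    lb = 0, ub = 1000)
  d2 <- find_duplicates(m2, cofactor_pairs = list(c("nadh", "nadph"),
                                                  c("nad", "nadp")))
  hit <- d2[d2$rxn1 == "DH1" & d2$rxn2 == "DH2", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$cofactor_variant)
  d3 <- find_duplicates(m2)
  expect_equal(nrow(d3[d3$rxn1 == "DH1" & d3$rxn2 == "DH2", ]), 0)
})
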