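test_that("gapfind reports structural and planted problem metabolites", {
  m <- chain_model()
  m$metabolites[["orphan[c]"]] <- metabolite("orphan[c]")
  m$reactions[["OU"]] <- reaction("OU", c("orphan[c]" = -1, "B[c]" = 1),
                                  lb = 0, ub = 1000)
  g <- gapfind(m)
  expect_true("orphan[c]" %in% g$no_production)
  expect_true("orphan[c]" %in% g$root)   # no producing term at all

  expect_length(gapfind(chain_model())$no_production, 0)
  expect_length(gapfind(chain_model())$no_consumption, 0)

  toy <- make_toy3()
  truth <- toy$truth$gaps
  for (k in names(toy$members)) {
    g <- gapfind(toy$members[[k]])
    expect_setequal(g$no_production,
                    truth$metabolite[truth$member == k &
                                       truth$direction == "production"])
    expect_setequal(g$no_consumption,
                    truth$metabolite[truth$member == k &
                                       truth$direction == "consumption"])
  }
})

test_that("a unique one-transporter fill is found; empty dbs return empty", {
  toy <- make_toy3()
  Y <- toy$members$Y
  cands <- gapfill(Y, "ac[c]", member_as_db(toy$members$X))
  expect_length(cands, 1)
  expect_equal(cands[[1]]$reactions, "T_ac")
  expect_equal(cands[[1]]$cardinality, 1)
  expect_equal(cands[[1]]$source, "X")

  expect_length(gapfill(Y, "ac[c]", member_as_db(toy$members$Z)), 0)
})

test_that("MILP fill cardinality equals exhaustive subset search", {
  set.seed(5)
  for (i in 1:8) {
    inst <- random_gapfill_instance()
    cands <- gapfill(inst$model, inst$target, inst$db, max_alternates = 1)
    oracle <- oracle_min_fill(inst$model, inst$target, inst$db)
    expect_identical(is.finite(oracle), length(cands) > 0)
    expect_equal(oracle, inst$expected)
    if (length(cands) > 0) expect_equal(cands[[1]]$cardinality, oracle)
  }
})

test_that("alternate fills are enumerated by integer cuts, ties in id order", {
  toy <- make_toy3()
  Z <- toy$members$Z
  cands <- gapfill(Z, "vb[c]", toy$db_universal, max_alternates = 5)
  expect_length(cands, 2)   # VBS and T_vb both have cardinality 1
  expect_equal(vapply(cands, `[[`, 0, "cardinality"), c(1, 1))
  expect_equal(vapply(cands, `[[`, 0, "solution_index"), c(1, 2))
  # lexicographic tie-break: T_vb before VBS
  expect_equal(cands[[1]]$reactions, "T_vb")
  expect_equal(cands[[2]]$reactions, "VBS")
  # rerun is deterministic
  cands2 <- gapfill(Z, "vb[c]", toy$db_universal, max_alternates = 5)
  expect_identical(lapply(cands, `[[`, "reactions"),
                   lapply(cands2, `[[`, "reactions"))
})

test_that("applying a returned candidate removes its target gap", {
  toy <- make_toy3()
  cases <- list(
    list(member = "Y", target = "ac[c]", dir = "production"),
    list(member = "Z", target = "vb[c]", dir = "production"),
    list(member = "X", target = "x2[c]", dir = "consumption"))
  for (cs in cases) {
    m <- toy$members[[cs$member]]
    cands <- gapfill(m, cs$target, toy$db_universal, direction = cs$dir)
    expect_gt(length(cands), 0)
    m2 <- apply_candidate(m, cands[[1]], toy$db_universal)
    g <- gapfind(m2)
    side <- if (cs$dir == "production") g$no_production else g$no_consumption
    expect_false(cs$target %in% side)
  }
})

test_that("member_as_db exports internal and transport reactions only", {
  toy <- make_toy3()
  X <- toy$members$X
  db <- member_as_db(X)
  n_ex <- sum(vapply(X$reactions, `[[`, TRUE, "is_exchange"))
  expect_length(db$entries, length(X$reactions) - n_ex - 1) # minus biomass
  expect_equal(db$source, "X")
  expect_true(db$entries[["T_ac"]]$is_transport)
  expect_false(any(vapply(db$entries, `[[`, TRUE, "is_exchange")))
  expect_false("BIO_X" %in% names(db$entries))

  # re-adding a member's own entries to itself is a no-op (duplicates fire)
  expect_length(fluxcom:::usable_db_entries(X, db), 0)
})

test_that("planted gaps are recovered with perfect sensitivity/specificity", {
  for (s in 1:6) {
    b <- generate_community(synthetic_spec(seed = s))
    truth <- b$truth$gaps
    for (k in names(b$members)) {
      g <- gapfind(b$members[[k]])
      expect_setequal(g$no_production,
                      truth$metabolite[truth$member == k &
                                         truth$direction == "production"])
      expect_setequal(g$no_consumption,
                      truth$metabolite[truth$member == k &
                                         truth$direction == "consumption"])
    }
  }
})
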