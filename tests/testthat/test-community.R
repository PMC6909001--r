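test_that("community assembly produces one pool row and four allocation
           variables per shared metabolite and member pair", {
  toy <- make_toy3()
  cm <- build_community(toy$members["X"], "ac", c(ac = 5))
  sys <- fluxcom:::community_system(cm)
  expect_equal(sum(grepl("^pool:", sys$row_tag)), 1)
  expect_length(sys$alloc, 2)  # r_up + r_ex for the one member with ac[e]

  cm2 <- bundle_community(toy)
  sys2 <- fluxcom:::community_system(cm2)
  expect_equal(sum(grepl("^pool:", sys2$row_tag)), length(toy$shared))
  # diet caps sit on pool_in only, never on member variables
  i_glc <- sys2$pool[["pool_in:glc"]] + 1
  expect_equal(unname(sys2$ub[i_glc]), 10)
  for (k in names(cm2$members)) {
    exr <- cm2$ex_map[["glc"]][k]
    if (is.na(exr)) next
    j <- sys2$info[[k]]$offset + match(exr, sys2$info[[k]]$rxn_ids)
    expect_equal(unname(sys2$lb[j]), -1000)
    expect_equal(unname(sys2$ub[j]), 1000)
  }
  expect_error(build_community(toy$members, "unobtainium", c()),
               "unobtainium")
})

test_that("the bilevel problem collapses to plain FBA for one member", {
  toy <- make_toy3()
  cm <- build_community(toy$members["X"], c("glc", "ac"), c(glc = 10))
  sol <- solve_optcom(cm, method = "kkt")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, fba(toy$members$X)$objective_value,
               tolerance = 1e-6)
  expect_true(all(sol$inner_check$ok))
})

test_that("KKT and collapsed joint-LP optima agree on TOY3", {
  toy <- make_toy3()
  cm <- bundle_community(toy)
  js <- solve_optcom(cm, method = "joint", verify = FALSE)
  ks <- solve_optcom(cm, method = "kkt")
  expect_equal(js$status, "optimal")
  expect_equal(ks$status, "optimal")
  expect_equal(ks$objective_value, js$objective_value, tolerance = 1e-5)
  expect_equal(ks$objective_value, 25, tolerance = 1e-5)
  expect_true(all(ks$inner_check$ok))
  expect_false(ks$dual_bound_hit)
})

test_that("an all-zero diet gives zero community growth", {
  toy <- make_toy3()
  cm <- build_community(apply_planted_fills(toy)$members, toy$shared,
                        numeric(0))
  sol <- solve_optcom(cm, method = "kkt", verify = FALSE)
  expect_equal(sol$objective_value, 0, tolerance = 1e-6)
})

test_that("pool mass balance holds for every shared metabolite", {
  toy <- make_toy3()
  cm <- bundle_community(toy)
  for (method in c("joint", "kkt")) {
    sol <- solve_optcom(cm, method = method, verify = FALSE)
    expect_true(all(abs(sol$pool$residual) < 1e-6))
  }
})

test_that("relaxing a diet bound never decreases the maximized objective", {
  toy <- make_toy3()
  bundle <- apply_planted_fills(toy)
  vals <- vapply(c(5, 10, 20), function(cap) {
    cm <- build_community(bundle$members, toy$shared, c(glc = cap))
    solve_optcom(cm, method = "kkt", verify = FALSE)$objective_value
  }, 0)
  expect_true(all(diff(vals) >= -1e-6))
  expect_lt(vals[1], vals[2])  # glc is binding on TOY3
})

test_that("community FVA pins the objective and bounds the transactions", {
  toy <- make_toy3()
  cm <- bundle_community(toy)
  sol <- solve_optcom(cm, method = "kkt", verify = FALSE)
  fv <- community_fva(cm, queries = c("X:BIO_X", "Y:BIO_Y", "Z:BIO_Z",
                                      "r_ex:ac:X", "r_up:ac:Y",
                                      "pool_in:glc"),
                      opt_value = sol$objective_value, method = "kkt")
  rg <- fv$ranges
  # member biomasses must sum to the pinned optimum at both ends
  bio <- rg[rg$reaction %in% c("X:BIO_X", "Y:BIO_Y", "Z:BIO_Z"), ]
  expect_true(all(bio$min <= bio$max + 1e-9))
  # at the growth optimum the cross-feed is obligatory: X must export >= 10
  expect_gt(rg$min[rg$reaction == "r_ex:ac:X"], 9.99)
  expect_gt(rg$min[rg$reaction == "r_up:ac:Y"], 9.99)
  # glc import is saturated
  expect_equal(rg$min[rg$reaction == "pool_in:glc"], 10, tolerance = 1e-4)
})

test_that("a reaction decoupled from pool and optimum keeps its standalone
           range", {
  toy <- make_toy3()
  cm <- bundle_community(toy)
  fv <- community_fva(cm, queries = c("X:CYC1"), method = "kkt")
  alone <- fva(apply_planted_fills(toy)$members$X, "CYC1")
  expect_equal(fv$ranges$min, alone$ranges$min, tolerance = 1e-5)
  expect_equal(fv$ranges$max, alone$ranges$max, tolerance = 1e-5)
})

test_that("the transaction table mirrors allocation ranges", {
  toy <- make_toy3()
  cm <- bundle_community(toy)
  tab <- transaction_table(cm, method = "joint")
  expect_true(all(c("metabolite", "member", "uptake_min", "uptake_max",
                    "export_min", "export_max") %in% names(tab)))
  expect_true(all(tab$uptake_min <= tab$uptake_max + 1e-9))
  ac_x <- tab[tab$metabolite == "ac" & tab$member == "X", ]
  expect_gt(ac_x$export_max, 9.99)
})
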