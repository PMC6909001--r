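test_that("the classification gates fire in the documented order", {
  toy <- make_toy3()
  Y <- toy$members$Y
  others <- toy$members[c("X", "Z")]

  # member-sourced transporter with experimental evidence, exporting donor,
  # no new cycle -> de novo interaction
  cand <- gapfill(Y, "ac[c]", member_as_db(toy$members$X))[[1]]
  recs <- classify_candidate(cand, Y, others, toy$kb, toy$tax,
                             member_as_db(toy$members$X))
  expect_length(recs, 1)
  expect_equal(recs[[1]]$status, "de_novo_interaction")
  expect_equal(recs[[1]]$donor, "X")
  expect_equal(recs[[1]]$receiver, "Y")
  expect_false(recs[[1]]$ambiguous)

  # same candidate, empty knowledgebase -> rejected at the transport gate
  recs0 <- classify_candidate(cand, Y, others, transporter_kb(), toy$tax,
                              member_as_db(toy$members$X))
  expect_equal(recs0[[1]]$status, "rejected")
  expect_match(recs0[[1]]$evidence$reason, "evidence")

  # universal candidate that closes a stoichiometric cycle -> rejected
  X <- toy$members$X
  cyc_cand <- structure(list(target = "glc[c]", direction = "production",
                             reactions = "REV_GLY", exchanges = character(0),
                             source = "universal", cardinality = 1L,
                             solution_index = 1L),
                        class = "gapfill_candidate")
  recs1 <- classify_candidate(cyc_cand, X, toy$members[c("Y", "Z")],
                              toy$kb, toy$tax, toy$db_universal)
  expect_equal(recs1[[1]]$status, "rejected")
  expect_match(recs1[[1]]$evidence$reason, "infeasible cycle")

  # universal non-transport candidate passing taxonomy -> accepted fill
  fill <- gapfill(X, "x1[c]", toy$db_universal)[[1]]
  recs2 <- classify_candidate(fill, X, toy$members[c("Y", "Z")], toy$kb,
                              toy$tax, toy$db_universal)
  expect_equal(recs2[[1]]$status, "accepted_fill")

  # the same fill fails when the taxonomy threshold excludes its taxa
  strict <- taxonomy_config(list(X = c("Y", "Z", "RelOrgX"),
                                 Y = toy$tax$ranks$Y, Z = toy$tax$ranks$Z),
                            threshold = 2L)
  recs3 <- classify_candidate(fill, X, toy$members[c("Y", "Z")], toy$kb,
                              strict, toy$db_universal)
  expect_equal(recs3[[1]]$status, "rejected")
  expect_match(recs3[[1]]$evidence$reason, "taxonomic")
})

test_that("TOY3 discovery yields exactly the planted cross-feed", {
  toy <- make_toy3()
  cm <- build_community(toy$members, toy$shared, toy$diet)
  tab <- discover_interactions(cm, toy$kb, toy$tax, toy$db_universal)
  dn <- tab[tab$status == "de_novo_interaction", ]
  expect_equal(nrow(dn), 1)
  expect_equal(dn$metabolite, "ac")
  expect_equal(dn$donor, "X")
  expect_equal(dn$receiver, "Y")
  # the other planted gaps resolve to accepted fills
  expect_true(any(tab$status == "accepted_fill" & tab$metabolite == "x1"))
  expect_true(any(tab$status == "accepted_fill" & tab$metabolite == "vb"))
})

test_that("an empty transporter knowledgebase yields zero de novo records", {
  toy <- make_toy3()
  cm <- build_community(toy$members, toy$shared, toy$diet)
  tab <- discover_interactions(cm, transporter_kb(), toy$tax,
                               toy$db_universal)
  expect_equal(sum(tab$status == "de_novo_interaction"), 0)
})

test_that("classification is deterministic", {
  toy <- make_toy3()
  cm <- build_community(toy$members, toy$shared, toy$diet)
  t1 <- discover_interactions(cm, toy$kb, toy$tax, toy$db_universal)
  t2 <- discover_interactions(cm, toy$kb, toy$tax, toy$db_universal)
  attr(t1, "records") <- NULL; attr(t2, "records") <- NULL
  expect_identical(t1, t2)
})

test_that("removing the donor's export flips the record away from de novo", {
  toy <- make_toy3()
  X <- toy$members$X
  X$reactions[["GLF"]]$ub <- 0   # X can no longer make (hence export) acetate
  members <- toy$members
  members$X <- X
  cm <- build_community(members, toy$shared, toy$diet)
  tab <- discover_interactions(cm, toy$kb, toy$tax, toy$db_universal)
  dn <- tab[tab$status == "de_novo_interaction" & tab$metabolite == "ac", ]
  expect_equal(nrow(dn), 0)
  acc <- tab[tab$metabolite == "ac", ]
  expect_true(all(acc$status %in% c("accepted_fill", "rejected")))
})

test_that("AMG bypass makes the planted exchange unnecessary (record lost)", {
  toy <- make_toy3()
  cm_pre <- build_community(toy$members, toy$shared, toy$diet)
  pre <- discover_interactions(cm_pre, toy$kb, toy$tax, toy$db_universal)
  post_members <- toy$members
  for (k in names(toy$amg)) {
    post_members[[k]] <- apply_amg(post_members[[k]], toy$amg[[k]])
  }
  cm_post <- build_community(post_members, toy$shared, toy$diet)
  post <- discover_interactions(cm_post, toy$kb, toy$tax, toy$db_universal,
                                phase = "post_AMG")
  d <- diff_interactions(pre, post)
  expect_equal(nrow(d$lost), 1)
  expect_equal(d$lost$metabolite, "ac")
  expect_equal(nrow(d$gained), 0)
  # identical lists are fully retained
  d0 <- diff_interactions(pre, pre)
  expect_equal(nrow(d0$retained),
               sum(pre$status == "de_novo_interaction"))
  expect_equal(nrow(d0$lost), 0)
})

test_that("planted cross-feeds are recovered across random communities", {
  for (s in 1:6) {
    b <- generate_community(synthetic_spec(seed = s))
    cm <- build_community(b$members, b$shared, b$diet)
    tab <- discover_interactions(cm, b$kb, b$tax, b$db_universal)
    dn <- tab[tab$status == "de_novo_interaction", ]
    truth <- b$truth$crossfeeds
    expect_equal(nrow(dn), nrow(truth))
    got <- paste(dn$metabolite, dn$donor, dn$receiver)
    want <- paste(truth$metabolite, truth$donor, truth$receiver)
    expect_setequal(got, want)
  }
})
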