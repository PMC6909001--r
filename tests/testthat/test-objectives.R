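test_that("the five standard objectives optimise their own quantity", {
  toy <- apply_planted_fills(make_toy3())
  cm <- build_community(toy$members, toy$shared, toy$diet)
  suite <- run_objective_suite(cm, toy$objectives, method = "kkt")
  vals <- vapply(suite$runs, function(r) r$solution$objective_value, 0)
  expect_equal(unname(vals["growth"]), 25, tolerance = 1e-5)
  expect_equal(unname(vals["scfa_production"]), 20, tolerance = 1e-5)
  expect_equal(unname(vals["feed_utilization"]), 10, tolerance = 1e-5)
  # gas release can be driven to zero by starving the fermentative route
  expect_equal(unname(vals["methane_co2_release"]), 0, tolerance = 1e-5)
  expect_equal(unname(vals["sugar_production"]), 20, tolerance = 1e-5)
  # pool conservation holds in every run
  for (r in suite$runs) {
    expect_true(all(abs(r$solution$pool$residual) < 1e-6))
  }
})

test_that("minimising gas release idles the methanogen", {
  toy <- apply_planted_fills(make_toy3())
  cm <- build_community(toy$members, toy$shared, toy$diet)
  sol <- solve_optcom(cm, toy$objectives$methane_co2_release,
                      method = "kkt", verify = FALSE)
  expect_equal(unname(sol$member_biomass["Z"]), 0, tolerance = 1e-6)
})

test_that("suite failures are recorded per spec and the run continues", {
  toy <- apply_planted_fills(make_toy3())
  cm <- build_community(toy$members, toy$shared, toy$diet)
  bad <- community_objective("bogus", "max",
                             data.frame(type = "pool_out", member = NA,
                                        id = "unobtainium", weight = 1))
  suite <- run_objective_suite(cm, list(bad, toy$objectives$growth),
                               queries = c("X:BIO_X"), method = "joint")
  expect_false(is.null(suite$runs[[1]]$error))
  expect_null(suite$runs[[2]]$error)
})

test_that("population SD statistics match the hand-computed fixture", {
  mk <- function(mins, maxs) {
    structure(list(ranges = data.frame(
      reaction = paste0("X:r", seq_along(mins)), min = mins, max = maxs,
      status = "optimal")), class = "fva_result")
  }
  # reaction r1: mins (0,0,0,0,3) -> population SD 1.2; r2 constant
  results <- lapply(list(c(0, 0), c(0, 0), c(0, 0), c(0, 0), c(3, 0)),
                    function(v) mk(v, v + 1))
  rep <- robustness_stats(results, members = "X")
  r1 <- rep$table[rep$table$key == "X:r1", ]
  expect_equal(r1$sd_min, 1.2)
  expect_equal(r1$sd_max, 1.2)
  expect_true(r1$nonzero)
  expect_false(rep$table$nonzero[rep$table$key == "X:r2"])
  expect_equal(rep$summary$fraction_nonzero, 0.5)
  expect_equal(rep$mean_sd, mean(c(1.2, 1.2, 0, 0)))
  expect_equal(rep$sd_range, c(0, 1.2))
  # sample SD option: sd of (0,0,0,0,3) with n-1
  rep2 <- robustness_stats(results, members = "X", sample = TRUE)
  expect_equal(rep2$table$sd_min[rep2$table$key == "X:r1"],
               stats::sd(c(0, 0, 0, 0, 3)))
  # identical results: all SDs zero
  rep0 <- robustness_stats(rep(list(mk(c(1, 2), c(3, 4))), 3))
  expect_true(all(rep0$table$sd_min == 0 & rep0$table$sd_max == 0))
  expect_error(robustness_stats(list(mk(1, 2), mk(c(1, 2), c(3, 4)))),
               "mismatched")
})

test_that("the TOY3 suite report is self-consistent", {
  toy <- apply_planted_fills(make_toy3())
  cm <- build_community(toy$members, toy$shared, toy$diet)
  suite <- run_objective_suite(cm, toy$objectives, method = "kkt")
  rep <- robustness_stats(suite, members = names(cm$members))
  # fractions and means recompute exactly from the per-reaction table
  for (i in seq_len(nrow(rep$summary))) {
    mem <- rep$summary$member[[i]]
    expect_equal(rep$summary$fraction_nonzero[[i]],
                 mean(rep$table$nonzero[rep$table$member == mem]))
  }
  expect_equal(rep$mean_sd, mean(c(rep$table$sd_min, rep$table$sd_max)))
  expect_equal(rep$sd_range, range(c(rep$table$sd_min, rep$table$sd_max)))
  expect_true(all(rep$table$sd_min >= 0 & rep$table$sd_max >= 0))
  expect_true(all(rep$summary$fraction_nonzero >= 0 &
                    rep$summary$fraction_nonzero <= 1))
})

test_that("density summaries integrate to one and sit where the data are", {
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                           utils::tail(y, -1)) / 2)
  d0 <- density_summary(rep(0, 50))
  expect_equal(trapz(d0$x, d0$density), 1, tolerance = 1e-3)
  expect_lt(abs(d0$x[which.max(d0$density)]), 0.5)

  d1 <- density_summary(c(0.2, 0.8))
  mode_x <- d1$x[which.max(d1$density)]
  expect_equal(trapz(d1$x, d1$density), 1, tolerance = 1e-3)
  # symmetric two-point input: density symmetric about the midpoint
  mid <- 0.5
  left <- stats::approx(d1$x, d1$density, mid - 0.2)$y
  right <- stats::approx(d1$x, d1$density, mid + 0.2)$y
  expect_equal(left, right, tolerance = 1e-6)

  set.seed(13)
  draws <- stats::rnorm(1000, mean = 2, sd = 0.3)
  d2 <- density_summary(draws)
  step <- diff(d2$x[1:2])
  expect_lt(abs(d2$x[which.max(d2$density)] - 2), 3 * step + 0.05)
  expect_error(density_summary(numeric(0)), "non-empty")
})
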