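make_design <- function(mets, K, seed = 1, low = 0, high = 10) {
  gsa_design(data.frame(metabolite_id = mets, mode = "uptake",
                        low = low, high = high),
             K, rng_seed = seed)
}

test_that("lhs_sample stratifies, is seeded, and has uniform margins", {
  d <- make_design("m", 4, seed = 5, low = 0, high = 4)
  x <- sort(lhs_sample(d)[, 1])
  expect_true(all(x >= 0:3 & x < 1:4))   # one draw per stratum

  expect_identical(lhs_sample(d), lhs_sample(d))

  d2 <- make_design(c("m1", "m2"), 100, seed = 9)
  X <- lhs_sample(d2)
  for (j in 1:2) {
    counts <- table(cut(X[, j], breaks = seq(0, 10, by = 1)))
    p <- stats::chisq.test(counts)$p.value
    expect_gt(p, 0.01)
  }
  expect_error(make_design("m", 3), class = "csense_design_error")
})

test_that("prcc matches normal-equations oracle and handles edge cases", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(runif(50 * 3), 50, 3)
    y <- 2 * X[, 1] - X[, 2] + rnorm(50, sd = 0.3)
    got <- prcc(X, y)
    expect_equal(got$prcc, oracle_prcc(X, y), tolerance = 1e-10)
  }

  # perfect monotone dependence
  x1 <- matrix(runif(30), 30, 1)
  expect_equal(prcc(x1, exp(x1[, 1]))$prcc, 1)

  # dominant negative dependence with a weak nuisance input
  set.seed(7)
  X <- matrix(runif(200), 100, 2)
  y <- -X[, 1] + 0.01 * X[, 2]
  r <- prcc(X, y)
  expect_lt(r$prcc[1], -0.9)
  expect_lt(r$p_value[1], 0.001)

  # constant response convention
  r0 <- prcc(X, rep(1, 100))
  expect_equal(r0$prcc, c(0, 0))
  expect_equal(r0$p_value, c(1, 1))

  # collinear rank columns are reported NA with a warning
  Xc <- cbind(X[, 1], 2 * X[, 1], X[, 2])
  w <- testthat::capture_warnings(rc <- prcc(Xc, y))
  expect_match(w, "collinear", all = TRUE)
  expect_true(all(is.na(rc$prcc[1:2])))
  expect_false(is.na(rc$prcc[3]))
})

test_that("prcc is invariant under strictly monotone transforms", {
  set.seed(3)
  X <- matrix(runif(60 * 2), 60, 2)
  y <- X[, 1] - 0.5 * X[, 2] + rnorm(60, sd = 0.2)
  base <- prcc(X, y)$prcc
  Xt <- cbind(exp(X[, 1]), X[, 2])
  expect_equal(prcc(Xt, y)$prcc, base, tolerance = 1e-12)
  expect_equal(prcc(X, exp(y) + 1)$prcc, base, tolerance = 1e-12)
})

test_that("run_gsa recovers designed dependencies on a toy model", {
  m <- make_toy_model("sp1", "glc", rng_seed = 4, inert_mets = "h2o")
  d <- default_design(m, 100, rng_seed = 21)
  res <- run_gsa(m, d)
  tab <- res$table
  expect_gt(tab$prcc[tab$metabolite_id == "glc"], 0.95)
  expect_gt(tab$p_value[tab$metabolite_id == "h2o"], 0.1)
  expect_length(res$growth_samples, 100)

  # single required substrate alone: growth = yield * capacity
  m1 <- make_toy_model("sp2", "glc", rng_seed = 4)
  r1 <- run_gsa(m1, default_design(m1, 50, rng_seed = 8))
  expect_equal(r1$table$prcc, 1)

  # metabolite without exchange reaction -> configuration error
  bad <- gsa_design(data.frame(metabolite_id = "nope", mode = "uptake",
                               low = 0, high = 10), 50, 1)
  expect_error(run_gsa(m1, bad), "nope", class = "csense_config_error")
})

test_that("infeasible-everywhere models fall back to the constant-y convention", {
  # toxin detox always exceeds the energy supply at these capacities
  m <- make_toy_model("sp1", "a", "b", rng_seed = 2)
  d <- gsa_design(data.frame(metabolite_id = c("a", "b"),
                             mode = "uptake",
                             low = c(0, 50), high = c(0.01, 60)),
                  50, rng_seed = 3)
  r <- run_gsa(m, d)
  expect_true(all(r$growth_samples == 0))
  expect_equal(r$table$prcc, c(0, 0))
  expect_equal(r$table$p_value, c(1, 1))
})
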