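test_that("model JSON round-trips field-for-field", {
  m <- make_toy_model("sp1", c("glc", "nh4"), "tox", rng_seed = 11)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  expect_equal(read_model(f), m)
})

test_that("malformed model JSON is rejected with a named field", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"id": "x", "metabolites": []}', f)
  expect_error(read_model(f), "reactions", class = "csense_format_error")

  # exchange touching two metabolites violates the exchange invariant
  m <- make_toy_model("sp1", "glc", rng_seed = 1)
  bad <- m
  bad$reactions[[1]]$stoichiometry <- c(glc = -1, prec_glc = 1)
  expect_error(metabolic_model(bad$id, bad$metabolites, bad$reactions),
               "exactly one metabolite",
               class = "csense_invariant_error")

  two_obj <- m
  two_obj$reactions[[2]]$is_objective <- TRUE
  expect_error(metabolic_model(two_obj$id, two_obj$metabolites,
                               two_obj$reactions),
               "objective", class = "csense_invariant_error")
})

test_that("solve_fba handles bound-limited growth and starvation", {
  m <- make_toy_model("sp1", "glc", rng_seed = 1)
  y <- toy_model_truth(m)$yields[["glc"]]

  expect_equal(solve_fba(m, list(EX_glc = c(0, 0)))$growth, 0)
  sol <- solve_fba(m, list(EX_glc = c(-10, 0)))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$growth, 10 * y, tolerance = 1e-9)

  # mass balance and bound residuals at the optimum
  S <- stoichiometric_matrix(m)
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)
  expect_gte(sol$fluxes[["EX_glc"]], -10 - 1e-9)
  expect_true(all(sol$fluxes[-1] >= -1e-9))
  ub <- vapply(m$reactions, `[[`, 0, "ub")
  expect_true(all(sol$fluxes <= ub + 1e-9))
})

test_that("LP growth matches vertex-enumeration oracle on random models", {
  for (seed in 1:10) {
    set.seed(seed)
    req <- sample(c("a", "b"), sample(1:2, 1))
    inh <- if (runif(1) < 0.5) "t" else character()
    m <- make_toy_model(paste0("sp", seed), req, inh, rng_seed = seed)
    caps <- stats::setNames(runif(length(exchange_map(m)), 0, 10),
                            names(exchange_map(m)))
    ov <- lapply(caps, function(u) c(-u, -u))
    names(ov) <- exchange_map(m)[names(caps)]
    got <- solve_fba(m, ov)
    want <- oracle_fba_growth(m, ov)
    if (is.na(want)) {
      expect_true(got$status != "optimal")
    } else {
      expect_equal(got$growth, max(want, 0), tolerance = 1e-6)
    }
  }
})

test_that("growth is monotone in uptake relaxation and scales linearly", {
  m <- make_toy_model("sp1", c("glc", "nh4"), rng_seed = 3)
  caps <- seq(0, 10, by = 2)
  g <- vapply(caps, function(u)
    solve_fba(m, list(EX_glc = c(-u, 0), EX_nh4 = c(-8, 0)))$growth, 0)
  expect_true(all(diff(g) >= -1e-9))

  # scaling every bound by k scales growth by k
  base <- list(EX_glc = c(-4, 0), EX_nh4 = c(-6, 0))
  g1 <- solve_fba(m, base)$growth
  g2 <- solve_fba(m, lapply(base, function(b) 2 * b))$growth
  expect_equal(g2, 2 * g1, tolerance = 1e-8)
})

test_that("growth_at_capacity realizes designed dependencies", {
  m <- make_toy_model("sp1", "a", "b", rng_seed = 2)
  tr <- toy_model_truth(m)
  expect_equal(growth_at_capacity(m, c(a = 0, b = 0)), 0)
  g0 <- growth_at_capacity(m, c(a = 10, b = 0))
  g5 <- growth_at_capacity(m, c(a = 10, b = 5))
  expect_lt(g5, g0)
  expect_equal(g0, 10 * tr$yields[["a"]], tolerance = 1e-8)
  expect_equal(g5, 10 * tr$yields[["a"]] - 5 * tr$costs[["b"]],
               tolerance = 1e-8)
  # toxin overload: infeasible forced environment reports growth 0
  expect_equal(growth_at_capacity(m, c(a = 0.1, b = 10)), 0)
})
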