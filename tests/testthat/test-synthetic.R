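test_that("generators are bit-reproducible for a fixed seed", {
  a <- make_community_scenario(5, 8, 4, rng_seed = 7)
  b <- make_community_scenario(5, 8, 4, rng_seed = 7)
  expect_identical(a, b)

  l1 <- make_lcms_scenario(50, 12, 6, 0.05, rng_seed = 3)
  l2 <- make_lcms_scenario(50, 12, 6, 0.05, rng_seed = 3)
  expect_identical(l1$table$intensities, l2$table$intensities)
})

test_that("toy model specification errors are caught", {
  expect_error(make_toy_model("sp", c("a", "b"), "a", rng_seed = 1),
               class = "csense_spec_error")
  expect_error(make_toy_model("sp", character(), rng_seed = 1),
               class = "csense_spec_error")
  expect_error(make_community_scenario(1, 5, 2),
               class = "csense_spec_error")
  expect_error(make_community_scenario(5, 3, 2),
               class = "csense_spec_error")
  expect_error(make_lcms_scenario(10, 5, 2),
               class = "csense_spec_error")
})

test_that("community scenario invariants hold", {
  sc <- make_community_scenario(5, 8, 4, rng_seed = 7)
  expect_length(sc$models, 5)
  expect_true(all(abs(rowSums(sc$abundance) - 1) < 1e-9))
  expect_true(all(sc$abundance >= 0))
  expect_true(all(abs(rowSums(sc$environment) - 1) < 1e-9))
  expect_true(all(table(sc$dependency_truth$species_id) >= 1))

  # every truth metabolite is an exchange metabolite of its model
  for (i in seq_len(nrow(sc$dependency_truth))) {
    row <- sc$dependency_truth[i, ]
    expect_true(row$metabolite_id %in%
                  names(exchange_map(sc$models[[row$species_id]])))
  }
})

test_that("positive truth tuples give positive finite-difference growth", {
  sc <- make_community_scenario(4, 6, 2, rng_seed = 11)
  tr <- sc$dependency_truth
  for (i in seq_len(nrow(tr))) {
    m <- sc$models[[tr$species_id[i]]]
    truth <- toy_model_truth(m)
    mets <- names(exchange_map(m))
    # probe: required substrates plentiful, toxins absent, so the
    # tested metabolite's arm is the one that moves
    lo <- stats::setNames(rep(8, length(mets)), mets)
    lo[truth$inhibitory] <- 0
    hi <- lo
    lo[tr$metabolite_id[i]] <- 2
    hi[tr$metabolite_id[i]] <- 4
    diff <- growth_at_capacity(m, hi) - growth_at_capacity(m, lo)
    if (tr$sign[i] > 0) expect_gt(diff, 0) else expect_lt(diff, 0)
  }
})

test_that("abundance link follows growth in the sample environment", {
  sc <- make_community_scenario(4, 8, 6, rng_seed = 1)
  n_mets <- ncol(sc$environment)
  for (s in seq_len(nrow(sc$abundance))) {
    mu <- vapply(sc$models, function(m) {
      mets <- names(exchange_map(m))
      growth_at_capacity(m, stats::setNames(
        5 * n_mets * sc$environment[s, mets], mets))
    }, 0)
    expect_equal(rank(sc$abundance[s, ]), rank(mu))
    # log-linear: log-abundance differences equal beta * growth gaps
    la <- log(sc$abundance[s, ])
    expect_equal(la - mean(la), sc$beta * (mu - mean(mu)),
                 tolerance = 1e-9)
  }

  # a species whose required metabolite is absent cannot dominate
  sc2 <- make_community_scenario(2, 2, 1, rng_seed = 1)
  req <- lapply(sc2$models, function(m) toy_model_truth(m)$required)
  env <- sc2$environment
  starved <- which(vapply(req, function(r) min(env[1, r]) < 1e-3, TRUE))
  for (i in starved)
    expect_lte(sc2$abundance[1, i], max(sc2$abundance[1, ]))
})

test_that("lcms scenario assembles the stated observation model", {
  sc <- make_lcms_scenario(50, 12, 6, 0.05, rng_seed = 3)
  expect_equal(ncol(sc$table$intensities), 18)
  expect_equal(sum(sc$table$injections$is_qc), 6)

  # identity case: no noise, no dilution, no drift
  id <- make_lcms_scenario(20, 6, 3, noise_cv = 0, rng_seed = 2,
                           drift_slope = 0, dilution_log_range = 0)
  inj <- id$table$injections
  smp <- which(!inj$is_qc)
  expect_equal(unname(id$table$intensities[, smp]),
               unname(id$true_concentrations[, inj$sample_id[smp]]))
  qc <- which(inj$is_qc)
  for (k in qc)
    expect_equal(unname(id$table$intensities[, k]),
                 unname(id$qc_profile))

  # exact reconstruction from the stored factors
  k <- which(!sc$table$injections$is_qc)[1]
  sid <- sc$table$injections$sample_id[k]
  expected_scale <- sc$dilution[[sid]] * sc$drift[k]
  ratio <- sc$table$intensities[, k] /
    (sc$true_concentrations[, sid] * expected_scale)
  cv <- stats::sd(log(ratio))
  expect_lt(abs(cv - sqrt(log(1 + 0.05^2))), 0.02)
})

test_that("scenario writer produces readable artifacts", {
  sc <- make_community_scenario(3, 4, 2, rng_seed = 9)
  d <- withr::local_tempdir()
  write_community_scenario(sc, d)
  expect_true(file.exists(file.path(d, "abundance.tsv")))
  m <- read_model(file.path(d, "models", "sp01.json"))
  expect_equal(m, sc$models[["sp01"]])
  env <- utils::read.table(file.path(d, "environment.tsv"), sep = "\t",
                           header = TRUE)
  expect_equal(env$metabolite_id, colnames(sc$environment))
})
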