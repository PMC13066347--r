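test_that("normalize_weights scales out-edges by absolute sum", {
  g <- sensitivity_graph(data.frame(
    source_id = c("m1", "m1"), target_id = c("sp1", "sp2"),
    mode = "uptake", weight = c(1, -1), p_value = 0.01))
  P <- normalize_weights(g)
  expect_equal(P["m1", "sp1"], 0.5)
  expect_equal(P["m1", "sp2"], -0.5)

  g2 <- sensitivity_graph(data.frame(
    source_id = c("m1", "m1"), target_id = c("sp1", "sp2"),
    mode = "uptake", weight = c(0.8, -0.2), p_value = 0.01))
  P2 <- normalize_weights(g2)
  expect_equal(P2["m1", c("sp1", "sp2")], c(sp1 = 0.8, sp2 = -0.2))

  expect_true(all(rowSums(abs(normalize_weights(toy_graph()))) <= 1 + 1e-12))
})

test_that("unclamped propagation matches the closed-form fixed point", {
  g <- toy_graph()   # 6 nodes
  seeds <- seed_set(c(sp1 = 2, sp2 = 1), "species_seed")
  st <- propagate(g, seeds, restart = 0.3, clamp = "off", tol = 1e-12)
  expect_true(st$converged)
  want <- oracle_propagate(g, seeds$values, 0.3)
  expect_equal(st$weights, want[names(st$weights)], tolerance = 1e-8)
})

test_that("clamping zeroes negative weights and is inert on positive graphs", {
  neg <- sensitivity_graph(data.frame(
    source_id = "m1", target_id = "sp1", mode = "uptake",
    weight = -0.9, p_value = 0.01))
  st <- propagate(neg, seed_set(c(m1 = 1), "environment"), clamp = "on")
  expect_equal(unname(st$weights["sp1"]), 0)

  pos <- sensitivity_graph(data.frame(
    source_id = c("m1", "m2"), target_id = c("sp1", "sp1"),
    mode = "uptake", weight = c(0.5, 0.7), p_value = 0.01))
  s <- seed_set(c(m1 = 0.6, m2 = 0.4), "environment")
  expect_equal(propagate(pos, s, clamp = "on")$weights,
               propagate(pos, s, clamp = "off")$weights)
})

test_that("clamped weights stay nonnegative on random signed graphs", {
  set.seed(99)
  for (i in 1:100) {
    n_sp <- sample(2:5, 1)
    n_m <- sample(2:5, 1)
    edges <- expand.grid(source_id = paste0("m", 1:n_m),
                         target_id = paste0("sp", 1:n_sp),
                         stringsAsFactors = FALSE)
    edges <- edges[runif(nrow(edges)) < 0.7, ]
    if (!nrow(edges)) next
    edges$mode <- "uptake"
    edges$weight <- runif(nrow(edges), -1, 1)
    edges$p_value <- 0.01
    g <- sensitivity_graph(edges)
    mets <- unique(edges$source_id)
    sv <- stats::setNames(runif(length(mets)), mets)
    st <- propagate(g, seed_set(sv, "environment"), clamp = "on",
                    max_iter = 500L)
    expect_true(all(st$weights >= 0))
  }
})

test_that("node order does not affect results; non-convergence is reported", {
  g <- toy_graph()
  gp <- g
  perm <- c(4, 2, 6, 1, 3, 5)
  gp$nodes <- gp$nodes[perm, ]
  seeds <- seed_set(c(m1 = 0.5, m2 = 0.3, m3 = 0.2), "environment")
  a <- propagate(g, seeds)$weights
  b <- propagate(gp, seeds)$weights
  expect_equal(a[sort(names(a))], b[sort(names(b))])

  # species seeds keep diffusing through the bipartite layers, so one
  # iteration cannot reach the fixed point
  sp_seeds <- seed_set(c(sp1 = 1, sp2 = 1), "species_seed")
  st <- propagate(g, sp_seeds, max_iter = 1L, tol = 1e-15)
  expect_false(st$converged)
  expect_equal(st$iterations, 1L)
})

test_that("seed constructors enforce modes and tie-breaks", {
  ab <- data.frame(sample_id = "S1", a = 5, b = 3, c = 1)
  expect_equal(seed_from_abundance(ab, "S1", 2)$values,
               c(a = 5, b = 3, c = 0))
  expect_equal(seed_from_abundance(ab, "S1", 10)$values,
               c(a = 5, b = 3, c = 1))
  tie <- data.frame(sample_id = "S1", b = 5, a = 5, c = 1)
  expect_equal(seed_from_abundance(tie, "S1", 1)$values,
               c(b = 0, a = 5, c = 0))   # lexicographic tie-break
  expect_error(seed_from_abundance(ab, "nope", 1),
               class = "csense_lookup_error")

  env <- data.frame(metabolite_id = c("m1", "m2"), S1 = c(3, 1))
  s <- seed_from_environment(env, "S1")
  expect_equal(s$values, c(m1 = 0.75, m2 = 0.25))

  g <- toy_graph()
  env2 <- data.frame(metabolite_id = c("m1", "zzz"), S1 = c(3, 1))
  expect_warning(s2 <- seed_from_environment(env2, "S1", graph = g),
                 "absent")
  expect_equal(s2$values, c(m1 = 1))
  env3 <- data.frame(metabolite_id = "zzz", S1 = 1)
  expect_error(suppressWarnings(
    seed_from_environment(env3, "S1", graph = g)),
    class = "csense_mapping_error")

  expect_error(propagate(g, seed_set(c(sp1 = 1), "environment")),
               class = "csense_seed_error")
})
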