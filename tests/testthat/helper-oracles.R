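# Independent oracles.  Each re-derives the quantity under test by a
# different route (enumeration, normal equations, direct linear solve,
# generic correlation) and must stay decoupled from the package's own
# code paths.

# Brute-force FBA: enumerate basic solutions of {S v = 0, lb <= v <= ub}.
# A vertex fixes n - rank(S) variables at one of their bounds; the rest
# solve the balance equations.  Returns the maximal feasible objective.
oracle_fba_growth <- function(model, overrides = list()) {
  S <- stoichiometric_matrix(model)
  rxn <- vapply(model$reactions, `[[`, "", "id")
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  names(lb) <- names(ub) <- rxn
  for (id in names(overrides)) {
    lb[id] <- overrides[[id]][1]
    ub[id] <- overrides[[id]][2]
  }
  obj <- which(vapply(model$reactions, function(r)
    isTRUE(r$is_objective), TRUE))
  n <- ncol(S)
  r <- qr(S)$rank
  nfix <- n - r
  best <- NA_real_
  fix_sets <- if (nfix == 0) list(integer(0)) else
    asplit(utils::combn(n, nfix), 2)
  for (Fi in fix_sets) {
    Fi <- as.integer(Fi)
    B <- setdiff(seq_len(n), Fi)
    combos <- if (length(Fi))
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(Fi))))
    else matrix(FALSE, 1, 0)
    for (ci in seq_len(nrow(combos))) {
      v <- numeric(n)
      v[Fi] <- ifelse(combos[ci, ], ub[Fi], lb[Fi])
      rhs <- -S[, Fi, drop = FALSE] %*% v[Fi]
      sb <- tryCatch(qr.solve(S[, B, drop = FALSE], rhs, tol = 1e-10),
                     error = function(e) NULL)
      if (is.null(sb)) next
      v[B] <- sb
      if (max(abs(S %*% v)) > 1e-6) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      val <- v[obj]
      if (is.na(best) || val > best) best <- val
    }
  }
  best
}

# PRCC by explicit normal equations on rank-transformed data.
oracle_prcc <- function(x, y) {
  rx <- apply(as.matrix(x), 2, rank)
  ry <- rank(y)
  p <- ncol(rx)
  vapply(seq_len(p), function(j) {
    if (p == 1L) return(stats::cor(rx[, 1], ry))
    Z <- cbind(1, rx[, -j, drop = FALSE])
    beta_x <- solve(t(Z) %*% Z, t(Z) %*% rx[, j])
    beta_y <- solve(t(Z) %*% Z, t(Z) %*% ry)
    ex <- rx[, j] - Z %*% beta_x
    ey <- ry - Z %*% beta_y
    sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  }, 0)
}

# Random-walk-with-restart fixed point by direct linear solve
# (clamp off, no pinning).
oracle_propagate <- function(graph, seed_values, restart) {
  P <- normalize_weights(graph)
  ids <- rownames(P)
  s <- stats::setNames(numeric(length(ids)), ids)
  s[names(seed_values)] <- seed_values
  x <- solve(diag(length(ids)) - (1 - restart) * t(P), restart * s)
  stats::setNames(as.numeric(x), ids)
}

# Savage scores straight from the harmonic-sum definition (untied).
oracle_savage <- function(ranks) {
  n <- length(ranks)
  base <- vapply(seq_len(n), function(i) sum(1 / (i:n)), 0)
  base[ranks]
}

# Top-down correlation as a generic Pearson correlation of
# Savage-transformed values (independent of the closed formula).
oracle_tdcc_pearson <- function(a, b) {
  ra <- rank(-a, ties.method = "average")
  rb <- rank(-b, ties.method = "average")
  stats::cor(oracle_savage(ra), oracle_savage(rb))
}

# Shared fixture: a small hand-made bipartite signed graph.
toy_graph <- function() {
  sensitivity_graph(data.frame(
    source_id = c("m1", "m1", "m2", "m2", "sp1", "sp2"),
    target_id = c("sp1", "sp2", "sp1", "sp3", "m3", "m3"),
    mode = c("uptake", "uptake", "uptake", "uptake",
             "secretion", "secretion"),
    weight = c(0.8, 0.5, -0.4, 0.9, 0.7, -0.3),
    p_value = 0.01))
}
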