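## Dense two-phase simplex for the small LPs arising from toy metabolic
## models.  No CRAN LP solver is assumed; problems here have tens of
## variables at most, so a tableau method with Bland's anti-cycling rule
## is adequate and fully deterministic.
##
## Solves:  maximize c'v  subject to  A v = b,  lb <= v <= ub
## with finite bounds (infinities are capped at +/- LP_BIG).

LP_BIG <- 1e6

#' @noRd
solve_lp <- function(c_obj, A, b, lb, ub, tol = 1e-9, max_iter = 10000L) {
  n <- length(c_obj)
  A <- matrix(as.numeric(A), nrow = length(b), ncol = n)
  lb <- pmax(as.numeric(lb), -LP_BIG)
  ub <- pmin(as.numeric(ub), LP_BIG)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }

  ## Shift x = v - lb so x >= 0; fixed variables (ub == lb) drop out.
  u <- ub - lb
  beq <- as.numeric(b - A %*% lb)
  free <- which(u > tol)
  nf <- length(free)
  x_full <- numeric(n)              # solution in shifted coordinates

  if (nf == 0L) {
    resid <- max(abs(beq))
    if (resid > 1e-6) {
      return(list(status = "infeasible", objective = NA_real_,
                  x = rep(NA_real_, n)))
    }
    v <- lb
    return(list(status = "optimal", objective = sum(c_obj * v), x = v))
  }

  Af <- A[, free, drop = FALSE]
  cf <- c_obj[free]
  uf <- u[free]
  m0 <- nrow(Af)

  ## Standard form: [Af 0; I I] (x, s) = (beq, uf), x,s >= 0.
  M <- m0 + nf
  N <- 2L * nf
  T0 <- matrix(0, M, N)
  T0[seq_len(m0), seq_len(nf)] <- Af
  T0[m0 + seq_len(nf), seq_len(nf)] <- diag(nf)
  T0[m0 + seq_len(nf), nf + seq_len(nf)] <- diag(nf)
  rhs <- c(beq, uf)

  neg <- rhs < 0
  T0[neg, ] <- -T0[neg, , drop = FALSE]
  rhs[neg] <- -rhs[neg]

  ## Phase 1: artificials on every row (slack columns of bound rows that
  ## survived the sign flip could seed the basis, but uniform artificials
  ## keep the code simple and these problems are tiny).
  Tab <- cbind(T0, diag(M))
  cost1 <- c(rep(0, N), rep(1, M))
  basis <- N + seq_len(M)
  ph1 <- simplex_core(Tab, rhs, cost1, basis, minimize = TRUE,
                      tol = tol, max_iter = max_iter,
                      banned = integer(0))
  if (ph1$status != "optimal") {
    return(list(status = ph1$status, objective = NA_real_,
                x = rep(NA_real_, n)))
  }
  if (ph1$objective > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_,
                x = rep(NA_real_, n)))
  }

  ## Drive any artificial still basic (at zero) out of the basis, or
  ## drop its row as redundant; then remove the artificial columns so
  ## phase 2 cannot re-inflate them.
  Tab <- ph1$Tab
  rhs2 <- ph1$rhs
  basis <- ph1$basis
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] <= N) next
    j <- which(abs(Tab[i, seq_len(N)]) > tol)[1]
    if (is.na(j)) {
      drop_rows <- c(drop_rows, i)
      next
    }
    piv <- Tab[i, j]
    Tab[i, ] <- Tab[i, ] / piv
    rhs2[i] <- rhs2[i] / piv
    for (k in seq_len(nrow(Tab))) {
      if (k != i && abs(Tab[k, j]) > tol) {
        f <- Tab[k, j]
        Tab[k, ] <- Tab[k, ] - f * Tab[i, ]
        rhs2[k] <- rhs2[k] - f * rhs2[i]
      }
    }
    basis[i] <- j
  }
  if (length(drop_rows)) {
    Tab <- Tab[-drop_rows, , drop = FALSE]
    rhs2 <- rhs2[-drop_rows]
    basis <- basis[-drop_rows]
  }
  Tab <- Tab[, seq_len(N), drop = FALSE]

  ## Phase 2: minimize -cf'x.
  cost2 <- c(-cf, rep(0, nf))
  ph2 <- simplex_core(Tab, rhs2, cost2, basis, minimize = TRUE,
                      tol = tol, max_iter = max_iter,
                      banned = integer(0))
  if (ph2$status != "optimal") {
    return(list(status = ph2$status, objective = NA_real_,
                x = rep(NA_real_, n)))
  }

  xs <- numeric(N)
  xs[ph2$basis] <- ph2$rhs
  x_full[free] <- xs[seq_len(nf)]
  v <- x_full + lb
  list(status = "optimal", objective = sum(c_obj * v), x = v)
}

## Tableau simplex (Bland's rule).  Tab rows are kept in basis-identity
## form; rhs >= 0 is maintained by the ratio test.
#' @noRd
simplex_core <- function(Tab, rhs, cost, basis, minimize = TRUE,
                         tol = 1e-9, max_iter = 10000L,
                         banned = integer(0)) {
  M <- nrow(Tab)
  allowed <- setdiff(seq_len(ncol(Tab)), banned)
  ## Put the tableau into basis-identity form for the starting basis.
  for (i in seq_len(M)) {
    piv <- Tab[i, basis[i]]
    if (abs(piv - 1) > tol || any(abs(Tab[-i, basis[i]]) > tol)) {
      Tab[i, ] <- Tab[i, ] / piv
      rhs[i] <- rhs[i] / piv
      for (k in seq_len(M)) {
        if (k != i && abs(Tab[k, basis[i]]) > tol) {
          f <- Tab[k, basis[i]]
          Tab[k, ] <- Tab[k, ] - f * Tab[i, ]
          rhs[k] <- rhs[k] - f * rhs[i]
        }
      }
    }
  }
  for (it in seq_len(max_iter)) {
    cb <- cost[basis]
    red <- cost - as.vector(cb %*% Tab)   # reduced costs
    enter <- 0L
    for (j in allowed) {                  # Bland: first improving index
      if (red[j] < -tol) { enter <- j; break }
    }
    if (enter == 0L) {
      return(list(status = "optimal", objective = sum(cost[basis] * rhs),
                  Tab = Tab, rhs = rhs, basis = basis))
    }
    col <- Tab[, enter]
    cand <- which(col > tol)
    if (length(cand) == 0L) {
      return(list(status = "unbounded", objective = NA_real_,
                  Tab = Tab, rhs = rhs, basis = basis))
    }
    ratio <- rhs[cand] / col[cand]
    best <- min(ratio)
    ties <- cand[ratio <= best + tol]
    leave <- ties[which.min(basis[ties])]  # Bland tie-break
    ## pivot
    piv <- Tab[leave, enter]
    Tab[leave, ] <- Tab[leave, ] / piv
    rhs[leave] <- rhs[leave] / piv
    for (k in seq_len(M)) {
      if (k != leave && abs(Tab[k, enter]) > tol) {
        f <- Tab[k, enter]
        Tab[k, ] <- Tab[k, ] - f * Tab[leave, ]
        rhs[k] <- rhs[k] - f * rhs[leave]
      }
    }
    rhs[rhs < 0 & rhs > -tol] <- 0
    basis[leave] <- enter
  }
  list(status = "maxiter", objective = NA_real_,
       Tab = Tab, rhs = rhs, basis = basis)
}
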