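## Global sensitivity analysis: Latin-hypercube sampling over exchange
## capacities, growth evaluation by FBA, and partial rank correlation
## coefficients with t-based significance.

#' Define a global sensitivity design
#'
#' @param parameters data.frame with columns `metabolite_id`, `mode`
#'   (`"uptake"` or `"secretion"`), `low`, `high` (capacity range,
#'   mmol/gDW/h, `low < high`, `low >= 0`).
#' @param n_samples number of Latin-hypercube samples K (needs
#'   `K >= p + 3` so the PRCC t-test has at least 1 df).
#' @param rng_seed integer seed.
#' @return object of class `gsa_design`.
#' @export
gsa_design <- function(parameters, n_samples, rng_seed = 1L) {
  need <- c("metabolite_id", "mode", "low", "high")
  if (!is.data.frame(parameters) || !all(need %in% names(parameters)))
    csense_error("parameters must have columns metabolite_id, mode, low, high",
                 "csense_design_error")
  if (!all(parameters$mode %in% c("uptake", "secretion")))
    csense_error("mode must be 'uptake' or 'secretion'",
                 "csense_design_error")
  if (anyDuplicated(parameters[c("metabolite_id", "mode")]))
    csense_error("duplicate (metabolite_id, mode) parameter",
                 "csense_design_error")
  if (any(parameters$low < 0) || any(parameters$low >= parameters$high))
    csense_error("need 0 <= low < high for every parameter",
                 "csense_design_error")
  p <- nrow(parameters)
  if (!is_count(n_samples, p + 3))
    csense_error(paste0("n_samples must be >= p + 3 = ", p + 3),
                 "csense_design_error")
  structure(list(parameters = parameters,
                 n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "gsa_design")
}

#' Default design over all exchange metabolites of a model
#'
#' @param model a `metabolic_model`.
#' @param n_samples Latin-hypercube sample count.
#' @param range capacity range, default `c(0, 10)` mmol/gDW/h.
#' @param mode `"uptake"` (default) or `"secretion"`.
#' @param rng_seed integer seed.
#' @return a `gsa_design`.
#' @export
default_design <- function(model, n_samples, range = c(0, 10),
                           mode = "uptake", rng_seed = 1L) {
  mets <- names(exchange_map(model))
  gsa_design(data.frame(metabolite_id = mets, mode = mode,
                        low = range[1], high = range[2]),
             n_samples, rng_seed)
}

#' Latin-hypercube sample of a design
#'
#' Each column holds exactly one uniform draw per one of K equal-width
#' strata of its `[low, high]` range, in an order shuffled by the design
#' seed; columns are sampled independently (no correlation induction).
#'
#' @param design a `gsa_design`.
#' @return K x p matrix, columns named `<metabolite_id>:<mode>`.
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "gsa_design"))
  K <- design$n_samples
  pars <- design$parameters
  p <- nrow(pars)
  with_seed(design$rng_seed, {
    X <- matrix(0, K, p)
    for (j in seq_len(p)) {
      strat <- (seq_len(K) - 1 + stats::runif(K)) / K
      vals <- pars$low[j] + strat * (pars$high[j] - pars$low[j])
      X[, j] <- vals[sample.int(K)]
    }
    colnames(X) <- paste(pars$metabolite_id, pars$mode, sep = ":")
    X
  })
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the response (average ranks
#' for ties).  For parameter `j`, the PRCC is the Pearson correlation
#' between the residuals of `rank(x_j)` and of `rank(y)` after linear
#' regression of each on the other `p - 1` rank columns plus an
#' intercept.  `t = r * sqrt(df / (1 - r^2))` with `df = K - 2 - (p-1)`
#' and a two-sided p-value from the t distribution.  A constant `y`
#' yields all coefficients 0 with p = 1 by convention; a rank column
#' collinear with the others yields `NA` with a warning.
#'
#' @param x K x p numeric matrix of inputs.
#' @param y numeric response of length K.
#' @return data.frame with columns `prcc`, `t_stat`, `p_value`, `df`,
#'   one row per input column.
#' @export
prcc <- function(x, y) {
  x <- as.matrix(x)
  K <- nrow(x)
  p <- ncol(x)
  if (length(y) != K)
    csense_error("length(y) must equal nrow(x)", "csense_design_error")
  if (K <= p + 2)
    csense_error("need K > p + 2 for the PRCC t-test",
                 "csense_design_error")
  df <- K - 2 - (p - 1)
  out <- data.frame(prcc = numeric(p), t_stat = numeric(p),
                    p_value = numeric(p), df = df)
  rownames(out) <- colnames(x)
  if (stats::sd(y) == 0) {
    out$prcc <- 0
    out$t_stat <- 0
    out$p_value <- 1
    return(out)
  }
  rx <- apply(x, 2, rank)
  ry <- rank(y)
  for (j in seq_len(p)) {
    others <- rx[, -j, drop = FALSE]
    if (p == 1L) {
      ex <- rx[, 1] - mean(rx[, 1])
      ey <- ry - mean(ry)
    } else {
      Z <- cbind(1, others)
      qz <- qr(Z)
      ex <- stats::setNames(qr.resid(qz, rx[, j]), NULL)
      ey <- stats::setNames(qr.resid(qz, ry), NULL)
    }
    sx <- sqrt(sum(ex^2))
    sy <- sqrt(sum(ey^2))
    if (sx < 1e-10) {
      ## input rank column collinear with the others: undefined
      warning("rank column ", j,
              " is collinear with the others; PRCC undefined")
      out$prcc[j] <- NA_real_
      out$t_stat[j] <- NA_real_
      out$p_value[j] <- NA_real_
      next
    }
    if (sy < 1e-10) {
      ## response fully explained by the other inputs: no partial
      ## association left for this one
      out$prcc[j] <- 0
      out$t_stat[j] <- 0
      out$p_value[j] <- 1
      next
    }
    r <- sum(ex * ey) / (sx * sy)
    r <- max(-1, min(1, r))
    tt <- if (abs(r) >= 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
    out$prcc[j] <- r
    out$t_stat[j] <- tt
    out$p_value[j] <- 2 * stats::pt(-abs(tt), df)
  }
  out
}

#' Run global sensitivity analysis on one model
#'
#' Draws the Latin-hypercube capacity matrix, evaluates growth at each
#' row, and computes PRCCs over all parameters jointly.  Uptake-mode
#' capacities pin the exchange flux to `-u` (forced, concentration-
#' driven influx; see [growth_at_capacity()]); secretion-mode
#' capacities relax the exchange upper bound to `+u` (lb 0).
#' Infeasible rows contribute growth 0.
#'
#' @param model a `metabolic_model`.
#' @param design a `gsa_design` whose metabolites all have exchange
#'   reactions in the model.
#' @return object of class `sensitivity_result`: the design
#'   `parameters` with `prcc`, `t_stat`, `p_value`, `df` columns, plus
#'   `species_id`, `n_samples`, `growth_samples`, and the capacity
#'   matrix `X`.
#' @export
run_gsa <- function(model, design) {
  stopifnot(inherits(design, "gsa_design"))
  ex <- exchange_map(model)
  pars <- design$parameters
  missing_ids <- setdiff(unique(pars$metabolite_id), names(ex))
  if (length(missing_ids))
    csense_error(paste0("no exchange reaction for metabolite(s): ",
                        paste(missing_ids, collapse = ", ")),
                 "csense_config_error")
  X <- lhs_sample(design)
  K <- nrow(X)
  growth <- numeric(K)
  rid_par <- ex[pars$metabolite_id]
  up_j <- which(pars$mode == "uptake")
  sec_j <- which(pars$mode == "secretion")
  for (k in seq_len(K)) {
    ov <- list()
    for (rid in unique(rid_par)) {
      u <- up_j[rid_par[up_j] == rid]
      w <- sec_j[rid_par[sec_j] == rid]
      if (length(u) && length(w)) {
        ## both directions sampled: plain bound box [-u, +w]
        ov[[rid]] <- c(-X[k, u], X[k, w])
      } else if (length(u)) {
        ## uptake only: pinned, concentration-driven influx
        ov[[rid]] <- c(-X[k, u], -X[k, u])
      } else {
        ov[[rid]] <- c(0, X[k, w])
      }
    }
    sol <- solve_fba(model, ov)
    growth[k] <- if (sol$status == "optimal") sol$growth else 0
  }
  stat <- prcc(X, growth)
  res <- cbind(pars, stat, row.names = NULL)
  structure(list(species_id = model$id, table = res,
                 n_samples = K, growth_samples = growth, X = X),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>", x$species_id, " K =", x$n_samples, "\n")
  print(x$table)
  invisible(x)
}
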