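## Top-down rank concordance.  Savage scores (harmonic tail sums)
## emphasize the top of a ranking, so agreement among the most abundant
## species dominates the coefficient -- appropriate because sampling
## variability of high-abundance taxa is comparatively small.

#' Savage scores for a ranking
#'
#' The item at (untied) rank `i` of `n` receives
#' `S_i = sum_{j=i..n} 1/j` (rank 1 = largest value); tied items share
#' the mean of their positions' scores.  Scores always sum to `n`.
#'
#' @param n number of items.
#' @param ranks numeric ranks covering 1..n, average ranks for ties
#'   (as produced by `rank(-x)`).
#' @return numeric vector of Savage scores aligned with `ranks`.
#' @export
savage_scores <- function(n, ranks) {
  if (length(ranks) != n)
    csense_error("length(ranks) must equal n", "csense_ranks_error")
  if (any(ranks < 1 - 1e-9) || any(ranks > n + 1e-9) ||
      abs(sum(ranks) - n * (n + 1) / 2) > 1e-9)
    csense_error("ranks must be average ranks covering 1..n",
                 "csense_ranks_error")
  base <- rev(cumsum(rev(1 / seq_len(n))))   # S_i for untied rank i
  out <- numeric(n)
  for (r in unique(ranks)) {
    idx <- which(abs(ranks - r) < 1e-9)
    g <- length(idx)
    pos <- seq.int(r - (g - 1) / 2, r + (g - 1) / 2)
    if (any(abs(pos - round(pos)) > 1e-9) || min(pos) < 1 ||
        max(pos) > n)
      csense_error("inconsistent tied ranks", "csense_ranks_error")
    out[idx] <- mean(base[round(pos)])
  }
  out
}

top_down_ranks <- function(values) rank(-values, ties.method = "average")

#' Pair two score vectors for top-down comparison
#'
#' @param values_a,values_b nonnegative scores over the same items
#'   (named alike, or unnamed and aligned).
#' @return object of class `ranking_pair` with derived ranks (1 =
#'   largest) and Savage scores.
#' @export
ranking_pair <- function(values_a, values_b) {
  if (length(values_a) != length(values_b))
    csense_error("value vectors differ in length",
                 "csense_alignment_error")
  if (!is.null(names(values_a)) && !is.null(names(values_b))) {
    if (!setequal(names(values_a), names(values_b)))
      csense_error("item sets differ", "csense_alignment_error")
    values_b <- values_b[names(values_a)]
  }
  n <- length(values_a)
  ra <- top_down_ranks(values_a)
  rb <- top_down_ranks(values_b)
  structure(list(item_ids = names(values_a) %||% as.character(seq_len(n)),
                 values_a = values_a, values_b = values_b,
                 ranks_a = ra, ranks_b = rb,
                 savage_a = savage_scores(n, ra),
                 savage_b = savage_scores(n, rb)),
            class = "ranking_pair")
}

#' Top-down correlation of two rankings
#'
#' `r_T = (sum_i S_a(i) S_b(i) - n) / (n - sum_{j=1..n} 1/j)`, where
#' `S` are Savage scores; equals 1 iff the (untied) rankings are
#' identical.
#'
#' @param a a `ranking_pair`, or the first value vector.
#' @param b second value vector when `a` is numeric.
#' @return the coefficient.
#' @export
top_down_correlation <- function(a, b = NULL) {
  pair <- if (inherits(a, "ranking_pair")) a else ranking_pair(a, b)
  n <- length(pair$savage_a)
  if (n < 3)
    csense_error("need at least 3 items", "csense_alignment_error")
  (sum(pair$savage_a * pair$savage_b) - n) /
    (n - sum(1 / seq_len(n)))
}

#' Top-down concordance coefficient of b rankings
#'
#' `C_T = (sum_i T_i^2 - b^2 n) / (b^2 (n - sum_{j=1..n} 1/j))` with
#' `T_i` the sum over rankings of item `i`'s Savage score; equals 1 for
#' identical untied rankings.
#'
#' @param rankings matrix (rankings in rows, items in columns) or list
#'   of value vectors over the same items; `b >= 2`.
#' @return the concordance coefficient.
#' @export
tdcc <- function(rankings) {
  if (is.list(rankings)) rankings <- do.call(rbind, rankings)
  b <- nrow(rankings)
  n <- ncol(rankings)
  if (is.null(b) || b < 2)
    csense_error("need at least 2 rankings", "csense_alignment_error")
  if (n < 3)
    csense_error("need at least 3 items", "csense_alignment_error")
  Tvec <- colSums(t(apply(rankings, 1, function(v)
    savage_scores(n, top_down_ranks(v)))))
  (sum(Tvec^2) - b^2 * n) / (b^2 * (n - sum(1 / seq_len(n))))
}

#' Concordance between predicted and observed community structure
#'
#' Computes the top-down correlation between propagated species
#' weights and observed abundances, with a permutation null obtained by
#' shuffling the observed vector's assignment to species.
#' `p = (1 + #{permuted r_T >= observed r_T}) / (permutations + 1)`.
#'
#' Both `state` and `observed` may also be species-by-sample matrices
#' (aligned rownames), in which case the reported coefficient is the
#' mean per-sample top-down correlation and the null permutes the
#' species labels once per replicate, shared across samples -- the
#' appropriate scenario-level test when several communities share one
#' graph.
#'
#' @param state a `propagation_state`, a named numeric of predicted
#'   species weights, or a species x sample matrix of weights.
#' @param observed named numeric abundances covering the predicted
#'   species (or a matching species x sample matrix).
#' @param permutations number of permutations (>= 19), default 99.
#' @param rng_seed integer seed.
#' @param species optional character vector restricting the comparison
#'   (defaults to the names of `observed`).
#' @return list with `tdcc`, `n_items`, `permutation_p` (and
#'   `per_sample` coefficients in the matrix case).
#' @export
concordance_report <- function(state, observed, permutations = 99L,
                               rng_seed = 1L, species = NULL) {
  if (!is_count(permutations, 19))
    csense_error("permutations must be >= 19", "csense_parameter_error")
  pred <- if (inherits(state, "propagation_state")) state$weights
          else state
  if (is.matrix(pred) && is.matrix(observed)) {
    return(concordance_report_multi(pred, observed, permutations,
                                    rng_seed, species))
  }
  species <- species %||% names(observed)
  miss <- setdiff(species, names(pred))
  if (length(miss))
    csense_error(paste0("predicted weights missing species: ",
                        paste(miss, collapse = ", ")),
                 "csense_alignment_error")
  pred <- pred[species]
  obs <- observed[species]
  if (all(pred == 0))
    csense_error("all predicted species weights are zero; concordance undefined",
                 "csense_concordance_error")
  r_obs <- top_down_correlation(pred, obs)
  perm <- with_seed(rng_seed, {
    vapply(seq_len(permutations), function(i)
      top_down_correlation(pred, stats::setNames(sample(obs),
                                                 names(obs))),
      0)
  })
  list(tdcc = r_obs, n_items = length(species),
       permutation_p = (1 + sum(perm >= r_obs)) / (permutations + 1),
       permuted = perm)
}

concordance_report_multi <- function(pred, observed, permutations,
                                     rng_seed, species = NULL) {
  species <- species %||% intersect(rownames(pred), rownames(observed))
  if (length(species) < 3)
    csense_error("need >= 3 shared species", "csense_alignment_error")
  common <- intersect(colnames(pred), colnames(observed))
  if (length(common) < 1)
    csense_error("no shared samples", "csense_alignment_error")
  P <- pred[species, common, drop = FALSE]
  O <- observed[species, common, drop = FALSE]
  if (all(P == 0))
    csense_error("all predicted species weights are zero; concordance undefined",
                 "csense_concordance_error")
  n <- length(species)
  mean_td <- function(perm) {
    mean(vapply(seq_along(common), function(j) {
      o <- O[perm, j]
      names(o) <- species
      top_down_correlation(P[, j], o)
    }, 0))
  }
  r_obs <- mean_td(seq_len(n))
  per_sample <- vapply(seq_along(common), function(j)
    top_down_correlation(P[, j], O[, j]), 0)
  names(per_sample) <- common
  perm <- with_seed(rng_seed,
    vapply(seq_len(permutations), function(i) mean_td(sample(n)), 0))
  list(tdcc = r_obs, n_items = n,
       permutation_p = (1 + sum(perm >= r_obs)) / (permutations + 1),
       per_sample = per_sample, permuted = perm)
}
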