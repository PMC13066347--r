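## LC-MS feature-table preprocessing: probabilistic quotient
## normalization against a pooled-QC reference, QC-based robust LOESS
## drift/batch correction, and the QC coefficient-of-variation filter.
## Missing values are excluded pairwise, never imputed.

#' Feature table container
#'
#' @param intensities feature x injection numeric matrix (positive or
#'   `NA`), dimnames = feature ids x injection ids.
#' @param injections data.frame with columns `injection_id`,
#'   `sample_id`, `order` (integer, unique within batch), `batch`,
#'   `is_qc`.
#' @param features data.frame with columns `feature_id` and optionally
#'   `metabolite_id`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(intensities, injections, features = NULL) {
  need <- c("injection_id", "sample_id", "order", "batch", "is_qc")
  miss <- setdiff(need, names(injections))
  if (length(miss))
    csense_error(paste0("injections missing column(s): ",
                        paste(miss, collapse = ", ")),
                 "csense_format_error")
  if (ncol(intensities) != nrow(injections))
    csense_error("intensity columns must match injection rows",
                 "csense_format_error")
  if (is.null(colnames(intensities)))
    colnames(intensities) <- injections$injection_id
  if (!identical(colnames(intensities), injections$injection_id))
    csense_error("intensity column names must equal injection ids",
                 "csense_format_error")
  for (b in unique(injections$batch)) {
    o <- injections$order[injections$batch == b]
    if (anyDuplicated(o))
      csense_error(paste0("duplicate injection order in batch ", b),
                   "csense_invariant_error")
  }
  if (is.null(features))
    features <- data.frame(feature_id = rownames(intensities),
                           metabolite_id = NA_character_)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- features$feature_id
  structure(list(intensities = intensities, injections = injections,
                 features = features),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", nrow(x$intensities), "features x",
      ncol(x$intensities), "injections (",
      sum(x$injections$is_qc), "QC,",
      length(unique(x$injections$batch)), "batch(es))\n")
  invisible(x)
}

qc_columns <- function(table) which(table$injections$is_qc)

#' Probabilistic quotient normalization
#'
#' The reference vector is the feature-wise mean over all QC
#' injections.  For each injection, quotients `x_f / r_f` are formed
#' over features with a positive reference and a present value, and the
#' injection is divided by the median quotient (its dilution
#' coefficient).  QC injections are normalized identically.
#'
#' @param table a `feature_table` with at least one QC injection.
#' @return list with `table` (normalized) and `coefficients` (named
#'   per-injection median quotients).
#' @export
pqn_normalize <- function(table) {
  qc <- qc_columns(table)
  if (!length(qc))
    csense_error("PQN needs at least one QC injection",
                 "csense_qc_error")
  x <- table$intensities
  ref <- rowMeans(x[, qc, drop = FALSE], na.rm = TRUE)
  usable <- !is.na(ref) & ref > 0
  if (!any(usable))
    csense_error("PQN reference vector is empty", "csense_qc_error")
  coef <- numeric(ncol(x))
  names(coef) <- colnames(x)
  for (s in seq_len(ncol(x))) {
    q <- x[usable, s] / ref[usable]
    c_s <- stats::median(q, na.rm = TRUE)
    if (!is.finite(c_s) || c_s <= 0)
      csense_error(paste0("degenerate PQN coefficient for injection '",
                          colnames(x)[s], "'"),
                   "csense_degenerate_sample_error")
    coef[s] <- c_s
    x[, s] <- x[, s] / c_s
  }
  out <- table
  out$intensities <- x
  list(table = out, coefficients = coef)
}

## Robust smooth of QC intensity vs injection order; constant
## extrapolation beyond the first/last QC.  Falls back from quadratic to
## linear local fits, then to linear interpolation, for very sparse QC.
fit_qc_curve <- function(orders_qc, values_qc, span, eval_orders) {
  eo <- pmin(pmax(eval_orders, min(orders_qc)), max(orders_qc))
  fit <- NULL
  for (deg in c(2L, 1L)) {
    fit <- tryCatch(
      stats::loess(values_qc ~ orders_qc, span = span, degree = deg,
                   family = "symmetric",
                   control = stats::loess.control(surface = "direct",
                                                  iterations = 3L)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    return(stats::approx(orders_qc, values_qc, xout = eo, rule = 2,
                         ties = mean)$y)
  ## direct-surface prediction reports condition numbers on exactly
  ## collinear (e.g. flat) QC profiles; the curve is validated by the
  ## caller, so silence the numeric chatter
  suppressWarnings(
    as.numeric(stats::predict(fit, data.frame(orders_qc = eo))))
}

#' QC-based robust LOESS drift and batch correction
#'
#' Per feature and per batch, a robust locally weighted smoother of QC
#' intensity against injection order is evaluated at every injection's
#' order (constant extrapolation beyond the terminal QCs), and the raw
#' value is rescaled by `median(QC intensity in batch) / curve`.
#' Features with fewer than 3 non-missing QC values in a batch, or a
#' non-positive fitted curve, are passed through unchanged with a
#' warning.
#'
#' @param table a `feature_table`.
#' @param span LOESS span in (0, 1], default 0.75.
#' @return corrected `feature_table`; uncorrected feature/batch pairs
#'   are listed in `attr(, "uncorrected")`.
#' @export
qc_rlsc <- function(table, span = 0.75) {
  if (!is.numeric(span) || span <= 0 || span > 1)
    csense_error("span must be in (0, 1]", "csense_parameter_error")
  x <- table$intensities
  inj <- table$injections
  uncorrected <- character(0)
  for (b in unique(inj$batch)) {
    cols <- which(inj$batch == b)
    qc_cols <- cols[inj$is_qc[cols]]
    if (length(qc_cols) < 3)
      csense_error(paste0("batch ", b, " has fewer than 3 QC injections"),
                   "csense_qc_error")
    ord <- inj$order[cols]
    qc_ord <- inj$order[qc_cols]
    for (f in seq_len(nrow(x))) {
      v_qc <- x[f, qc_cols]
      ok <- !is.na(v_qc)
      if (sum(ok) < 3) {
        uncorrected <- c(uncorrected,
                         paste0(rownames(x)[f], "@", b, ":sparse-qc"))
        next
      }
      curve <- fit_qc_curve(qc_ord[ok], v_qc[ok], span, ord)
      if (any(!is.finite(curve)) || any(curve <= 0)) {
        uncorrected <- c(uncorrected,
                         paste0(rownames(x)[f], "@", b,
                                ":nonpositive-curve"))
        next
      }
      x[f, cols] <- x[f, cols] * stats::median(v_qc[ok]) / curve
    }
  }
  if (length(uncorrected))
    warning(length(uncorrected),
            " feature/batch pair(s) passed through uncorrected")
  out <- table
  out$intensities <- x
  attr(out, "uncorrected") <- uncorrected
  out
}

#' QC coefficient-of-variation filter
#'
#' Per feature, `CV = 100 * sd / mean` over QC injections (sample
#' standard deviation, pairwise-complete).  Features with CV above the
#' cutoff are removed, as are features with non-positive QC mean;
#' features with fewer than 2 usable QC values are kept (CV not
#' assessable) with a warning.
#'
#' @param table a `feature_table` with >= 2 QC injections.
#' @param cutoff_percent CV threshold in percent, default 30.
#' @return list with `table` (kept features), `removed` (data.frame
#'   `feature_id`, `cv`, `reason`), and `cv` (named per-feature CVs).
#' @export
cv_filter <- function(table, cutoff_percent = 30) {
  qc <- qc_columns(table)
  if (length(qc) < 2)
    csense_error("CV filter needs >= 2 QC injections", "csense_qc_error")
  x <- table$intensities[, qc, drop = FALSE]
  m <- rowMeans(x, na.rm = TRUE)
  s <- apply(x, 1, stats::sd, na.rm = TRUE)
  nok <- rowSums(!is.na(x))
  cv <- ifelse(m > 0, 100 * s / m, NA_real_)
  names(cv) <- rownames(table$intensities)
  reason <- rep(NA_character_, length(cv))
  reason[!is.na(m) & m <= 0] <- "nonpositive-mean"
  reason[is.na(reason) & nok >= 2 & cv > cutoff_percent] <- "high-cv"
  if (any(nok < 2)) {
    warning(sum(nok < 2), " feature(s) with < 2 QC values kept unassessed")
  }
  drop <- !is.na(reason)
  removed <- data.frame(feature_id = names(cv)[drop],
                        cv = unname(cv[drop]),
                        reason = reason[drop])
  out <- table
  out$intensities <- table$intensities[!drop, , drop = FALSE]
  out$features <- table$features[!drop, , drop = FALSE]
  list(table = out, removed = removed, cv = cv)
}

#' Full preprocessing chain
#'
#' Applies, in order, the steps requested (default PQN then QC-RLSC
#' then the CV filter) and records the applied order as a provenance
#' attribute on the result.
#'
#' @param table a `feature_table`.
#' @param steps subset of `c("pqn", "rlsc", "cv")`, applied in the
#'   order given.
#' @param cv_cutoff CV threshold in percent, default 30.
#' @param span LOESS span for QC-RLSC, default 0.75.
#' @return list with `table`, `coefficients` (PQN, or `NULL`),
#'   `removed` (CV filter, or `NULL`); `attr(, "provenance")` records
#'   the step order and parameters.
#' @export
prep_metabolome <- function(table, steps = c("pqn", "rlsc", "cv"),
                            cv_cutoff = 30, span = 0.75) {
  steps <- match.arg(steps, c("pqn", "rlsc", "cv"), several.ok = TRUE)
  coefficients <- NULL
  removed <- NULL
  for (st in steps) {
    if (st == "pqn") {
      r <- pqn_normalize(table)
      table <- r$table
      coefficients <- r$coefficients
    } else if (st == "rlsc") {
      table <- qc_rlsc(table, span = span)
    } else {
      r <- cv_filter(table, cutoff_percent = cv_cutoff)
      table <- r$table
      removed <- r$removed
    }
  }
  out <- list(table = table, coefficients = coefficients,
              removed = removed)
  attr(out, "provenance") <- list(order = steps, cv_cutoff = cv_cutoff,
                                  span = span)
  out
}

#' Read / write feature tables
#'
#' `features.tsv`: features as rows, injections as columns, first
#' column `feature_id`.  `injections.tsv`: columns `injection_id`,
#' `sample_id`, `order`, `batch`, `is_qc`.
#'
#' @param features_path,injections_path TSV paths.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(features_path, injections_path) {
  f <- utils::read.table(features_path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  inj <- utils::read.table(injections_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (names(f)[1] != "feature_id")
    csense_error("first column of features.tsv must be feature_id",
                 "csense_format_error")
  m <- as.matrix(f[, -1, drop = FALSE])
  rownames(m) <- f$feature_id
  inj$is_qc <- as.logical(inj$is_qc)
  feature_table(m[, inj$injection_id, drop = FALSE], inj)
}

#' @rdname read_feature_table
#' @param table a `feature_table`.
#' @param dir output directory.
#' @export
write_feature_table <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(feature_id = rownames(table$intensities),
                   table$intensities, check.names = FALSE)
  utils::write.table(df, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(table$injections, file.path(dir, "injections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
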