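## Metabolic model container and flux balance analysis.
##
## Models follow the COBRA sign convention: every exchange reaction
## touches exactly one metabolite with coefficient -1, so negative
## exchange flux is uptake and positive flux is secretion.  The biomass
## reaction is the single objective and its optimal flux is the growth
## rate (1/h).

#' Construct a metabolic model
#'
#' @param id model identifier (usually the species/strain id).
#' @param metabolites data.frame with columns `id`, `name`,
#'   `is_external` (logical; external metabolites are the exchangeable
#'   compounds at the community boundary).
#' @param reactions list of reactions; each a list with fields `id`,
#'   `stoichiometry` (named numeric, metabolite id -> coefficient),
#'   `lb`, `ub` (flux bounds, mmol/gDW/h), `is_objective`,
#'   `is_exchange`, and `exchange_metabolite` (id or `NA`).
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions) {
  m <- structure(list(id = id, metabolites = metabolites,
                      reactions = reactions),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' @noRd
validate_model <- function(m) {
  if (!is.data.frame(m$metabolites) ||
      !all(c("id", "name", "is_external") %in% names(m$metabolites)))
    csense_error("metabolites must have columns id, name, is_external",
                 "csense_format_error")
  met_ids <- m$metabolites$id
  if (anyDuplicated(met_ids))
    csense_error("duplicate metabolite ids", "csense_invariant_error")
  n_obj <- 0L
  for (r in m$reactions) {
    need <- c("id", "stoichiometry", "lb", "ub", "is_objective",
              "is_exchange")
    miss <- setdiff(need, names(r))
    if (length(miss))
      csense_error(paste0("reaction '", r$id %||% "?",
                          "' missing field(s): ",
                          paste(miss, collapse = ", ")),
                   "csense_format_error")
    if (r$lb > r$ub)
      csense_error(paste0("reaction '", r$id, "': lb > ub"),
                   "csense_invariant_error")
    bad <- setdiff(names(r$stoichiometry), met_ids)
    if (length(bad))
      csense_error(paste0("reaction '", r$id, "': unknown metabolite(s) ",
                          paste(bad, collapse = ", ")),
                   "csense_format_error")
    if (isTRUE(r$is_objective)) n_obj <- n_obj + 1L
    if (isTRUE(r$is_exchange)) {
      s <- r$stoichiometry
      if (length(s) != 1L || abs(s[[1]] + 1) > 1e-12)
        csense_error(paste0("exchange reaction '", r$id,
                            "' must touch exactly one metabolite with ",
                            "coefficient -1"),
                     "csense_invariant_error")
      if (is.null(r$exchange_metabolite) ||
          is.na(r$exchange_metabolite) ||
          !identical(r$exchange_metabolite, names(s)[1]))
        csense_error(paste0("exchange reaction '", r$id,
                            "': exchange_metabolite must name its single ",
                            "metabolite"),
                     "csense_invariant_error")
    }
  }
  if (n_obj != 1L)
    csense_error(paste0("model must have exactly one objective reaction, ",
                        "found ", n_obj),
                 "csense_invariant_error")
  rxn_ids <- vapply(m$reactions, `[[`, "", "id")
  if (anyDuplicated(rxn_ids))
    csense_error("duplicate reaction ids", "csense_invariant_error")
  invisible(m)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", length(x$reactions),
      " exchanges:",
      sum(vapply(x$reactions, function(r) isTRUE(r$is_exchange), TRUE)),
      "\n")
  invisible(x)
}

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

#' Exchange reaction lookup
#'
#' Map external metabolite ids to exchange reaction ids.
#' @param model a `metabolic_model`.
#' @return named character vector, metabolite id -> reaction id.
#' @export
exchange_map <- function(model) {
  ex <- Filter(function(r) isTRUE(r$is_exchange), model$reactions)
  stats::setNames(vapply(ex, `[[`, "", "id"),
                  vapply(ex, `[[`, "", "exchange_metabolite"))
}

#' Stoichiometric matrix
#'
#' @param model a `metabolic_model`.
#' @return metabolites x reactions numeric matrix.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- reaction_ids(model)
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  for (j in seq_along(model$reactions)) {
    s <- model$reactions[[j]]$stoichiometry
    S[names(s), j] <- as.numeric(s)
  }
  S
}

#' Read a metabolic model from JSON
#'
#' JSON schema: `{"id", "metabolites":[{"id","name","is_external"}],
#' "reactions":[{"id","stoichiometry":{...},"lb","ub","is_objective",
#' "is_exchange","exchange_metabolite"}]}`.
#'
#' @param path file path.
#' @return a `metabolic_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("id", "metabolites", "reactions"))
    if (is.null(j[[f]]))
      csense_error(paste0("model JSON missing field '", f, "'"),
                   "csense_format_error")
  mets <- do.call(rbind, lapply(j$metabolites, function(m) {
    for (f in c("id", "name", "is_external"))
      if (is.null(m[[f]]))
        csense_error(paste0("metabolite entry missing field '", f, "'"),
                     "csense_format_error")
    data.frame(id = m$id, name = m$name,
               is_external = isTRUE(m$is_external))
  }))
  rxns <- lapply(j$reactions, function(r) {
    for (f in c("id", "stoichiometry", "lb", "ub", "is_objective",
                "is_exchange"))
      if (is.null(r[[f]]))
        csense_error(paste0("reaction entry missing field '", f, "'"),
                     "csense_format_error")
    list(id = r$id,
         stoichiometry = unlist(r$stoichiometry),
         lb = as.numeric(r$lb), ub = as.numeric(r$ub),
         is_objective = isTRUE(r$is_objective),
         is_exchange = isTRUE(r$is_exchange),
         exchange_metabolite =
           if (is.null(r$exchange_metabolite)) NA_character_
           else r$exchange_metabolite)
  })
  metabolic_model(j$id, mets, rxns)
}

#' Write a metabolic model to JSON
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  j <- list(
    id = model$id,
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i)
      list(id = model$metabolites$id[i],
           name = model$metabolites$name[i],
           is_external = model$metabolites$is_external[i])),
    reactions = lapply(model$reactions, function(r)
      list(id = r$id,
           stoichiometry = as.list(r$stoichiometry),
           lb = r$lb, ub = r$ub,
           is_objective = r$is_objective,
           is_exchange = r$is_exchange,
           exchange_metabolite =
             if (is.na(r$exchange_metabolite %||% NA)) NULL
             else r$exchange_metabolite)))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Flux balance analysis
#'
#' Maximizes the biomass flux subject to steady-state mass balance
#' `S v = 0` and flux bounds.  Growth values below `1e-8` are reported
#' as exactly 0 to stabilize downstream ranks; infeasibility is reported
#' in `status`, never raised.
#'
#' @param model a `metabolic_model`.
#' @param overrides named list, reaction id -> `c(lb, ub)`, replacing
#'   that reaction's bounds for this solve.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `growth`, and `fluxes` (named numeric).
#' @export
solve_fba <- function(model, overrides = list()) {
  rxn_ids <- reaction_ids(model)
  bad <- setdiff(names(overrides), rxn_ids)
  if (length(bad))
    csense_error(paste0("overrides reference unknown reaction(s): ",
                        paste(bad, collapse = ", ")),
                 "csense_format_error")
  lb <- vapply(model$reactions, `[[`, 0, "lb")
  ub <- vapply(model$reactions, `[[`, 0, "ub")
  names(lb) <- names(ub) <- rxn_ids
  for (id in names(overrides)) {
    lb[id] <- overrides[[id]][1]
    ub[id] <- overrides[[id]][2]
  }
  if (any(lb > ub)) {
    return(list(status = "infeasible", growth = NA_real_, fluxes = NULL))
  }
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(vapply(model$reactions, function(r)
    isTRUE(r$is_objective), TRUE))
  sol <- solve_lp(obj, S, rep(0, nrow(S)), lb, ub)
  if (sol$status != "optimal") {
    return(list(status = sol$status, growth = NA_real_, fluxes = NULL))
  }
  growth <- sol$objective
  if (abs(growth) < 1e-8) growth <- 0
  list(status = "optimal", growth = growth,
       fluxes = stats::setNames(sol$x, rxn_ids))
}

#' Growth under pinned uptake capacities
#'
#' Evaluates growth when external metabolite availability forces a
#' diffusion-driven influx: each capacity `u` pins its exchange flux to
#' exactly `-u` (consumption of the full ambient supply).  This is the
#' capacity semantics used by the global sensitivity analysis, under
#' which suppression of growth by a metabolite (a toxin whose disposal
#' costs resources) is expressible; a pure lower-bound relaxation can
#' never reduce an LP optimum.
#'
#' @param model a `metabolic_model`.
#' @param capacities named numeric, external metabolite id -> capacity
#'   (mmol/gDW/h, >= 0).
#' @return growth rate; 0 if the forced environment is infeasible.
#' @export
growth_at_capacity <- function(model, capacities) {
  ex <- exchange_map(model)
  bad <- setdiff(names(capacities), names(ex))
  if (length(bad))
    csense_error(paste0("no exchange reaction for metabolite(s): ",
                        paste(bad, collapse = ", ")),
                 "csense_config_error")
  ov <- lapply(capacities, function(u) c(-u, -u))
  names(ov) <- ex[names(capacities)]
  sol <- solve_fba(model, ov)
  if (sol$status != "optimal") 0 else sol$growth
}
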