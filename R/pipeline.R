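## One-command orchestration: models + abundance + metabolite
## environment -> GSA -> sensitivity graph -> propagation -> top-down
## concordance, with provenance.

#' Build and validate a pipeline configuration
#'
#' @param models_dir directory of model JSON files.
#' @param abundance_path abundance TSV (samples x species, first column
#'   `sample_id`).
#' @param environment_path metabolite TSV (metabolites x samples,
#'   first column `metabolite_id`).
#' @param gsa list: `n_samples`, `alpha`, `adjust`, `range`, `seed`.
#' @param propagation list: `restart`, `clamp`, `absorbing`, `tol`,
#'   `max_iter`, `mode`, `top_n`.
#' @param tdcc list: `permutations`, `seed`.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(models_dir, abundance_path,
                            environment_path,
                            gsa = list(), propagation = list(),
                            tdcc = list()) {
  defaults <- list(
    gsa = list(n_samples = 200L, alpha = 0.1, adjust = "none",
               range = c(0, 10), seed = 1L),
    propagation = list(restart = 0.3, clamp = "on", absorbing = FALSE,
                       tol = 1e-8, max_iter = 10000L,
                       mode = "environment", top_n = 10L),
    tdcc = list(permutations = 99L, seed = 1L))
  merge_cfg <- function(user, def, where) {
    unknown <- setdiff(names(user), names(def))
    if (length(unknown))
      csense_error(paste0("unknown ", where, " option(s): ",
                          paste(unknown, collapse = ", ")),
                   "csense_validation_error")
    utils::modifyList(def, user)
  }
  cfg <- list(models_dir = models_dir,
              abundance_path = abundance_path,
              environment_path = environment_path,
              gsa = merge_cfg(gsa, defaults$gsa, "gsa"),
              propagation = merge_cfg(propagation, defaults$propagation,
                                      "propagation"),
              tdcc = merge_cfg(tdcc, defaults$tdcc, "tdcc"))
  if (cfg$gsa$alpha <= 0 || cfg$gsa$alpha >= 1)
    csense_error("gsa$alpha must be in (0, 1)",
                 "csense_validation_error")
  if (!cfg$gsa$adjust %in% c("none", "bh"))
    csense_error("gsa$adjust must be 'none' or 'bh'",
                 "csense_validation_error")
  if (cfg$propagation$restart <= 0 || cfg$propagation$restart > 1)
    csense_error("propagation$restart must be in (0, 1]",
                 "csense_validation_error")
  if (!cfg$propagation$mode %in% c("environment", "species"))
    csense_error("propagation$mode must be 'environment' or 'species'",
                 "csense_validation_error")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file (JSON or YAML)
#' @param path config file; `.yaml`/`.yml` requires the yaml package.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      csense_error("yaml package required for YAML configs",
                   "csense_validation_error")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("models_dir", "abundance_path", "environment_path",
             "gsa", "propagation", "tdcc")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    csense_error(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 "csense_validation_error")
  do.call(pipeline_config, raw)
}

#' Run the full analysis
#'
#' GSA on every model, graph assembly, per-sample propagation from the
#' metabolite environment (or top-N species counts), and top-down
#' concordance against the observed abundances.  Writes `edges.tsv`,
#' `graph.tsv`, `state.tsv` (last sample), `tdcc.json`, `run.log`, and
#' `provenance.json` into `out_dir`.  Reruns with identical config are
#' bit-identical except timestamps.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created).
#' @return list with `graph`, per-sample `states` and `concordance`,
#'   and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(expr, error = function(e)
      stop(name, ": ", conditionMessage(e), call. = FALSE))
    logf(name, " done in ", round(proc.time()[["elapsed"]] - t0, 2),
         "s")
    r
  }

  models <- stage("load-models", {
    paths <- list.files(config$models_dir, pattern = "\\.json$",
                        full.names = TRUE)
    if (!length(paths)) csense_error("no model JSON files found",
                                     "csense_validation_error")
    lapply(sort(paths), read_model)
  })
  abundance <- stage("load-abundance",
    utils::read.table(config$abundance_path, sep = "\t", header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE))
  environment_tab <- stage("load-environment",
    utils::read.table(config$environment_path, sep = "\t",
                      header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE))

  gsa_cfg <- config$gsa
  results <- stage("gsa", {
    seeds <- derive_seeds(gsa_cfg$seed, length(models))
    lapply(seq_along(models), function(i)
      run_gsa(models[[i]],
              default_design(models[[i]], gsa_cfg$n_samples,
                             range = gsa_cfg$range,
                             rng_seed = seeds[i])))
  })
  graph <- stage("graph",
    build_graph(results, alpha = gsa_cfg$alpha,
                adjust = gsa_cfg$adjust))
  edges_path <- file.path(out_dir, "edges.tsv")
  all_edges <- do.call(rbind, lapply(results, function(r)
    cbind(species_id = r$species_id, r$table,
          n_samples = r$n_samples)))
  utils::write.table(all_edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_edges(graph, file.path(out_dir, "graph.tsv"))

  samples <- abundance$sample_id
  prop_cfg <- config$propagation
  td_cfg <- config$tdcc
  states <- list()
  conc <- list()
  td_seeds <- derive_seeds(td_cfg$seed, length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    seeds <- if (prop_cfg$mode == "environment")
      seed_from_environment(environment_tab, s, graph = graph)
    else
      seed_from_abundance(abundance, s, top_n = prop_cfg$top_n)
    st <- stage(paste0("propagate:", s),
      propagate(graph, seeds, restart = prop_cfg$restart,
                clamp = prop_cfg$clamp, tol = prop_cfg$tol,
                max_iter = prop_cfg$max_iter,
                absorbing = isTRUE(prop_cfg$absorbing)))
    states[[s]] <- st
    obs <- unlist(abundance[abundance$sample_id == s,
                            setdiff(names(abundance), "sample_id")])
    sp <- intersect(names(obs),
                    graph$nodes$id[graph$nodes$kind == "species"])
    conc[[s]] <- stage(paste0("tdcc:", s),
      concordance_report(st, obs, permutations = td_cfg$permutations,
                         rng_seed = td_seeds[i], species = sp))
  }
  write_state(states[[length(states)]], graph,
              file.path(out_dir, "state.tsv"))
  td_out <- lapply(conc, function(z)
    z[c("tdcc", "n_items", "permutation_p")])
  jsonlite::write_json(td_out, file.path(out_dir, "tdcc.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(config = unclass(config),
               package_version =
                 as.character(utils::packageVersion("csense")),
               r_version = R.version.string,
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete")
  invisible(list(graph = graph, states = states, concordance = conc,
                 out_dir = out_dir))
}
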