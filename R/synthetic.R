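## Seeded synthetic-data generators.  These stand in for resources the
## analysis normally consumes (curated genome-scale reconstructions,
## shotgun abundance tables, LC-MS runs) and carry known ground truth so
## every downstream stage can be tested.

#' Build a toy metabolic model with designed metabolite dependencies
#'
#' The model grows on a set of required external metabolites (Leontief
#' style: biomass needs a dedicated precursor from each, so growth is 0
#' whenever any required uptake capacity is 0) and is inhibited by
#' toxin-like metabolites whose forced influx must be detoxified at a
#' stoichiometric cost drained from the first required metabolite's
#' precursor pool -- a maintenance-cost stand-in for regulatory
#' inhibition, which plain FBA cannot express.  Unused substrate and
#' inert metabolites exit through free overflow reactions.
#'
#' Per-metabolite assimilation yields (log-uniform 0.8--1.25) and detox
#' costs (0.2--0.8) are drawn from `rng_seed`; the yield of metabolite `m` is
#' stored as the precursor coefficient of reaction `UP_<m>`.
#'
#' @param species_id identifier for the species/strain.
#' @param required_mets character, metabolites required for growth
#'   (1--10).
#' @param inhibitory_mets character, growth-suppressing metabolites
#'   (0--10); must not overlap `required_mets`.
#' @param rng_seed integer seed.
#' @param inert_mets character, exchangeable metabolites with no effect
#'   on growth.
#' @return a `metabolic_model`.
#' @export
make_toy_model <- function(species_id, required_mets,
                           inhibitory_mets = character(),
                           rng_seed = 1L,
                           inert_mets = character()) {
  required_mets <- as.character(required_mets)
  inhibitory_mets <- as.character(inhibitory_mets)
  inert_mets <- as.character(inert_mets)
  if (length(required_mets) < 1L || length(required_mets) > 10L)
    csense_error("required_mets must have 1..10 entries",
                 "csense_spec_error")
  if (length(inhibitory_mets) > 10L)
    csense_error("inhibitory_mets must have <= 10 entries",
                 "csense_spec_error")
  if (length(intersect(required_mets,
                       c(inhibitory_mets, inert_mets))) > 0L ||
      length(intersect(inhibitory_mets, inert_mets)) > 0L)
    csense_error("required, inhibitory and inert metabolite lists overlap",
                 "csense_spec_error")

  with_seed(rng_seed, {
    ## log-symmetric around 1 and deliberately narrow: with a Leontief
    ## biomass, a substrate arm whose yield dwarfs its siblings almost
    ## never limits growth and its designed dependency would be
    ## statistically invisible -- the truth table must stay recoverable
    yields <- stats::setNames(
      exp(stats::runif(length(required_mets), log(0.8), log(1.25))),
      required_mets)
    costs <- stats::setNames(stats::runif(length(inhibitory_mets), 0.2, 0.8),
                             inhibitory_mets)
    ext <- c(required_mets, inhibitory_mets, inert_mets)
    prec <- paste0("prec_", required_mets)
    mets <- data.frame(
      id = c(ext, prec),
      name = c(ext, paste("precursor from", required_mets)),
      is_external = c(rep(TRUE, length(ext)), rep(FALSE, length(prec))))

    rxns <- list()
    for (m in ext) {
      rxns[[length(rxns) + 1L]] <- list(
        id = paste0("EX_", m),
        stoichiometry = stats::setNames(-1, m),
        lb = -10, ub = 1000,
        is_objective = FALSE, is_exchange = TRUE,
        exchange_metabolite = m)
    }
    for (m in required_mets) {
      rxns[[length(rxns) + 1L]] <- list(
        id = paste0("UP_", m),
        stoichiometry = stats::setNames(c(-1, yields[[m]]),
                                        c(m, paste0("prec_", m))),
        lb = 0, ub = 1000,
        is_objective = FALSE, is_exchange = FALSE,
        exchange_metabolite = NA_character_)
    }
    ## overflow valves: forced influx beyond need must have a sink
    for (m in c(required_mets, inert_mets)) {
      rxns[[length(rxns) + 1L]] <- list(
        id = paste0("OF_", m),
        stoichiometry = stats::setNames(-1, m),
        lb = 0, ub = 1000,
        is_objective = FALSE, is_exchange = FALSE,
        exchange_metabolite = NA_character_)
    }
    energy_prec <- paste0("prec_", required_mets[1])
    for (m in inhibitory_mets) {
      rxns[[length(rxns) + 1L]] <- list(
        id = paste0("DETOX_", m),
        stoichiometry = stats::setNames(c(-1, -costs[[m]]),
                                        c(m, energy_prec)),
        lb = 0, ub = 1000,
        is_objective = FALSE, is_exchange = FALSE,
        exchange_metabolite = NA_character_)
    }
    rxns[[length(rxns) + 1L]] <- list(
      id = "BIOMASS",
      stoichiometry = stats::setNames(rep(-1, length(prec)), prec),
      lb = 0, ub = 1000,
      is_objective = TRUE, is_exchange = FALSE,
      exchange_metabolite = NA_character_)

    metabolic_model(species_id, mets, rxns)
  })
}

#' Metabolite dependency classes of a toy model
#' @param model a `metabolic_model` from [make_toy_model()].
#' @return list with `required`, `inhibitory`, `inert` metabolite ids
#'   and the named `yields`/`costs` coefficients.
#' @export
toy_model_truth <- function(model) {
  rxn <- reaction_ids(model)
  req <- sub("^UP_", "", grep("^UP_", rxn, value = TRUE))
  inh <- sub("^DETOX_", "", grep("^DETOX_", rxn, value = TRUE))
  ext <- model$metabolites$id[model$metabolites$is_external]
  yields <- vapply(req, function(m) {
    r <- model$reactions[[which(rxn == paste0("UP_", m))]]
    r$stoichiometry[[paste0("prec_", m)]]
  }, 0)
  costs <- vapply(inh, function(m) {
    r <- model$reactions[[which(rxn == paste0("DETOX_", m))]]
    -r$stoichiometry[[2]]
  }, 0)
  list(required = req, inhibitory = inh,
       inert = setdiff(ext, c(req, inh)),
       yields = yields, costs = costs)
}

#' Generate a community scenario with known species-metabolite truth
#'
#' Builds one toy model per species (1--2 required metabolites and,
#' with probability 1/2, one inhibitory metabolite, drawn from a shared
#' pool), a per-sample metabolite environment (symmetric Dirichlet), and
#' per-sample species abundances through a log-linear fitness link:
#' abundance is proportional to `exp(beta * mu)`, where `mu` is the
#' species' FBA growth rate when every exchange capacity is
#' proportional to the metabolite's environmental abundance
#' (`capacity = 5 * n_mets * environment`).  Species whose required
#' metabolites are plentiful -- and whose inhibitors are scarce --
#' dominate a sample, consistently with the growth truth planted in the
#' models.  The link is deterministic given the environment; all
#' sampling noise enters through the single seeded generator.
#'
#' Models contain exchanges only for their true dependency metabolites;
#' inert-exchange behaviour is exercised separately via
#' [make_toy_model()]'s `inert_mets`.
#'
#' @param n_species number of species (>= 2).
#' @param n_mets number of metabolites (>= n_species).
#' @param n_samples number of community samples.
#' @param rng_seed integer seed.
#' @param beta strength of the abundance/environment link (default 1).
#' @return list of class `community_scenario`: `models`,
#'   `dependency_truth` (data.frame metabolite_id, species_id, sign,
#'   mode), `abundance` (samples x species, rows sum to 1),
#'   `environment` (samples x metabolites, rows sum to 1), `rng_seed`.
#' @export
make_community_scenario <- function(n_species, n_mets, n_samples,
                                    rng_seed = 1L, beta = 1) {
  if (!is_count(n_species, 2))
    csense_error("n_species must be >= 2", "csense_spec_error")
  if (!is_count(n_mets, n_species))
    csense_error("n_mets must be >= n_species", "csense_spec_error")
  if (!is_count(n_samples, 1))
    csense_error("n_samples must be >= 1", "csense_spec_error")

  with_seed(rng_seed, {
    mets <- sprintf("met%02d", seq_len(n_mets))
    species <- sprintf("sp%02d", seq_len(n_species))
    model_seeds <- sample.int(.Machine$integer.max - 1L, n_species)

    truth <- list()
    models <- vector("list", n_species)
    names(models) <- species
    for (i in seq_len(n_species)) {
      n_req <- sample(1:2, 1)
      req <- sample(mets, n_req)
      pool <- setdiff(mets, req)
      inh <- if (stats::runif(1) < 0.5 && length(pool) > 0)
        sample(pool, 1) else character()
      models[[i]] <- make_toy_model(species[i], req, inh,
                                    rng_seed = model_seeds[i])
      truth[[length(truth) + 1L]] <- data.frame(
        metabolite_id = c(req, inh),
        species_id = species[i],
        sign = c(rep(1, length(req)), rep(-1, length(inh))),
        mode = "uptake")
    }
    truth <- do.call(rbind, truth)

    env <- matrix(stats::rgamma(n_samples * n_mets, shape = 1),
                  n_samples, n_mets, dimnames = list(
                    sprintf("S%02d", seq_len(n_samples)), mets))
    env <- env / rowSums(env)

    ## fitness link: growth of each model in the sample's environment,
    ## with exchange capacity proportional to metabolite abundance
    ab <- matrix(0, n_samples, n_species,
                 dimnames = list(rownames(env), species))
    for (s in seq_len(n_samples)) {
      mu <- vapply(models, function(m) {
        mets <- names(exchange_map(m))
        growth_at_capacity(m, stats::setNames(
          5 * n_mets * env[s, mets], mets))
      }, 0)
      w <- exp(beta * mu)
      ab[s, ] <- w / sum(w)
    }

    structure(list(models = models, dependency_truth = truth,
                   abundance = ab, environment = env,
                   rng_seed = rng_seed, beta = beta),
              class = "community_scenario")
  })
}

#' Generate a synthetic LC-MS run with planted dilution and drift
#'
#' Observed intensity is exactly
#' `concentration * dilution * drift(order) * noise`, with pooled-QC
#' injections sharing one concentration profile (the feature-wise mean
#' of the sample profiles, emulating equal-volume pooling) at dilution
#' 1.  QC injections are interleaved evenly across the injection order;
#' batches split the order range into contiguous blocks.
#'
#' Defaults plant a linear drift `1 + 0.02 * order` and a per-sample
#' dilution `exp(U(-0.7, 0.7))` (about 0.5--2 fold, a realistic range
#' for stool extracts); multiplicative log-normal noise has coefficient
#' of variation `noise_cv`.
#'
#' @param n_features number of metabolite features.
#' @param n_samples number of biological samples (one injection each).
#' @param n_qc number of pooled-QC injections (>= 3).
#' @param noise_cv multiplicative noise CV (0 disables noise).
#' @param rng_seed integer seed.
#' @param n_batches number of contiguous batches (each needs >= 3 QC).
#' @param drift_slope slope of the linear drift (0 disables drift).
#' @param dilution_log_range half-width of the log-uniform dilution
#'   (0 disables dilution).
#' @return list of class `lcms_scenario`: `true_concentrations`
#'   (features x samples), `dilution` (per sample), `drift` (per
#'   injection), `batch`, `qc_flags`, `table` (a [feature_table()]),
#'   `rng_seed`.
#' @export
make_lcms_scenario <- function(n_features, n_samples, n_qc,
                               noise_cv = 0.05, rng_seed = 1L,
                               n_batches = 1L, drift_slope = 0.02,
                               dilution_log_range = 0.7) {
  if (!is_count(n_qc, 3))
    csense_error("n_qc must be >= 3 (QC-RLSC needs >= 3 anchors)",
                 "csense_spec_error")
  if (!is_count(n_features, 1) || !is_count(n_samples, 1))
    csense_error("n_features and n_samples must be positive counts",
                 "csense_spec_error")
  if (noise_cv < 0)
    csense_error("noise_cv must be >= 0", "csense_spec_error")

  with_seed(rng_seed, {
    n_inj <- n_samples + n_qc
    ## even interleaving of QC positions, endpoints included
    qc_pos <- unique(round(seq(1, n_inj, length.out = n_qc)))
    while (length(qc_pos) < n_qc) {   # collision fix for tiny runs
      qc_pos <- sort(union(qc_pos, setdiff(seq_len(n_inj), qc_pos)[1]))
    }
    is_qc <- seq_len(n_inj) %in% qc_pos

    feature_ids <- sprintf("F%04d", seq_len(n_features))
    sample_ids <- sprintf("S%02d", seq_len(n_samples))
    base <- exp(stats::rnorm(n_features, mean = log(1e5), sd = 1))
    conc <- base * exp(matrix(stats::rnorm(n_features * n_samples,
                                           sd = 0.5),
                              n_features, n_samples))
    dimnames(conc) <- list(feature_ids, sample_ids)
    qc_profile <- rowMeans(conc)

    dilution <- stats::setNames(
      exp(stats::runif(n_samples, -dilution_log_range,
                       dilution_log_range)),
      sample_ids)
    order <- seq_len(n_inj)
    drift <- 1 + drift_slope * order
    if (any(drift <= 0))
      csense_error("drift must stay positive over the run",
                   "csense_spec_error")
    batch <- if (n_batches == 1L) rep("B1", n_inj)
             else paste0("B", cut(order, n_batches, labels = FALSE))
    if (min(table(batch[is_qc])) < 3 && n_batches > 1)
      csense_error("each batch needs >= 3 QC injections",
                   "csense_spec_error")

    inj_sample <- character(n_inj)
    inj_sample[!is_qc] <- sample_ids
    inj_sample[is_qc] <- "QC"
    injection_id <- sprintf("inj%03d", order)

    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    noise <- if (sdlog > 0)
      exp(matrix(stats::rnorm(n_features * n_inj, sd = sdlog),
                 n_features, n_inj))
    else matrix(1, n_features, n_inj)

    obs <- matrix(0, n_features, n_inj,
                  dimnames = list(feature_ids, injection_id))
    for (k in seq_len(n_inj)) {
      prof <- if (is_qc[k]) qc_profile else conc[, inj_sample[k]]
      dil <- if (is_qc[k]) 1 else dilution[[inj_sample[k]]]
      obs[, k] <- prof * dil * drift[k] * noise[, k]
    }

    injections <- data.frame(injection_id = injection_id,
                             sample_id = inj_sample,
                             order = order, batch = batch,
                             is_qc = is_qc)
    features <- data.frame(feature_id = feature_ids,
                           metabolite_id = NA_character_)
    tab <- feature_table(obs, injections, features)

    structure(list(true_concentrations = conc,
                   qc_profile = qc_profile,
                   dilution = dilution, drift = drift,
                   batch = batch, qc_flags = is_qc,
                   noise_cv = noise_cv, table = tab,
                   rng_seed = rng_seed),
              class = "lcms_scenario")
  })
}

#' Write a community scenario to a directory
#'
#' Writes one model JSON per species, `abundance.tsv` (samples x
#' species), `environment.tsv` (metabolites x samples, first column
#' `metabolite_id`), and `truth.json`.
#'
#' @param scenario a `community_scenario`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mdir <- file.path(dir, "models")
  dir.create(mdir, showWarnings = FALSE)
  for (m in scenario$models)
    write_model(m, file.path(mdir, paste0(m$id, ".json")))
  ab <- data.frame(sample_id = rownames(scenario$abundance),
                   scenario$abundance, check.names = FALSE)
  utils::write.table(ab, file.path(dir, "abundance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  env <- data.frame(metabolite_id = colnames(scenario$environment),
                    t(scenario$environment), check.names = FALSE)
  utils::write.table(env, file.path(dir, "environment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(scenario$dependency_truth,
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
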