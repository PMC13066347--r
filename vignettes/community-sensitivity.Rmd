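---
title: "Predicting microbial community structure from the metabolic environment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microbial community structure from the metabolic environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csense)
```

## The problem

Gut microbial communities are shaped by exo-metabolites: small molecules
that community members secrete and consume, and through which they feed
or poison one another. Given (i) metabolic reconstructions of the
member species and (ii) a measured metabolite profile of the
environment, can we predict which species the community will favour --
and check that prediction against shotgun-metagenomic abundances?

`csense` implements this analysis as four composable stages plus the
LC-MS preprocessing needed to obtain a usable metabolite profile in the
first place:

1. **FBA** -- growth of each species is the optimum of a linear
   program: maximize the biomass flux $v_{bio}$ subject to steady-state
   mass balance $S\,v = 0$ and flux bounds (COBRA sign convention:
   negative exchange flux is uptake).
2. **Global sensitivity analysis** -- Latin-hypercube sampling of
   exchange capacities; for each species and metabolite, the partial
   rank correlation coefficient (PRCC) between capacity and growth,
   with a t-based two-sided p-value at $df = K - 2 - (p - 1)$.
3. **Sensitivity graph** -- significant coefficients become the edges
   of a signed, weighted, directed bipartite graph. Uptake
   dependencies point metabolite $\to$ species, production
   dependencies species $\to$ metabolite; a negative weight means
   growth is suppressed as the metabolite becomes more available.
4. **Propagation and concordance** -- a random-walk-with-restart
   kernel, extended to signed directed edges, spreads seed weights
   until convergence:
   $x \leftarrow (1-r)\,P^{\mathsf T}x + r\,s$, where $P$ is the
   out-degree-normalized signed operator. Negative node weights are
   clamped to zero (extinction / full consumption). Metabolite
   profiles act as pinned boundary conditions in *environment* mode.
   Predicted species weights are compared against observed abundances
   with the top-down concordance coefficient (TDCC) on Savage scores,
   $S_i = \sum_{j=i}^n 1/j$, so agreement among abundant species
   counts more than agreement in the noisy tail.

## Why forced influx in the sensitivity analysis

A subtle but load-bearing choice. If an uptake capacity $u$ only
*relaxes* the exchange lower bound ($lb = -u$, $ub = 0$), then by LP
duality growth is non-decreasing in $u$, and no metabolite could ever
carry a negative coefficient -- yet suppression of growth by a
metabolite is half the point of a signed graph. `run_gsa()` therefore
interprets capacity as concentration-driven *forced* influx and pins
the exchange flux to exactly $-u$. Toxin-like metabolites whose
disposal costs resources then show up with negative PRCCs, required
substrates with positive ones, and inert compounds with none.
`solve_fba()` itself is agnostic: arbitrary bound overrides remain
available, and the monotone-under-relaxation property is part of the
test suite.

## The synthetic stated world

No public data accompany the analysis this package operationalizes, so
`csense` ships generators whose ground truth is known by construction.

**Toy metabolic models** (`make_toy_model()`). Growth is Leontief in
the required metabolites: each contributes a dedicated biomass
precursor, so growth is zero whenever any required substrate is absent
and equals $\min_i(y_i u_i)$ minus detoxification costs otherwise.
Assimilation yields $y_i$ are drawn log-uniformly from $[0.8, 1.25]$:
deliberately narrow, because an arm whose yield dwarfs its siblings
almost never limits growth and its designed dependency would be
statistically invisible -- the generator must keep its own truth table
recoverable. Inhibition is a maintenance-cost drain (0.2--0.8 units of
the first required precursor per unit toxin), a stand-in for
regulatory inhibition that plain FBA cannot express; this is a
documented limitation, not a claim about mechanism. Inert metabolites
flow through free overflow valves and carry no signal.

**Communities** (`make_community_scenario()`). Each of the species
draws 1--2 required metabolites and, with probability one half, one
inhibitory metabolite from a shared pool; per-sample environments are
symmetric Dirichlet. Abundances follow a log-linear fitness link,
$a_{s,i} \propto \exp(\beta\,\mu_i(e_s))$ with $\beta = 1$, where
$\mu_i$ is species $i$'s FBA growth when every exchange capacity is
proportional to the metabolite's environmental share
($5\,n_{met}\,e$). An earlier draft linked abundance to the *sum* of
required-metabolite availabilities only; that contradicted the models'
own growth truth whenever a toxin was plentiful (the generated ranking
kept a species high while every faithful method must rank it low), so
the link was made consistent with the planted truth. What a green
end-to-end test establishes is therefore: *when* abundances are
fitness-ordered in a known environment, the GSA-graph-propagation
chain recovers that order. It does not establish anything about real
stool communities, ecological drift, or cross-feeding dynamics the
generator does not contain.

**LC-MS runs** (`make_lcms_scenario()`). Observed intensity is exactly
`concentration x dilution x drift(order) x noise`: per-sample dilution
$\exp(U(-0.7, 0.7))$ (about 0.5--2 fold), linear drift $1 + 0.02\,
\mathrm{order}$, log-normal noise at a chosen CV (default 5 %), and
pooled QC injections -- the feature-wise mean of all sample profiles
at dilution 1 -- interleaved evenly across the run. Real LC-MS
artefacts that are *not* emulated: peak-shape effects, adducts,
isotopes, censoring at the detection limit, and retention-time drift.

## Preprocessing chain

`prep_metabolome()` applies, in order: **PQN** (reference = feature
mean over QC injections; each injection divided by the median quotient
against that reference), **QC-RLSC** (per feature and batch, a robust
LOESS of QC intensity on injection order, default span 0.75, two
robustifying iterations, quadratic falling back to linear local fits
for sparse QC; constant extrapolation beyond terminal QCs; correction
factor = batch QC median / fitted curve), and the **CV filter**
(remove features whose QC coefficient of variation exceeds 30 %,
sample standard deviation). The applied order is recorded as a
provenance attribute. Whether PQN should precede drift correction is
genuinely open; PQN-first is the default because dilution is a
per-sample property that QC injections (dilution 1) cannot see, while
drift is a per-injection property that survives PQN unchanged.

PQN is exactly idempotent when all QC injections share one profile (no
noise); with measurement noise the second-pass coefficients deviate
from 1 by the order of the noise CV. The idempotency test therefore
uses the noise-free case, and dilution recovery is tested at 5 % noise.

## Numerical choices

* **LP solver**: a dense two-phase tableau simplex with Bland's rule,
  written for this package (no LP solver is available in the target
  environment). Artificials are driven out of the basis before phase
  2; redundant rows are dropped. Bounds are capped at $\pm 10^6$;
  growth below $10^{-8}$ reports as exactly 0 so downstream ranks are
  stable. Degenerate alternate optima may move fluxes but not growth,
  and only growth feeds the PRCC, so the pipeline is deterministic.
  Tests compare against brute-force enumeration of basic solutions.
* **PRCC**: average ranks for ties; residual regressions via QR. A
  response fully explained by the other inputs yields coefficient 0
  with p = 1 (no partial association); an input rank column collinear
  with the others yields `NA` with a warning.
* **Propagation**: restart 0.3, L1 tolerance $10^{-8}$, cap 10,000
  iterations. The clamp is applied per iteration and is *not*
  absorbing by default -- a clamped node recovers if positive inflow
  later dominates, since "full consumption" must be reversible while
  producers are active; `absorbing = TRUE` gives permanent extinction.
  Non-convergence is reported in the returned state, never raised.
* **Ties in rankings**: average Savage scores, so zero-weight species
  tie at the bottom; `seed_from_abundance()` breaks top-N ties by
  lexicographic id.
* **Significance**: raw two-sided p < 0.1 by default ("significant at
  the level of 10 %" read as a raw threshold); Benjamini-Hochberg
  within each species' parameter set behind `adjust = "bh"`, since
  each species' GSA is an independent screening experiment.
  Configurable, not global pooling, by default.

## Scenario-level concordance

With five species a per-sample permutation test is granularity-limited:
only ~120 distinct label permutations exist and the top-down weighting
makes near-identity permutations score almost as high as the identity,
so a per-sample p $\le$ 0.05 is not reliably attainable for *any*
method. When several samples share one graph, `concordance_report()`
accepts species-by-sample matrices and reports the mean per-sample
TDCC against a null that permutes species labels once per replicate,
shared across samples -- the exchangeability structure actually under
test.

## Worked example

```{r example, eval = FALSE}
sc <- make_community_scenario(5, 8, 4, rng_seed = 7)
seeds <- sample.int(2^31 - 2, 5)
results <- lapply(seq_along(sc$models), function(i)
  run_gsa(sc$models[[i]],
          default_design(sc$models[[i]], 200, rng_seed = seeds[i])))
g <- build_graph(results, alpha = 0.1)
graph_summary(g)

envt <- data.frame(metabolite_id = colnames(sc$environment),
                   t(sc$environment), check.names = FALSE)
sd1 <- seed_from_environment(envt, "S01", graph = g)
st <- propagate(g, sd1)
concordance_report(st, sc$abundance["S01", ], permutations = 99,
                   rng_seed = 1)
```

## Known limitations

* Toy models are caricatures: 3--8 reactions, no internal pathway
  structure, no secretion truth by default (production edges are
  supported but the default scenario plants only uptake
  dependencies).
* FBA here is plain growth maximization -- no FVA, parsimonious FBA,
  or joint community optimization.
* The propagation kernel's restart probability, clamp behaviour and
  normalization are configuration with documented defaults; no claim
  is made that these match any particular published run.
* The CV filter, QC-RLSC and PQN address dilution, drift and
  reliability only; compound identification, adducts and missing-value
  imputation are out of scope.
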