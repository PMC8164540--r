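---
title: "Clustering cell-cell networks with mixture ERGMs and finding hub cells with a hidden MRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering cell-cell networks with mixture ERGMs and finding hub cells with a hidden MRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

cellmixnet analyses single-cell expression data through a network lens:
cells become nodes of a correlation graph, latent cell subpopulations become
blocks of a mixture of exponential random graph models (ERGMs), and the
cells that bridge subpopulations are prioritized by a hidden Markov random
field (MRF). This vignette explains each model, the assumptions behind it,
the tunable parameters and their defaults, and the design decisions that
were genuinely open when the package was written.

```{r setup, message = FALSE}
library(cellmixnet)
library(igraph)
```

## 1. From expression matrix to cell-cell network

Given a genes-by-cells matrix, `pearson_matrix()` computes all pairwise
Pearson correlations between cell profiles across the `n_m` genes. The
significance transform for a single correlation is the usual t-statistic

$$T = \frac{r\sqrt{n_m - 2}}{\sqrt{1 - r^2}} \sim t_{n_m - 2},$$

implemented in `correlation_t_statistic()`; a Fisher z alternative
(`correlation_fisher_z()`) is provided for users who prefer the variance-
stabilized scale. `build_cell_graph()` keeps an edge wherever
$r \ge$ `threshold` and discards pairs strictly below it. The default
threshold is 0.27, a conventional cutoff for cell-cell correlation networks
of this kind; it is a plain parameter and not re-derived from a t-quantile,
because the critical value depends on `n_m` and the appropriate gene count
varies between studies. Only positive correlations create edges: the model
downstream interprets an edge as co-expression similarity, for which
anti-correlation is not evidence.

Two practical choices:

* **Scale.** Expression values are `log1p`-transformed before correlating
  by default (`transform = "none"` gives the paper-literal behavior on
  already-processed input). Log transformation is the standard variance
  stabilization for non-negative expression counts.
* **Degenerate cells.** A cell with zero variance across genes has no
  defined correlation; its entries are set to 0 with a warning naming the
  cell, rather than silently dropping it, so the cell stays visible in all
  downstream tables.

## 2. Mixture of ERGMs over latent cell classes

An ERGM puts $P(Y \mid \theta) \propto \exp\{\theta^\top S(Y)\}$ on a graph
$Y$, where $S(Y)$ are summary statistics: here `edges`, the two-star count
$\sum_i \binom{d_i}{2}$, triangles, and the geometrically weighted degree
and edgewise-shared-partner statistics (gw-degree, gwesp) with a fixed
decay $\lambda$ (default 0.5). The normalizing constant of the ERGM is
intractable and is **never evaluated**: all inference uses change
statistics — the difference $S(Y^+_{ij}) - S(Y^-_{ij})$ caused by toggling
one dyad — through maximum pseudolikelihood (logistic regression of edge
indicators on change statistics, `fit_mple()`) and through Metropolis
ratios in the network sampler (`sample_ergm()`).

The mixture model attaches to each cell a latent class
$Z_i \sim \mathrm{Multinomial}(1, \alpha)$. Conditional on classes, each
dyad follows the ERGM of its block pair $\theta_{Z_i Z_j}$. Within-class
blocks use the full configured term set; between-class dyads are modelled
as edges-only Bernoulli — edges between different subnetworks arise at
random under this model, and systematic cross-cluster structure is instead
picked up by the hub MRF stage. The networks here are undirected, so the
directed "in/out" variants of the geometrically weighted degree statistics
collapse to a single undirected gw-degree term, and "mixed two-stars"
is the undirected two-star count.

### Fitting: classification EM on the pseudolikelihood

`fit_mixture_ergm()` alternates:

* **E-step** (`e_step()`): for each cell, the responsibility of class $q$
  is proportional to $\alpha_q$ times the exponentiated conditional
  log-pseudolikelihood of the cell's dyads with the cell in class $q$ and
  all other cells at their current hard labels. Rows are normalized by
  log-sum-exp; cells are visited in index order with labels updated in
  place.
* **M-step** (`m_step()`): mixing weights from the class indicator means;
  each within-class $\theta$ by weighted MPLE with dyad weights given by
  the products of the class indicators; between-class Bernoulli rates in
  closed form.

Inside the fitting loop the M-step weights are the products of the *hard*
one-hot indicators. This makes each E/M pair exact coordinate ascent on the
monitored objective — the classification log-pseudolikelihood
$L_C = \sum_i \log \alpha_{z_i} + \sum_{i<j} \ell(y_{ij}; \theta_{z_i z_j})$
— so the objective trace is non-decreasing. The exported `m_step()`
accepts any soft responsibility matrix for users who want a softer update.
Convergence is declared when the relative change of $L_C$ drops below
`tol` (default `1e-6`) or after `max_iter` (default 50) iterations.

Blocks can degenerate during fitting. A block whose effective dyad weight
vanishes keeps its previous parameters (with a warning). A block whose
induced subgraph is complete or empty — routine in correlation networks,
where cell types form near-cliques — has a separated pseudolikelihood; its
parameters collapse to a Haldane–Anscombe-regularized edges-only estimate,
$\hat p = (\sum w y + \tfrac12)/(\sum w + 1)$, which stays finite and
tracks the block density. The same regularization is used for the
between-class rates.

An **online** variant visits cells in a seeded random order and updates the
mixing weights by Robbins–Monro steps $\gamma_t = t^{-\kappa}$ with
$\kappa \in (0.5, 1]$ (default 0.7), refreshing $\theta$ after each sweep;
it is intended for networks too large for full sweeps to be convenient.
Initialization is spectral (k-means on the leading eigenvectors of the
symmetrically normalized adjacency) by default, with random restarts
available; ties in the final argmax labels break toward the lowest class
index, and all randomness is controlled by the seed.

### Choosing the number of classes

The integrated classification likelihood,

$$\mathrm{ICL}(G) = -2 L_C + (G\,M + G - 1)\log n,$$

with $M$ the number of summary statistics, is computed by `icl()` and
scanned over a range by `select_G()`. Written this way it is a penalized
deviance, so the package **minimizes** it — the same optimum as maximizing
the equivalent penalized classification likelihood. Two caveats are worth
stating plainly:

* $L_C$ is a log-**pseudo**likelihood: dyads are treated as independent
  given labels, which they are not under a general ERGM, so ICL here is a
  heuristic rather than an approximation with guarantees.
* On clique-like graphs (which thresholded correlation networks typically
  are), the ICL can legitimately prefer *fewer* classes than planted:
  degree-sensitive change statistics evaluated at the observed graph
  partially separate present from absent dyads (an endpoint of an existing
  edge has degree $d$, while the same endpoint of a candidate edge has
  degree $d$ including no contribution from that dyad), letting one block
  with transitivity or degree terms fit a union of cliques almost
  perfectly. `select_G()` therefore always returns the full ICL table, and
  `run_config(G = ...)` overrides the automatic choice — the intended
  workflow when the analyst knows, or wants to probe, a different
  resolution.

```{r mixture-demo}
sim <- simulate_mixture_network(n = 60, seed = 11)
sel <- suppressWarnings(select_G(sim$graph, 2:5, seed = 7))
sel$table
mclust::adjustedRandIndex(sel$best_model$labels, sim$true_labels)
```

## 3. Hub cells: a Gaussian hidden MRF

After clustering, each cell gets a **hub value**
$hv_i = n_i / d_i \in (0, 1]$, where $n_i$ counts the distinct cluster
labels among the neighbors of cell $i$ (the cell's own label is not
added) and $d_i$ is its degree; isolated cells get $hv = 1$, the
no-evidence value. The ratio already lies in $(0,1]$, so the optional
extra min–max rescale is off by default. The evidence enters the field as
$\omega_i = \Phi^{-1}(1 - hv_i/2)$ (`z_transform()`), clamped below at
`1e-8` so the quantile stays finite.

Two documented quirks of this transform, implemented as printed:

* Under a Uniform(0,1) null for $hv$, $\omega$ is **half-normal**, not
  standard normal (the standard-normal emission below is the model's
  assumption, not a consequence of the transform).
* Direction: *small* hub values give *large* $\omega$ and hence hub calls.
  Analysts who want "touches many clusters per unit degree" to score high
  can set `invert = TRUE` (or `invert_hv` in the pipeline config), which
  applies the transform to $1 - hv$.

States $T_i \in \{0,1\}$ mark hub cells. The emission is
$\omega_i \mid T_i = 0 \sim N(0,1)$ and
$\omega_i \mid T_i = 1 \sim N(\mu_i, \sigma_i^2)$ with a conjugate
Normal–Inverse-Gamma prior
$\sigma_i^2 \sim \mathrm{InvGamma}(\upsilon/2, \upsilon d/2)$,
$\mu_i \mid \sigma_i^2 \sim N(\bar u, \sigma_i^2/a)$. The prior over the
state field is a degree-weighted Ising model on the graph,

$$\log P(T) = h \sum_i I_1(T_i)
  + \tau_0 \sum_{(i,j) \in E} (d_i^{1/2} + d_j^{1/2})\, I_0(T_i) I_0(T_j)
  + \tau_1 \sum_{(i,j) \in E} (d_i^{1/2} + d_j^{1/2})\, I_1(T_i) I_1(T_j)
  - \log Z,$$

whose normalizing function $Z$ (a sum over $2^n$ configurations) is only
ever computed in the exact-enumeration validation mode
(`enumerate_hub_posterior()`, $n \le 20$).

`gibbs_posterior()` runs a systematic-scan Gibbs sampler alternating the
$T_i$ full conditionals with conjugate NIG redraws of $(\mu_i,
\sigma_i^2)$, and returns Monte-Carlo posterior marginals
$P(T_i = 1 \mid \omega)$. Hub calls threshold the marginal at 0.5 — the
marginal posterior mode, a standard stand-in for the joint MAP that the
model's argmax formulation asks for. Defaults: 1,000 burn-in sweeps, 5,000
retained sweeps; seeded runs are bitwise reproducible.

Hyperparameter defaults are $h = -2$ (hub calls are a priori rare),
$\tau_0 = \tau_1 = 0.5$, $\bar u = 2$, $a = 1$, $\upsilon = 4$, $d = 1$,
with no empirical-Bayes estimation — all are user-configurable. One
practical warning: the couplings multiply $(d_i^{1/2} + d_j^{1/2})$ summed
over *edges*, so their influence grows with graph density. On a dense
100-node graph, $\tau = 0.5$ contributes on the order of $10^2$ log-units
per state flip and freezes the field regardless of the evidence; couplings
of order $10^{-2}$–$10^{-1}$ are appropriate there, and the package's own
recovery experiments use $\tau_0 = \tau_1 = 0$, the analysis matched to
their i.i.d. planted truth (below).

## 4. Gene-set enrichment

`hypergeom_point()` evaluates the hypergeometric point probability
$\binom{M_p}{m_p}\binom{M - M_p}{m - m_p}/\binom{M}{m}$ in log-gamma
arithmetic; `enrich_test()` defaults to the upper-tail probability
$P(X \ge m_p)$, the standard over-representation test, with the point form
available as `mode = "point"` for the literal printed formula.
`enrich_collection()` maps a GMT collection, sorts by p-value and offers
Benjamini–Hochberg adjustment (off by default, matching the practice of
raw cutoffs for this test). The background set is a required explicit
argument — whether it is all assayed or all expressed genes is a study
decision the package refuses to make silently.

## 5. What the simulators emulate — and what they do not

All test fixtures are generated in code, with every simulator a pure
function of its arguments and seed.

* `simulate_mixture_network()` draws labels from
  $\mathrm{Multinomial}(1, \alpha)$, samples each within-class subgraph
  from its ERGM by Metropolis (default burn-in $20 n_g^2$ dyad proposals),
  and fills between-class dyads with independent Bernoulli draws. The
  default three-class design uses the term set (edges, two-stars, gwesp,
  gw-degree) with within-class edge propensities around 0.4 / 0.3 / 0.2, a
  mild shared transitivity effect (gwesp coefficient 0.2), and
  between-class log-odds $\mathrm{logit}(0.05)$ — dense, internally
  cohesive blocks over a sparse background (realized within-block density
  roughly 0.3–0.45, at least four times the between-block density). The
  generating coefficients are package choices: they produce the separation
  regime the recovery studies assume, with block structure clearly present
  but individual dyads still stochastic.
* `simulate_expression()` builds each cell profile from a shared program,
  a cluster program and i.i.d. noise, weighted so the population
  correlation is exactly `within_rho` within clusters (default 0.6) and
  `between_rho` across (default 0.05); a constant shift enforces
  non-negativity without touching any Pearson correlation. Cluster sizes
  are balanced.
* `plant_hub_field()` draws hub states i.i.d. Bernoulli(`frac_hubs`)
  (optionally refined by one Gibbs sweep under the Ising prior) and emits
  $\omega$ from the model's two Gaussians, with hub mean $\mu^* = 4$ and
  unit sd by default.

What passing tests on these fixtures show is that the estimators recover
the *model's own* generative process at realistic sizes. What they do not
show: robustness to count noise (the expression simulator emits continuous
values, not negative-binomial counts), dropout, doublets, batch effects,
or unbalanced and overlapping cell types. Real single-cell data has all of
these, and conclusions about real data need the usual caution.

## 6. Numerical choices

* Change statistics are exact closed forms (verified against brute-force
  recomputation on random graphs); the triangle/shared-partner terms reuse
  the adjacency product, so a fit precomputes one dyad-by-term design
  matrix and the EM is then linear algebra plus small weighted logistic
  fits.
* Responsibilities are normalized in log space; rows sum to 1 within
  `1e-10`. Degenerate score rows fall back to a uniform row with a
  warning.
* The weighted logistic fits run through `stats::glm.fit` with the
  binomial family; standard errors come from the Fisher information of
  the weighted fit and should be read as approximate under dyad
  dependence.
* Boundary rule for graph construction: exclusion only when strictly
  below the threshold, so `r == threshold` keeps its edge. Argmax ties
  break toward the lowest class index. The hub-value clamp (`1e-8`) and
  the Bernoulli-rate clamp (`1e-12`) are the only places values are
  truncated.
* Problem sizes in the shipped studies — 60-node networks with 10
  replicates for mixture recovery and ICL selection, 100 nodes for hub
  recovery, 50,000 Gibbs sweeps against $2^n$ enumeration at $n \le 12$,
  200×60 expression fixtures for the pipeline — were chosen so the full
  validation suite runs in a few minutes on one core while keeping
  Monte-Carlo error well inside the tolerances tested.

## 7. Known limitations

* Pseudolikelihood everywhere: no MCMC-MLE, no bridge sampling; curved
  ERGM decays are fixed, not estimated. Directed and valued networks are
  out of scope.
* ICL on pseudolikelihood under-penalizes in some regimes and, on
  clique-like graphs, can prefer merged classes (see §2); the table is
  always reported so the choice can be audited.
* The Ising couplings of the hub field are not estimated from data, and
  their effective strength scales with graph density; defaults suit
  sparse graphs.
* No normalization, imputation or batch-correction pipeline: the package
  starts from a matrix the user considers analysis-ready.
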