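# cellmixnet

Cell–cell network clustering for single-cell expression data: mixture
ERGMs for the clusters, a hidden Markov random field for the hub cells.

## The problem

Single-cell RNA-seq resolves the heterogeneity that bulk sequencing
averages away, but clustering cells directly in gene space suffers from
the usual high-dimensional similarity breakdown. cellmixnet takes the
network route instead:

1. **Graph construction** — cells become nodes; an edge joins two cells
   whose expression profiles have Pearson correlation `r ≥ 0.27` (the
   t-statistic `T = r√(n_m − 2)/√(1 − r²) ~ t(n_m − 2)` gives the
   significance scale; the threshold is configurable).
2. **Clustering** — a mixture of exponential random graph models
   (ERGMs): each cell carries a latent class
   `Z_i ~ Multinomial(1, α)`, and conditional on classes each dyad
   follows the ERGM of its block pair,
   `P(Y|θ) ∝ exp(θᵀS(Y))` with statistics `S` = edges, two-stars,
   gw-degree, gwesp. Estimation is a classification EM on the maximum
   pseudolikelihood (logistic regression on change statistics — the
   intractable ERGM normalizer is never evaluated), and the number of
   classes is chosen by the integrated classification likelihood
   `ICL(G) = −2·L_C + (G·M + G − 1)·log n`.
3. **Hub cells** — per-cell hub values `hv_i = n_i/degree_i` (distinct
   neighbor clusters per unit degree), z-transformed to
   `ω_i = Φ⁻¹(1 − hv_i/2)`, feed a Gaussian hidden MRF with a
   degree-weighted Ising prior over binary hub states; a Gibbs sampler
   returns posterior hub probabilities.
4. **Enrichment** — exact hypergeometric gene-set tests
   (`P = C(M_p, m_p)·C(M−M_p, m−m_p)/C(M, m)`, point or upper-tail)
   against GMT collections.

Built-in simulators (mixture-ERGM networks with known labels,
block-correlated expression matrices, planted hub fields) give every stage
a ground truth, so the whole method is testable offline. Intended users:
computational biologists analysing cell heterogeneity who want a
network-model alternative to feature-space clustering, and methods people
who want a self-contained, validated ERGM-mixture/MRF reference
implementation.

## Worked example

```r
library(cellmixnet)

# a 200-gene x 60-cell matrix with three planted cell clusters
sim <- simulate_expression(n_genes = 200, n_cells = 60, n_clusters = 3,
                           seed = 1)

g <- build_cell_graph(pearson_matrix(sim$matrix), threshold = 0.27)
igraph::ecount(g)
#> [1] 570

fit <- fit_mixture_ergm(g, G = 3, seed = 1)
fit
#> <mixture_ergm> G = 3, n = 60, L_C = -68.908 (converged after 2 iterations)
#> alpha: 0.333 0.333 0.333
icl(fit)
#> # A tibble: 1 × 5
#>       G   L_C M_stats     n   icl
#>   <dbl> <dbl>   <int> <dbl> <dbl>
#> 1     3 -68.9       4    60  195.
```

The three clusters are recovered exactly (all 60 cells at responsibility
1; adjusted Rand index 1 against the planted labels), with mixing weights
1/3 each and the classification log-pseudolikelihood `L_C` and its ICL
shown above. Hub detection then scores each cell:

```r
hv <- hub_values(g, fit$labels)
post <- gibbs_posterior(z_transform(hv), g,
                        mrf_hyperparams(tau0 = 0.02, tau1 = 0.02), seed = 1)
head(dplyr::arrange(tidy(post), dplyr::desc(posterior_marginal)), 3)
#> # A tibble: 3 × 4
#>   node_id omega posterior_marginal hub_call
#>   <chr>   <dbl>              <dbl> <lgl>
#> 1 cell40   1.94             0.0306 FALSE
#> 2 cell17   1.94             0.0292 FALSE
#> 3 cell21   1.94             0.0292 FALSE
```

On this clean fixture no cell bridges clusters, so all posterior hub
probabilities stay far below the 0.5 call threshold — the correct answer
for disjoint planted blocks. Finally, an enrichment test at the counts
scale of a typical module (background 200 genes, 25 prioritized, gene set
overlapping 40/12):

```r
enrich_test(counts = c(M = 200, m = 25, M_p = 40, m_p = 12))
#> # A tibble: 1 × 5
#>       M     m   M_p   m_p  p_value
#>   <dbl> <dbl> <dbl> <dbl>    <dbl>
#> 1   200    25    40    12 0.000662
```

`select_G()` scans a range of class counts and returns the full ICL table
plus the minimizing model; `run_pipeline()` chains all stages and writes
edge lists, cluster/hub tables and a replayable JSON manifest;
`autoplot()` methods draw the ICL curve, the EM objective trace and the
hub posterior. See the vignette (`vignettes/cell-network-clustering.Rmd`)
for the models, assumptions, and parameter guidance.

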