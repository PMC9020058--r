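# deregnet

Identification of maximally deregulated subnetworks in directed
biomolecular networks.

Pathway enrichment tools score *predefined* gene sets; they cannot
discover a disease module that cuts across pathway boundaries. `deregnet`
solves the corresponding *de novo* problem for directed regulatory
networks: given a network $G = (V, E)$ and per-gene deregulation scores
$s : V \to \mathbb{R}$ (log2 fold changes, trinary up/down calls,
promoter-methylation scores, ...), it finds the root-connected subgraph
$V^*$ that maximizes (or minimizes) the **average** node score

$$\max_{x,y \in \{0,1\}^V} \; \frac{s^T x}{e^T x}
\qquad k_{min} \le e^T x \le k_{max},$$

where a unique root (optionally restricted to a *receptor* set) reaches
every selected node by a directed path inside the subgraph, and every
selected node without a selected out-neighbor may be required to belong
to a *terminal* set. The average objective makes the subgraph size
self-selecting within the bounds — low-scoring linker genes are included
exactly when the connection they enable pays for itself. The fractional
integer program is solved exactly by a Dinkelbach-type iteration over an
exact branch-and-bound core (written in C++), with every emitted solution
verified against the full constraint system.

Under the package's Bernoulli deregulation model (score 1 with
probability $p'$ inside a latent subgraph, $p < p'$ outside), the
average-score optimum is a maximum-likelihood configuration at its own
fitted rates; the fixed-size variant corresponds to maximum-likelihood
estimation with the size known. See the methods vignette
(`vignettes/deregnet-methods.Rmd`) for the model, the algorithm, and all
numerical design choices.

The package is intended for computational biologists analyzing omics
cohorts on curated directed networks (KEGG-style exports, SIF/GraphML):
cohort-level ("global") subgraphs, patient-level ("personalized")
subgraphs, multi-omics methylation-transcription consistency modules, and
survival stratification by subgraph membership (*network-defined cancer
genes*).

## Worked example

A small signaling cascade with receptor EGFR and terminal MYC is included
as plain-text fixtures:

```r
library(deregnet)

net    <- read_network(system.file("extdata", "toy_signaling.sif",
                                   package = "deregnet"), "sif")
scores <- read_score_table(system.file("extdata", "toy_scores.tsv",
                                       package = "deregnet"))
inst <- deregnet_instance(net, scores, receptors = "EGFR",
                          terminals = "MYC", k_min = 3, k_max = 6)
sol <- deregnet_solve(inst)
sol
#> <deregnet_solution> rank 0 | 6 nodes | root EGFR | avg score 1.91667
#>   nodes: EGFR ERK MEK MYC RAF RAS
glance(sol)
#> # A tibble: 1 × 8
#>   objective total_score n_nodes root   rank converged iterations sense
#>       <dbl>       <dbl>   <int> <chr> <int> <lgl>          <int> <chr>
#> 1      1.92        11.5       6 EGFR      0 TRUE               2 maximize
```

The solver keeps the low-scoring linker MEK (score 0.2) because the
strongly upregulated RAS–RAF–ERK–MYC axis it connects pays for it: the
six-node cascade averages 1.92, while the short EGFR–PI3K–AKT–MYC route
only reaches 1.33. That alternative surfaces as the next-best subgraph:

```r
solve_suboptimal(inst, n = 2)
#> [[1]] <deregnet_solution> rank 0 | 6 nodes | root EGFR | avg score 1.91667
#>   nodes: EGFR ERK MEK MYC RAF RAS
#> [[2]] <deregnet_solution> rank 1 | 4 nodes | root EGFR | avg score 1.325
#>   nodes: AKT EGFR MYC PI3K
```

(The toy instance has exactly two feasible subgraphs, so the enumeration
stops there.) `tidy()` returns the per-node table, `union_summary()` the
frequency-annotated union subgraph, and `write_solution()` a
GraphML + JSON serialization.

Score construction, simulation benchmarking, and survival stratification
follow the same data-frame-first style:

```r
trinary_global_score(diff_table)         # per-gene {-1, 0, +1} calls
run_benchmark(generate_network(300, 2, seed = 1), simulation_config())
network_defined_genes(patient_subgraphs, survival_records)
```

A command-line wrapper over the same functions lives at
`system.file("cli", "deregnet.R", package = "deregnet")` with
`solve`, `benchmark`, `scores`, and `ndg` subcommands.

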