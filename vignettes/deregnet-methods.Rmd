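---
title: "Deregulated subgraph inference: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deregulated subgraph inference: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deregnet)
```

## The model

Given a directed biomolecular network $G = (V, E)$ without self-loops and a
node score $s : V \to \mathbb{R}$ summarizing omics evidence of
deregulation, the package extracts the *maximally deregulated
root-connected subgraph*: a node set $V^* \subseteq V$ with a distinguished
root from which every member is reachable by a directed path inside $V^*$,
maximizing (or minimizing) the **average** score

$$\max_{x, y \in \{0,1\}^V} \frac{s^T x}{e^T x}$$

subject to: the root is selected and unique ($y \le x$, $e^T y = 1$); the
subgraph size is bounded ($k_{min} \le e^T x \le k_{max}$); every selected
non-root node has a selected in-neighbor; no strongly connected component
of the selection may float free of the root (for every node set $S$
inducing a strongly connected subgraph, either the root lies in $S$ or $S$
receives an edge from another selected node); optionally the root must
come from a *receptor* set $R$, every selected node without a selected
out-neighbor must come from a *terminal* set $T$, and *include*/*exclude*
sets force or forbid individual nodes. The average (rather than total)
score objective is what frees the model from a fixed a-priori subgraph
size and lets it connect receptors to terminals through low-scoring
linker nodes only when they pay for themselves.

Optimizing a ratio of linear functions over a combinatorial feasible set
is a fractional integer program. Maximization targets upregulated
subgraphs, minimization downregulated ones, the element-wise absolute
score $|s|$ targets generically dysregulated ones, and *reverse mode* —
solving on the edge-reversed network with receptor and terminal roles
swapped — yields subgraphs that converge into a single terminal node.

## Probabilistic interpretation

The score model treats binary scores as independent Bernoulli draws:
inside a latent subgraph $V'$ nodes are deregulated with probability
$p'$, outside with background probability $p < p'$. `fit_rates()` gives
the maximum-likelihood rates of a candidate subgraph (the inside/outside
sample fractions), `log_likelihood()` evaluates the model, and
`profile_log_likelihood()` profiles the rates out with the usual
$0 \cdot \log 0 = 0$ convention. When the fitted ordering violates
$p' > p$ the model is reported *degenerate* (pooled-rate supremum) rather
than silently clamped.

Two precise statements connect the optimization to likelihood:

* **Fixed size.** Among feasible subgraphs of one fixed size, the
  maximum-*total*-score subgraph maximizes the profile likelihood. This is
  exactly the regime of fixed-size subgraph models, and it holds without
  exception in our enumeration tests.
* **Self-consistency.** The maximum-*average*-score subgraph maximizes the
  likelihood evaluated at its own fitted rates $(\hat p, \hat p')$ — a
  fixed-point property linking the fractional optimum to maximum
  likelihood estimation without fixing the size.

A natural-looking stronger claim — that the maximum-average subgraph also
maximizes the *profiled* likelihood over all feasible subgraphs — is
false, and the package documents a minimal counterexample in its test
suite: on a 10-node network with a directed path $v_1 \to v_2 \to v_3 \to
v_4$ and score-1 nodes $\{v_1, v_2, v_4\}$, the set $\{v_1, v_2\}$ has
average 1 but profile log-likelihood $-3.01$, while $\{v_1, \dots, v_4\}$
has average $0.75$ and $-2.25$: capturing the third score-1 node lowers
the *outside* rate estimate by enough to dominate the inside dilution.
The enumeration tests therefore assert the two statements above and
merely log how often the profiled comparison prefers a non-maximal-average
subgraph (about 1–3% of instances under the benchmark score model).

## Solution algorithm

The fractional program is solved by a Dinkelbach-type iteration: given a
ratio parameter $\lambda$, solve the parametric (non-fractional) problem
$\max\, s^T x - \lambda\, e^T x$ over the same feasible set, update
$\lambda$ to the incumbent's average score, and stop when the parametric
optimum is within `gap_tolerance` of zero ($10^{-6}$ by default; the
sequence is monotone and, with the small integer-valued scores typical of
trinary inputs, converges in a handful of iterations, far below the
`max_iterations = 50` cap). $\lambda_0$ is initialized from a greedy
feasible subgraph (breadth-first growth from the best-scoring admissible
root up to $k_{min}$ nodes); when the greedy construction fails
feasibility, the worst single-node score is used, which is always a valid
starting bound.

The parametric subproblem is solved exactly by a purpose-built
branch-and-bound over rooted connected subgraphs, implemented in C++:

* **Connectivity by construction.** The search grows the selection from
  the root through out-neighbors only, so every explored state is
  root-connected; the in-neighbor and strongly-connected-component
  constraint families are satisfied by construction rather than separated
  lazily. `separate_scc_violations()` implements the component separation
  check independently, and every emitted solution is verified post hoc to
  produce an empty violation list and to pass the full declarative
  constraint check — the same fixed point a lazy-row formulation reaches.
* **Bound.** At each node of the search tree, a breadth-first pass
  collects nodes still reachable through undecided nodes within the
  remaining size budget; the sum of the largest positive weights among
  them (capped by the budget) bounds the attainable improvement.
* **Tie-breaking.** Among equal-objective optima the solver prefers the
  larger node set. This mirrors the behavior of the parametric objective
  at any $\lambda$ strictly below the optimal ratio, where larger
  optimal-ratio subgraphs strictly dominate, and it makes the returned
  subgraph well-defined when many subsets of score-1 nodes tie at the
  optimal average — the relevant regime for near-binary scores. Remaining
  ties resolve by deterministic search order (sorted node ids), so runs
  are reproducible; fixed-size solves keep plain first-found order, since
  all candidates there share one cardinality.
* **Degenerate inputs.** Empty receptor sets make every node an
  admissible root; empty terminal sets drop the sink condition; a
  $k_{max}$ beyond $|V|$ is clamped (it is never binding); excluding all
  nodes, or a terminal/receptor configuration with no feasible set,
  raises a typed infeasibility condition. Time and search-node limits
  raise a typed timeout condition carrying the best incumbent.

Next-best subgraphs (`solve_suboptimal()`) are enumerated by re-solving
under *no-good cuts* that forbid returning an exact previous node set.
This is deliberately the weakest exclusion guaranteeing a new node set:
supersets of earlier solutions stay admissible, which matches the
intended semantics of "next best suboptimal subgraphs" (a cut of the form
$\sum_{v \in V^*} x_v \le |V^*| - 1$ would also forbid all supersets and,
e.g., could never return the full triangle after its best two-node path).

`brute_force_optimal()` enumerates all (node set, root) pairs within the
size bounds and filters by the declarative feasibility checker. It shares
no code with the C++ search path and serves as the correctness oracle:
the test suite requires objective agreement to $10^{-9}$ on dozens of
random instances across both senses, absolute scoring, and reverse mode.

## Node scores

* **Trinary global expression score**: $+1$ for significant strong
  up-regulation (log2 fold change $> 2$ and $p < 0.05$), $-1$ for
  significant strong down-regulation (log2 fold change $< -2$ and
  $p < 0.05$), else 0. The down branch uses the sign-symmetric threshold
  $-2$; thresholds are strict and configurable.
* **Personalized score**: per-patient log2 fold change of tumor
  expression against the mean of all control samples, with a pseudocount
  (default 1) added to both numerator and denominator — the placement is
  configurable since "adding a pseudocount" is ambiguous — then
  thresholded at $\pm 2$ into a trinary score.
* **Promoter methylation score**: probes are called as differentially
  methylated when the tumor-vs-control difference of median beta values
  exceeds $0.2$ in magnitude (strict); a gene is $+1$ with at least one
  up-call and no down-calls among its promoter probes (within 1500 bp
  upstream of the transcription start site; the probe-to-gene map is an
  input, not computed), $-1$ in the mirrored case, 0 otherwise —
  including conflicting evidence and unprobed genes.
* **Consistency score**: the indicator that the trinary expression score
  and the methylation gene score have strictly negative product, flagging
  genes whose promoter methylation and transcription move in opposite
  directions; subgraphs maximizing its average are candidate epigenetically
  driven modules.

Scores for network nodes absent from a score table default to the neutral
value 0, and score ids absent from the network are dropped with a count —
omics tables and curated networks rarely share an exact gene universe,
and a neutral default keeps the objective honest.

## Synthetic data and the benchmark

`generate_network()` grows a directed scale-free-like graph by
preferential attachment with randomized edge orientation. It emulates the
degree heterogeneity (hubs) and sparsity of curated regulatory networks
at adjustable size; it does not emulate interaction labels, motif
composition, or the modular pathway structure of real databases, so
benchmark results on it demonstrate *algorithmic* recovery, not
biological fidelity. Any user-supplied network file can be substituted
for full-scale replication.

A benchmark instance plants a root-connected subgraph by uniform random
out-growth (target size uniform on a configured range, dead-ended growth
restarts from a fresh root, at most 1000 retries) and draws binary scores
at rate $p' = 0.99$ inside and $p = 0.01$ outside — the generative
conditions the score model assumes. `run_benchmark()` then runs both the
average-score model with size bounds $[k_{min}, k_{max}]$ and the
fixed-size comparator as a union over every size in the same range, both
with free root and empty receptor/terminal sets (the comparator's
original formulation has no receptor/terminal machinery, and leaving the
root free is the permissive reading), and scores node recovery with
sensitivity, precision, F1, Jaccard, Matthews correlation, and size
efficiency (inferred over true size), plus the upper-tail hypergeometric
enrichment of each emitted subgraph against the simulated score-1 set.
Per-instance RNG streams derive from the master seed and instance index,
so any instance can be regenerated in isolation.

The packaged experiment scale — a 300-node network, 20 instances, true
sizes 8–12, bounds 6–15 — was chosen as the smallest configuration at
which the qualitative contrasts are stable: median Matthews correlation
at or near 1 for the average-score model, a clear advantage over the
fixed-size union comparator (whose union inflates size efficiency well
above 1), and universal enrichment significance. The
`scripts/acceptance.R` script recomputes all of these from scratch.

## Survival stratification

For patient-level (personalized) subgraphs, `network_defined_genes()`
implements the stratification screen: for every gene contained in at
least one patient's subgraph, patients split into carriers and
non-carriers of the gene; strata with at least `min_group_size` patients
on both sides (default 3 — the procedure's minimum stratum size is not
prescribed, so it is explicit and configurable) are compared by the
standard unweighted log-rank test with the aggregated treatment of tied
event times. Raw p-values are reported alongside Benjamini–Hochberg
adjusted ones and the table is ranked by the adjusted value by default;
ranking by raw p-values is available since the screen is a
hypothesis-generation device rather than a confirmatory test. Groups
without any event yield a flagged degenerate result (statistic 0, p 1)
instead of an error. Kaplan–Meier estimation and the log-rank statistic
are delegated to the survival package behind the module surface; the test
suite checks them against hand-computed product-limit and
observed-vs-expected tables.

## Known limitations

* The exact branch-and-bound is built for the sparse, moderate-size
  networks and tight size bounds of subnetwork inference; on dense
  networks with large $k_{max}$ and near-uniform scores its worst case is
  exponential, and the time/node limits then return flagged incumbents
  rather than proven optima.
* Ties beyond the documented cardinality preference resolve by node-id
  order, which is reproducible but not semantically meaningful.
* The generalized Charnes–Cooper reformulation of the fractional program
  is not implemented; the Dinkelbach path is the sole solution route.
* The benchmark generator plants subgraphs by the same growth process the
  simulation protocol assumes; recovery numbers do not speak to
  misspecified planting processes.
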