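---
title: "From co-expression to pathway projection networks: methods and design"
author: "ppnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From co-expression to pathway projection networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppnet)
```

# The analysis in one paragraph

ppnet turns a genes-by-samples expression matrix into an undirected
*derived interaction network* — an edge joins two genes when the absolute
Pearson correlation of their expression profiles strictly exceeds a
threshold $\tau$ — then partitions that network into topological
communities by divisive edge-betweenness removal with modularity-based cut
selection, and finally re-expresses condition-specific communities in
pathway space: a *Pathway Projection Network* (PPN) whose nodes are
pathways, sized by how many community genes were assigned to them and
linked by the gene–gene edges that run between their gene sets. The
motivating use case is a two-condition design (e.g. normal versus
dystrophic skeletal muscle), where communities private to one condition,
and the pathway couplings inside them, are the object of interest.

# The model and its assumptions

## Derived interaction networks

For genes $i, j$ with expression profiles $x_i, x_j$ across the samples of
one condition, the adjacency rule is

$$A_{ij} = \mathbf{1}\left[\,|r(x_i, x_j)| > \tau\,\right], \qquad i \neq j,$$

with $r$ the Pearson coefficient. The working hypothesis is that a
stronger correlation signifies a stronger interaction; the hard threshold
makes the graph sparse and unweighted for the downstream combinatorics.
Points worth making explicit:

* the inequality is **strict**: $r = \tau$ exactly creates no edge;
* the rule is **sign-blind** ($|r|$), so strong mutual inhibition also
  links genes; the signed $r$ is kept as the edge's `weight` attribute for
  reporting, but every algorithm afterwards treats the graph as unweighted;
* genes whose profile has zero variance have no defined correlation; they
  are flagged (`undefinedGenes()`) and can never form edges;
* genes left without any above-threshold partner are dropped from the
  vertex set and counted (`isolatedGenes()`).

The default $\tau = 0.8$ is the conventional "strong correlation" cut-off
for this analysis style; it is a `RunConfig` field, not a constant.

## Community detection by divisive edge removal

The loop is the classical divisive one: compute the betweenness of every
remaining edge — the number of shortest paths between all vertex pairs
that run along it, equally split among a pair's co-shortest paths — remove
the edge with the largest value, recompute, repeat until no edges remain.
Ties for the largest betweenness are broken uniformly at random under a
caller-supplied seed, which is the only stochastic element of the whole
pipeline; the same seed reproduces the removal order exactly. The loop is
exact, $O(m^2 n)$ overall; no fast-greedy or spectral shortcuts are
offered, because on desk-scale networks exactness is affordable and the
removal order itself is part of the output.

Each time a removal increases the number of connected components, the
component partition is recorded together with its modularity

$$Q = \mathrm{Tr}\,e - \sum_i \left(\sum_j e_{ij}\right)^2,$$

where $e_{ij}$ is the fraction of the **original** network's edges linking
community $i$ to community $j$ (an inter-community edge contributes $1/2$
to each of $e_{ij}$ and $e_{ji}$). Two conventions matter and are fixed
deliberately:

* $Q$ is evaluated only at splits, not after every removal, because
  partitions are defined by components and components change only at
  splits;
* $Q$ is always computed against the original edge set, never the depleted
  graph, since $e$ is defined on "all edges" of the network being
  partitioned;
* a disconnected input records its initial component partition before any
  edge is removed, so the natural partition of a fragmented graph is
  always a candidate.

`bestPartition()` returns the recorded split with maximal $Q$, with ties
going to the earliest (fewest communities). Community ids are dense
1-based integers, largest community first.

The edge-betweenness primitive itself is delegated to igraph's exact
implementation; the test suite holds it to a brute-force shortest-path
enumeration oracle at $10^{-9}$, and holds the modularity statistic to
both a direct intra-edge/degree-count oracle and igraph's independent
implementation over every partition of small random graphs.

## Pathway projection

For each community of the reference condition (A), the condition-specific
sub-network is the induced subgraph of A's network on the community genes
**absent** from condition B's network — the part of the community that
exists only in condition A. Sub-networks with fewer than
`min_cardinality` vertices (default 100, configurable; the synthetic
examples use smaller floors) are set aside.

Gene–pathway annotation is many-to-many. To avoid a combinatorial
explosion of projections, the *maximum spanning pathway reduction
heuristic* collapses it to one-to-one: each annotated gene $g$ of the
sub-network is assigned the candidate pathway $p$ maximising the number of
*other* annotated sub-network genes whose candidate set also contains $p$.
Three design choices fix the ambiguities the verbal rule leaves open:

* support counts are computed **once** from the raw candidate sets (a
  single simultaneous pass); the rule is per-gene, so no iterative
  re-assignment is performed;
* "can also be assigned $p$" is read as *has $p$ in its candidate set*,
  regardless of eventual assignment;
* ties are broken by lexicographically smallest pathway id, making the
  reduction invariant to gene input order. (Since a gene always supports
  its own candidates, subtracting the gene itself from each support count
  shifts all its candidates equally and cannot change the argmax.)

`buildPPN()` then contracts the sub-network by the assignment: node
cardinality = assigned genes, edge weight = gene edges between two
pathways' gene sets, intra-pathway gene edges accumulate as node
self-weights. Self-weights are excluded from the node degree used for
colour coding, because that degree is meant to measure connectivity
*between* pathways. The conservation identity
$\sum \text{edge weights} + \sum \text{self-weights} = $ number of gene
edges among assigned genes holds exactly and is asserted on random
fixtures. Unannotated genes are excluded from the projection but counted.
Because weighted and binary readings of PPN edges are both defensible, the
writers emit the count and a 0/1 view side by side.

`topPairs()` reports, for a chosen pathway pair, the gene edges whose
endpoints are assigned to the two pathways, sorted by $|r|$ descending
with lexicographic tie-breaks — the cross-pathway coupling evidence at
gene level.

# The synthetic benchmark

`SyntheticSpec()` / `generateSynthetic()` define the study conditions the
package is validated under: a block-structured correlation model in which
each planted community is a block with within-block correlation
$\rho_{in}$ and between-block correlation $\rho_{out}$. Samples are drawn
from a zero-mean multivariate normal via the symmetric (eigen) square root
of the target correlation matrix — exact in expectation, no per-gene
loops — with optional independent jitter of standard deviation
$\sigma$ (which attenuates realised correlations by $1/(1+\sigma^2)$;
the default is $\sigma = 0$ because finite-sample estimation noise at
13–50 samples is already the realistic error source). The target matrix
must be positive semi-definite; genuinely impossible structures error
before sampling, while degenerate $\rho_{in} = 1$ blocks (perfectly
correlated genes) remain expressible.

Defaults mirror a two-condition muscle-biopsy style design: 4 blocks of
10 genes, $\rho_{in} = 0.95$, $\rho_{out} = 0$, 13 samples in the
"normal" condition and 23 in the "dmd" condition, and in condition B the
second half of the blocks decorrelated to $\rho_{in} = 0.3$, so that
thresholding yields the sparser disease network the two-condition
contrast needs. Each block carries its own planted pathway and every
second gene additionally a shared pathway, so the annotation is genuinely
one-to-many and the reduction heuristic has real work to do. All
randomness flows from the spec's single seed; the same spec reproduces
the matrices bit for bit.

What the generator deliberately does **not** emulate: microarray noise
physics (probe effects, saturation, background), probe multiplicity
(probe collapsing is tested on hand-built fixtures instead), and
heavy-tailed expression distributions. Passing the planted benchmark
therefore demonstrates the pipeline's correctness and its statistical
behaviour under clean block correlation — not robustness to array
artefacts.

Recovery is scored by the adjusted Rand index (`evaluateRecovery()`,
chance-corrected, 1 iff identical up to relabelling). Under the benchmark
conditions with 50 samples, the network is four near-cliques, the best
partition recovers the blocks with ARI 1 in essentially every seed, and
$Q_{\max}$ sits at $1 - 1/4 = 0.75$ (the exact value for four equal
disconnected cliques), inside the expected $[0.5, 0.78]$ band.

# Numerical and degenerate-input choices

* Betweenness ties are compared with an absolute slack of $10^{-9}$
  before the random pick, so floating-point noise cannot silently
  de-randomise a genuine tie.
* Probe collapsing: probes mapping to more than one gene are dropped;
  among a gene's remaining probes the one with maximal expression
  variance is kept (ties: smallest probe id); rows with missing values
  are dropped and counted. Retained values are never rescaled — row
  values stay bit-identical to the source file.
* Topology panel conventions (the published analyzers disagree, so they
  are fixed here and unit-tested): mean local clustering coefficient with
  degree-<2 vertices contributing 0; diameter, radius and characteristic
  path length over connected ordered pairs only, with vertex eccentricity
  taken over reachable vertices; percentage of connected ordered pairs;
  degree centralization $\frac{n}{n-2}(k_{\max}/(n-1) - \text{density})$;
  heterogeneity = population coefficient of variation of the degree
  distribution. A radius of 1 under this convention requires a vertex
  adjacent to everything it can reach; conventions that assign isolated
  or cross-component pairs infinite distance will differ.
* Single-vertex graphs: density and clustering are defined as 0;
  modularity is undefined (error) on edgeless graphs.
* Empty condition-specific sub-networks are legal results, flagged with a
  message rather than an error; an empty thresholded network aborts the
  pipeline cleanly at the network stage.

# Problem sizes

The bundled tests and the acceptance script run entirely on generated
data: networks of up to 40 genes and ~200 edges, 20 replicate seeds for
the recovery benchmark, 100 random fixtures for the conservation
identity, and brute-force betweenness oracles on graphs of up to 25
vertices. These sizes keep the exact $O(m^2 n)$ loop comfortable while
exercising every code path; the pipeline itself has no hard-coded size
limits, and the full-scale analysis of a ~7,500-gene, ~130,000-edge
network is a cluster-scale computation by the algorithm's complexity, not
a different code path.

# Known limitations

* Pearson correlation only ("linear correlation"); no Spearman, partial
  correlation, or mutual information alternatives, and no
  multiple-testing control on correlations — the hard threshold is the
  contract.
* The divisive loop is exact and therefore quadratic in edges; very large
  networks need patience, not a different setting.
* The reduction heuristic is greedy per gene and unaware of the eventual
  assignment of other genes; its ties are resolved deterministically but
  arbitrarily (lexicographic).
* No statistical enrichment testing on pathways: PPN cardinality and
  degree are descriptive, as intended.
* Expression input is assumed normalised and log-scaled by its source; no
  background correction or batch handling is attempted.

# A worked miniature

```{r example, message = FALSE}
spec <- SyntheticSpec(seed = 7)
syn <- generateSynthetic(spec)

net <- buildNetwork(correlationMatrix(syn$expression$normal), tau = 0.8)
cs <- bestPartition(ngDendrogram(net, seed = 7))
cs
evaluateRecovery(membership(cs), syn$truth[names(membership(cs))])

sub <- conditionSpecificSubnetwork(communityList(cs)[[3]], net,
  buildNetwork(correlationMatrix(syn$expression$dmd), tau = 0.8))
red <- reducePathways(sub, syn$annotation)
buildPPN(sub, red)
```
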