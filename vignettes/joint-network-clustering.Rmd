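---
title: "Simultaneous clustering of multiple gene networks"
author: "jointclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simultaneous clustering of multiple gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointclust)
```

## The problem

Genome-scale datasets describe the same genes from different angles: a
coexpression network summarises how transcript levels covary across samples,
while a physical network records protein-protein and protein-DNA
interactions.  A gene module that is supported *simultaneously* by several
such networks — well connected inside every network, weakly connected to the
rest — is far more likely to correspond to a real pathway or complex than a
module found in any single network.  `jointclust` detects such modules by
jointly partitioning k weighted networks defined over one common gene set.

## Quality measures

All quality measures are normalised so that networks of very different edge
density can be compared.

**Conductance.** For a cut $(S, C \setminus S)$ of a node set $C$, measured
in the subgraph induced by $C$,
$$\phi(S) \;=\; \frac{w(S,\, C \setminus S)}{\min\!\big(a(S),\, a(C \setminus S)\big)},$$
where $w(A,B)$ is the total weight of edges between $A$ and $B$ and $a(S)$
is the weight incident at $S$ (edges inside $S$ count once per endpoint).
The ratio is defined as 0 when its denominator vanishes, and is invariant to
rescaling all edge weights.  The conductance of a *cluster* is the minimum
conductance over all its cuts; the conductance of a *clustering* is the
minimum over its clusters.  An $(\alpha, \varepsilon)$ simultaneous
clustering is a partition whose conductance is at least $\alpha_i$ in every
graph $G_i$ while the aggregated weight of inter-cluster edges is at most an
$\varepsilon$ fraction of the total edge weight of all graphs.  Before
clustering, every graph is rescaled to a common total edge weight
(`rescaleCollection()`); conductance is unaffected, and the aggregated cost
becomes meaningful.

**Min-modularity.** A cluster $C$ is scored in graph $i$ by the weighted
Newman modularity
$Q_i(C) = w_i(C,C)/w_i(E) - \big(a_i(C) / 2 w_i(E)\big)^2$ and across graphs
by $\min_i Q_i(C)$, so a cluster only scores well when it holds up in the
*worst* network.  The subtracted term is the closed-form expectation of the
within-cluster weight under degree-preserving randomisation; we use the
closed form rather than actually rewiring edges because it is exact,
deterministic and cheap, and it is what the $a^2$ term of the standard
modularity already encodes.

## The algorithm

The recursion removes approximate sparsest cuts until only well-connected
node sets remain:

1.  **Spectral sweep** (`approxSparsestCut()`).  On the subgraph induced by
    the current node set, the Fiedler vector of the degree-normalised
    Laplacian orders the nodes; all $n-1$ prefix cuts are evaluated and the
    minimum-conductance one is kept.  The sweep conductance satisfies the
    Cheeger bound $\phi \le \sqrt{2\lambda_2}$ and upper-bounds the true
    sparsest cut; finding the sparsest cut exactly is NP-hard.
2.  **Flow refinement** (`improveCut()`).  Each sweep cut is refined by a
    max-flow quotient improvement (MQI-style): a subset of one side with a
    strictly smaller quotient cut corresponds to a max-flow below the
    current crossing weight.  We seed the search from both sides of the cut
    and alternate until a fixed point; the result never has higher
    conductance than the input, and re-applying the refinement changes
    nothing.
3.  **Sparse-enough test.**  A refined cut qualifies when its conductance is
    *strictly* below the threshold $\alpha_i$ of the graph that proposed it.
    Graph-specific thresholds let clusters have different strengths in
    different networks.
4.  **Mixture scaling** (`jointClusterTree(mode = "scaling")`).  Cutting each
    input graph separately (the basic algorithm) bounds the edges lost in
    the proposing graph but not in the others.  The scaling heuristic
    instead proposes cuts from mixture graphs
    $H_i(s) = W_i + \tfrac1s \sum_{j \ne i} W_j$: at $s = 1$ every mixture is
    the sum graph, so early cuts are cheap in *all* graphs; as $s$ grows the
    mixtures approach the individual graphs and refine clusters that the sum
    graph leaves coarse.  A mixture cut qualifies when its conductance *in
    that mixture* is strictly below $\alpha_i$ — as $H_i(s) \to G_i$ this
    interpolates to the basic test, which is why we chose it as the mixture
    eligibility rule.  The scale advances along a geometric schedule
    $s \in \{1, 2, 4, \dots, 64\}$ only when no mixture cut qualifies at the
    current scale and node set, is carried down each branch (never
    decreasing), and when the schedule is exhausted the node set falls back
    to the basic algorithm.  The geometric schedule covers the transition
    from sum-graph to individual-graph behaviour in few steps; past
    $s = 64$ the mixtures are practically the individual graphs at the
    weight resolutions involved.
5.  **Cut selection** (`bestCut()`).  When several graphs propose qualifying
    cuts, the one that is sparse-enough in the most input graphs wins; ties
    break toward the least aggregated crossing-weight fraction, then the
    lowest source-graph index, then the lexicographically smallest side —
    a total order, so runs are reproducible.

The recursion records every cut in a binary `ClusteringTree`; leaves are
node sets in which no graph can propose a sparse-enough cut.

## Parsing the tree

`parseTree()` turns the tree into final clusters with a bottom-up dynamic
program: the score of a node is the larger of its node set's min-modularity
kept whole and the sum of its children's optimal scores.  The DP maximises
the clustering score (the summed min-modularity of the frontier) exactly,
which the test suite verifies against exhaustive frontier enumeration.  A
tie between keeping and splitting keeps the coarser cluster (parsimony).
Clusters are ranked by min-modularity: rank 1 is the strongest joint module.
`modularitySignificance()` compares a cluster's modularity per graph with
uniformly drawn gene sets of the same size (add-one-smoothed empirical
p-value), which is how we separate genuinely modular clusters from large but
unstructured ones.

## Learning the thresholds

The thresholds $\alpha_i$ are learnt per graph (`learnAlphas()`): the
single-graph recursion runs with a permissive threshold of 0.5, the
conductances of all accepted cuts are collected, and $\alpha_i$ is the
median of that distribution, clamped to $[0.01, 0.5]$.  The median sits
between the conductances of genuine separations (low) and the near-0.5 cuts
of well-connected regions, so it adapts to each network's density; the
clamp keeps degenerate distributions usable.  The full distributions are
returned as an attribute for audit.  A graph in which *no* cut falls below
0.5 (for example a clique) has no usable separation at all and raises an
error rather than guessing.

## The simulator

`simulateGraphs()` emulates a planted-partition benchmark: `nGraphs`
independent unit-weight random graphs carry the same planted clustering of
`nClusters` equal-sized clusters; each node has expected total degree
`kTotal` (default 16), of which `kOut` edges leave its cluster, so
`kOut/kTotal` is the false positive rate of a graph.  Edges are independent
Bernoulli draws with $p_{in} = (k_{total}-k_{out})/(|C|-1)$ and
$p_{out} = k_{out}/(n-|C|)$ — expectations, not exact degrees.  The default
layout is 128 nodes in 4 clusters of 32, two graphs, 20 instances per noise
setting; all of it is configurable.  The simulator produces homogeneous
equal-sized clusters with independent noise across graphs; real networks
have heavy-tailed degrees, correlated errors between data sources, and
clusters of very unequal size, so recovery on the benchmark demonstrates
the algorithm's behaviour under controlled noise, not performance on any
particular organism's data.

`runBenchmark()` compares the joint method against the baselines of the
field: single-tree clustering (one reference graph's tree parsed with
min-modularity over all graphs) and coassociation consensus (cluster each
graph separately, count co-cluster votes into a consensus graph, cluster
that).  Jaccard is pair-counting: co-clustered pairs shared by the two
partitions over pairs co-clustered in either.

## Enrichment evaluation

`hypergeomEnrich()` tests cluster vs gene-set overlaps with the upper-tail
hypergeometric distribution, restricting sets to the analysis universe (the
networks' gene set) and Bonferroni-correcting by the number of sets tested
in the class; significance means corrected $p < 0.005$.  Sensitivity is the
percentage of reference sets hit by some reported cluster, specificity the
percentage of reported clusters hitting some set; only clusters with at
least 10 genes are reported.  `predictFunction()` implements
guilt-by-association: uncharacterized genes inherit the most significant
annotation of their cluster (ties break to the lexicographically smallest
set name), and `correlationSupport()` quantifies per-gene support via
Bonferroni-corrected Pearson correlation tests against cluster co-members.

## Numerical choices and degenerate inputs

*  Weight matrices are normalised to unit total before the eigensolve and
   the flow refinement; conductance is scale-invariant and this makes
   proportional inputs (for example two identical networks, or any mixture
   of them) behave identically down to floating point.
*  Disconnected induced subgraphs short-circuit to a zero-conductance
   component split (smallest component, ties by node name) before any
   eigensolve, where eigensolvers are unstable and the answer is trivial.
*  Eigenvector ties in the sweep ordering break lexicographically by node
   name; all other ties (cut selection, component choice, DP keep-vs-split,
   prediction ties) have documented deterministic resolutions.
*  Singleton clusters and empty cut ranges contribute a vacuous conductance
   of 1, so they never limit a clustering's conductance.
*  Dense symmetric eigensolvers are used throughout: the package targets
   networks up to a few thousand nodes, where a dense solve of the induced
   subproblems is both robust and fast.
*  Exhaustive conductance enumeration is capped at 20 nodes
   ($2^{19}$ cuts); the test oracles use up to 8.

The test suite exercises the recursion at 32-128 nodes with 2-4 networks
and 20 simulation instances per noise setting, sizes at which every
contract (leaf partition, conservation identities, oracle equalities) is
checked exhaustively where an oracle exists.

## Limitations

*  Clusters are disjoint: the framework produces partitions, not
   overlapping modules.
*  The approximation guarantees of the recursion are inherited contracts
   (sweep-cut upper bound, Cheeger bound, monotone refinement); the package
   asserts them as qualitative invariants rather than with explicit
   constants.
*  Directed interactions are not modelled; orientations must be dropped
   before building edge lists.
*  Coexpression graphs are kept dense (no correlation threshold), matching
   the construction the measures assume; thresholding is available when
   scalability demands it but changes the conductance landscape.

## A worked miniature

```{r example}
set.seed(1)
sim <- simulateGraphs(simConfig(nNodes = 64, nClusters = 4, kTotal = 12,
                                kOut = 3), seed = 7)
gc <- sim$collection
alphas(gc) <- unname(learnAlphas(gc))
tree <- jointClusterTree(gc, mode = "scaling")
part <- parseTree(tree, gc)
part
jaccardIndex(part, sim$truth)
```
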