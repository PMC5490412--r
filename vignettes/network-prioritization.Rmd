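---
title: "Network-based gene prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based gene prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BridgeNet)
```

# Overview

BridgeNet implements a network-based strategy for prioritizing candidate
genes in a poorly characterized biological process (the motivating use case
is wound healing in mouse). Starting from a handful of literature-derived
seed genes, the pipeline

1. expands the seeds into a weighted protein-protein interaction (PPI)
   network from STRING-style evidence tables,
2. checks the network's biological coherence by hypergeometric gene-set
   enrichment against KEGG/GO catalogs,
3. partitions the network into cohesive, possibly overlapping clusters and
   extracts their hub genes (regulatory workhorses),
4. ranks *bridge nodes* — sparsely connected genes sitting between
   modules — by bridging centrality and annotation relevance (drug-target
   candidates), and
5. simulates a treatment stimulus on a signed pathway model (KGML)
   converted to a Boolean network with continuous ODE semantics, ranking
   genes by how often the stimulus flips their state.

Supporting statistics (Welch tests on log2 expression, Stouffer
combination of per-gene p-values) quantify coordinated gene-set-level
responses in validation experiments.

# Network construction

Edges are accepted when (i) the combined confidence score is strictly
above `min_score` (default 0.7, the conventional high-confidence cutoff —
"higher than 0.7" is read as a strict inequality) and (ii) at least one
required evidence channel (default `experimental`, `database`) has a
positive score. Whether the evidence requirement should be a conjunction
is genuinely ambiguous; we default to the permissive union reading
(`channelMode = "any"`) and expose `"all"` as a switch, because an edge
supported by either curated-database or experimental evidence already
avoids the text-mining noise the filter is meant to exclude. Integer
scores on the 0–999 STRING scale are detected per column and divided by
1000. Duplicate and reversed pairs keep the maximum combined score.

The node set is the seeds plus their direct interaction partners; the
edge set is the full induced subgraph on those nodes, weighted by the
combined score. Seeds without qualifying interactions remain as isolated
flagged nodes so the input list is never silently truncated.

Hub selection uses a *global* degree threshold: the 90th percentile
(linear interpolation, so the threshold is generally non-integer) of the
unweighted-degree distribution over all nodes, with strict `>` selection.
Degree is the plain neighbor count even though edges are weighted, because
hubness here means breadth of direct interaction, not cumulative
confidence; a weighted variant exists behind a flag.

# Enrichment

Over-representation uses the exact hypergeometric tail, never a normal
approximation. Terms with zero overlap are not reported. KEGG pathways
and GO terms are corrected separately with Benjamini–Hochberg, since they
are separate annotation systems reported separately downstream. The
significance threshold (default 0.001) is applied to the adjusted values
by default; a raw-p mode (`adjust = FALSE`) covers the literal reading of
"p < 0.001", because which of the two the original analysis used is not
recoverable from its description. The background universe defaults to all
catalog genes; network-restricted universes can be supplied explicitly.
No GO-graph propagation is performed: annotations are taken as given.

# Clustering

Clusters are grown greedily from high-weighted-degree seeds to local
maxima of the cohesiveness objective

$$f(S) = \frac{w_{in}(S)}{w_{in}(S) + w_{bound}(S) + p\,|S|},$$

where $w_{in}$ is the total internal edge weight, $w_{bound}$ the total
boundary weight, and $p$ a per-node penalty modeling unobserved
interactions. Candidates smaller than `min_size` or with weighted density
$w_{in} / \binom{|S|}{2}$ below `min_density` are discarded, and
candidates with overlap score $\omega(A,B) = |A\cap B|^2/(|A||B|)$ at or
above `overlap_threshold` are merged. Defaults (penalty 2, min size 3,
min density 0.3, overlap 0.8) are the published defaults of this
algorithm family; the original analysis did not state its settings, so we
keep the canonical ones and expose all four. Growth tie-breaks are
lexicographic on node label, making results deterministic.

Cluster quality is the one-sided Mann–Whitney U p-value comparing, per
member, the weight towards the cluster (in-weight) against the weight
towards the rest of the network (out-weight); clusters with p < 0.05 are
called significant. The exact null distribution is used when both samples
have at most 20 values and no ties occur, otherwise the normal
approximation with tie correction — matching standard practice for this
test. Unclustered nodes are reported as the `OUT` group rather than
dropped.

# Bridging centrality

Bridge candidates are ranked by
$BR(n) = RWBC(n) \times BCoeff(n)$, where $RWBC$ is random-walk
(current-flow) betweenness with edge weights as conductances and

$$BCoeff(n) = \frac{D(n)^{-1}}{\sum_{v \in N(n)} D(v)^{-1}}$$

with unweighted degrees $D$. Current flow is computed per connected
component from the inverse of the reduced graph Laplacian, accumulating
each edge's pair-summed absolute current through a sorted-rank formula;
node scores exclude the pairs in which the node is itself the source or
target and are normalized by the component's pair count. On trees this
reduces exactly to shortest-path betweenness under the same
normalization, which the tests exploit as an independent cross-check
alongside a brute-force per-pair current solver. Disconnected graphs are
handled per component; isolated nodes score 0, as does the bridging
coefficient of a node without neighbors (with a warning), since the ratio
is undefined there.

Bridges are the nodes with $BR$ strictly above the 90th percentile of all
$BR$ values. Each bridge is then scored by counting the reference KEGG
pathways and reference GO terms annotating it; counts are rescaled to
[0, 1] by dividing by the per-category maximum over the bridge set (the
rescaling formula was unstated in the original description; max-division
is the simplest map sending the top count to 1, and a min–max variant is
available behind a flag) and combined with the noisy-OR
$S_{tot} = 1 - (1 - S_{KEGG})(1 - S_{GO})$, so relevance in either
annotation system suffices for a high score. Ties are broken by $BR$,
then lexicographically.

# Boolean pathway simulation

KGML relations with subtype `activation`/`expression` become positive
regulations, `inhibition`/`repression` negative ones; other subtypes are
skipped with a warning, and group entries expand to one regulation per
component. Each target's synchronous rule is the inhibitor-dominant
convention `OR(activators) AND NOT OR(inhibitors)` — the standard choice
for KGML-derived logic when a pathway-specific rule table is not
available; per-node overrides can be expressed by editing the regulation
table before assembly. Nodes without regulators are inputs and stay
constant.

The continuous transform replaces each rule by its multilinear (BooleCube)
interpolation $\tilde B_t$ over the unit hypercube, giving
$\dot x_t = (\tilde B_t(x) - x_t)/\tau_t$. Regulator states can pass
through Hill functions $h(x) = x^n/(x^n + k^n)$ (HillCube) or normalized
Hill functions $h(x)/h(1)$, which restore exact corner agreement with the
Boolean rule. Defaults — normalized HillCube, $n = 3$, $k = 0.5$,
$\tau = 1$, horizon 10 — are the conventional settings of this transform
family and produce sigmoidal, switch-like trajectories on pathway-scale
models. Because the rule factorizes into an OR over activators and a
NOT-OR over inhibitors on disjoint variable sets, the interpolation is
computed in closed form as
$(1 - \prod_a(1 - h(x_a)))\prod_i(1 - h(x_i))$ rather than by summing
over $2^d$ corners. Integration uses `deSolve::lsoda` with tight
tolerances (1e-8); the unit cube is forward-invariant up to solver
tolerance.

Treatment simulation initializes the treatment nodes at their stated 0/1
values and draws every other node independently from Bernoulli(1/2); 1000
Monte-Carlo simulations are run by default. Treatment nodes are
*initialized, not clamped*, by default — matching a stimulus that sets
initial expression — with `clampTreatment = TRUE` available since a
sustained stimulus is biologically plausible too. A gene counts as
switched when its final state lies on the opposite side of 0.5 from its
initial value; we compare endpoints rather than detecting transient
crossings, reading "passes the 0.5 threshold" as a net state change
(transient excursions that return are not a stable response). Genes are
ranked by switch frequency, treatment nodes excluded. Initial states are
drawn per node *name* in lexicographic order, so rankings are invariant
to internal node ordering and exactly reproducible from the seed.

# Expression statistics

Per-gene comparisons use Welch's unequal-variance t-test on log2
expression (two-sided), requiring at least two replicates per group and
nonzero variance. Gene-set-level signal uses the Stouffer Z-transform:
$Z_x = \Phi^{-1}(1 - P_x)$, $Z = \sum_x Z_x / \sqrt n$, with combined
p-value $1 - \Phi(Z)$. The transform is applied to the two-sided p-values
without directionality, because the combination rule as stated carries no
sign information; a fold-change-signed variant is the natural extension
but is deliberately not the default. Note that at $n = 1$ the combined
p-value equals the input p-value, and under the null the combined p-value
is uniform — both are enforced by tests. Housekeeping normalization is
assumed already applied to the input table; no multiple-testing
correction is applied across genes, as the intended use is small,
underpowered validation panels where a coordinated set-level signal, not
per-gene discovery, is the question.

# Synthetic data

The generators define the study conditions for all tests:

- `makePlantedNetwork()`: dense modules (`p_in = 0.9`, weights uniform on
  (0.7, 1], i.e. above the confidence filter), sparse cross-module noise
  (`p_out = 0.02`, weights below the filter so filtering is exercised),
  and connector nodes wired to a few members of at least two modules with
  high-confidence edges — the planted bridges. The recovery benchmarks
  use two 20-node modules and one connector.
- `makeToyKgml()` emits minimal well-formed KGML that round-trips through
  the parser; pathway-scale performance tests use a random 44-node,
  49-edge signed graph, the size of a typical signaling pathway model.
- `makeExpressionTable()` mirrors a 2×2 scratch/treatment design with two
  timepoints (1 h, 5 h) and three biological replicates, the usual shape
  of a qRT-PCR validation panel.
- `makeFixtureInputs()` assembles a complete input set; its annotation
  catalog embeds the network genes in a 4× larger background with the
  "relevant" reference terms concentrated in network genes, so
  whole-network enrichment behaves like a real over-representation
  analysis against a genome-scale universe.

What these fixtures do **not** emulate: real STRING score distributions
(bimodal, channel-correlated), scale-free PPI degree distributions,
overlapping biological modules, real KEGG topologies, or qPCR technical
artifacts. Passing the recovery benchmarks therefore demonstrates
correctness of the algorithms under clean planted structure, not
performance guarantees on real databases.

# Numerical choices and problem sizes

- Percentiles use the linear-interpolation definition (R's type-7
  quantile) with strict `>` selection throughout.
- Cohesiveness growth requires strict improvement (tolerance 1e-12),
  which guarantees termination; merging of overlapping candidates takes
  connected components of the overlap graph in a single pass.
- Current-flow betweenness solves one reduced-Laplacian system per
  component and one sorted-rank pass per edge, keeping pathway-scale
  networks (hundreds of nodes, tens of thousands of edges) around a
  minute on one core.
- The end-to-end scale exercise uses a 446-node / ~25,000-edge fixture
  (three 148-node modules at `p_in = 0.78`, two connectors) — the size of
  a realistic seed-expanded PPI network — and completes in a few minutes
  including 1000 Monte-Carlo pathway simulations.
- Monte-Carlo switch statistics at 1000 simulations carry binomial
  standard error ≈ 0.016 on a frequency of 0.5; tests allow three
  standard errors.

# Known limitations

- The clustering is a faithful re-implementation of the published
  cohesiveness-growth algorithm, not a byte-level clone of any particular
  binary; on networks with weak module structure the greedy growth order
  can differ from other implementations.
- The Boolean conversion supports one logic convention (inhibitor
  dominance); pathways with documented OR-of-inhibitor semantics need
  their regulation tables edited before assembly.
- No ortholog mapping, no multi-species identifier handling, no live
  database access: all inputs are files in the documented dialects.
- Switch detection at the final time point can miss oscillatory
  responses; inspect trajectories via `integrateModel()` when dynamics
  matter.
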