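---
title: "Nested network models: dendrogram superimposition, module aggregation and constrained layout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestnet)
```

## The model

Biological networks are rarely flat. Co-expression networks decompose into
modules of tightly correlated genes; time-course perturbation experiments
produce subnetworks that grow over time around a stable core. `nestnet`
represents such data as a *two-layer hierarchical graph*: an undirected,
weighted network on leaf nodes (genes, proteins), plus a containment
forest of *container* nodes above them. Each node has at most one parent,
containers may hold containers, and following parent pointers always
terminates — the hierarchy is a directed acyclic tree over an undirected
leaf-level graph. Horizontal *association* edges may additionally connect
containers (or leaves) outside the hierarchy; the package uses them to
carry aggregated module–module connectivity.

The structural contracts are deliberately strict and all enforced by
`validate_graph()`:

* ids unique; parents exist and are containers; no containment cycles;
* edges undirected and stored canonically (`u < v`), one edge per
  unordered pair and layer, no self-loops, nonnegative weights;
* leaf-layer edges connect two leaves.

`nest()` places a new container at the *deepest common ancestor* its
members had before the call, so chained nesting naturally builds multiple
levels; `unnest()` promotes children to the dissolved container's parent.
These two are inverse in the common case where all members shared a prior
parent.

## Superimposing a clustering onto a network

The central operation maps a hierarchical clustering onto the network
topology. `build_dendrogram()` performs complete-linkage agglomerative
clustering with Euclidean distance (backed by `stats::hclust`); any
numeric matrix works — an expression matrix or the graph adjacency matrix.

Two cut metrics convert the tree into clusters:

* `rootdist` — the integer depth of a merge below the root. A cut at
  level `c` keeps the maximal subtrees whose root merge sits exactly `c`
  branchings below the dendrogram root; leaves that detach closer to the
  root become singletons. We interpret the root distance as an integer
  merge depth because the companion parameter `nlev` counts successive
  hierarchy levels, and a cut at small integer depths is what produces a
  handful of top-level modules. A cut deeper than the tree degrades
  gracefully to all singletons rather than failing.
* `height` — sever every merge above a height threshold (equivalent to
  `stats::cutree(h =)`). `cut_height_for_k()` computes the threshold that
  yields exactly *k* clusters, which is how the co-expression pipeline
  asks for "5 modules" robustly: a fixed `rootdist` level can split a
  shallow module or lump deep ones when tree shapes vary across datasets,
  whereas the height cut tuned to *k* is shape-invariant.

`nest_dendrogram()` then creates one container per cluster with at least
two members; for `nlev > 1` each cluster's child subtrees (one more
branching down) are nested inside it recursively. Singletons stay
unnested — a one-member module container carries no information. Any
previous containment of the affected leaves is replaced, so re-running the
mapping with new parameters is idempotent. If fewer levels exist than
`nlev` requests, the available levels are mapped silently.

`cut_clusters()` always returns a disjoint cover of the leaves, and the
outermost containers of `nest_dendrogram()` coincide with it by
construction; both properties are tested on random dendrograms.

## Inter-module connectivity

For two non-nested containers $A$, $B$ the aggregated module edge is

$$w(A,B) \;=\; \frac{\#\{\text{leaf edges between } A \text{ and } B\}}
                   {|A|\,|B|},$$

the cross-edge count divided by the number of possible cross pairs over
their *leaf descendants*. This bipartite-pair normalization is the only
one that makes the value a density in $[0,1]$, equal to 1 exactly when
the cross-bipartite graph is complete; it is what the SVG exporter draws
as module out-edge width. Edges are *counted*, not weight-summed, by
default ("sum of all edges" as a count); `weighted = TRUE` switches to
summing weights, in which case the result can exceed 1 if weights do.
A container paired with effectively one leaf uses $|A| \times 1$ pairs,
the consistent limit of the formula.

Annotation styling follows the same case-study conventions: a symmetric
diverging blue–white–red scale for signed values (log2 fold-changes; the
midpoint maps exactly to the neutral color, and the default domain is
$\pm\max|x|$ so that colors mirror across zero), and an *inverse* linear
size scale for nonnegative distances (kilobases from a transcription
start site to the nearest binding site), so genes close to a binding site
are drawn large. Constant input maps to the midrange size.

## Nested force-directed layout

The layout treats nodes as mutually repulsive charged particles and edges
as springs, with the classic spring-embedder force family: for distance
$d$ and length scale $k$ = `rest_length`,

$$f_\text{attract}(d) = d^2/k, \qquad
  f_\text{repel}(d) = \rho\, k^2/d,$$

which for an isolated connected pair balances exactly at $d = k$ — the
closed-form equilibrium the tests check to within 5%.

Nesting changes *who* interacts with whom:

* springs and repulsion act between **siblings** (nodes sharing a
  parent); containers participate as super-nodes at their own level;
* an edge whose endpoints live in different containers exerts its spring
  on the two enclosing representatives in their deepest common frame, not
  on the hidden members — so a container's interior reaches a local
  equilibrium independently of forces outside it;
* a member that drifts past 80% of its parent's radius feels a linear
  restoring force (stiffness 10 per unit overshoot) back toward the
  container center;
* moving a container rigidly carries everything inside it, and container
  centers are recomputed as member centroids after every step.

Updates are synchronous with simulated-annealing-style cooling: each
node's force displacement is scaled by a gain of 0.1 and capped by the
current temperature, which decays by the factor `cooling` every
iteration; the per-step cap is what makes the relaxation deterministic
and convergent. The gain, the 0.8 boundary fraction and the stiffness are
internal constants calibrated against the contracts above (pair
equilibrium within tolerance; empty `containment_check()` at
termination), since no canonical constants exist for the nested variant
of the algorithm. Container radii are `container_padding * sqrt(n_leaves)
* rest_length / 2` — area proportional to membership.

Initial positions are uniform in a square of side
$\sqrt{n}\,\cdot$`rest_length`, drawn from a private RNG stream seeded by
`params$seed` (the caller's RNG state is untouched). Consequences tested
as invariants: identical (graph, params) give bit-identical layouts; the
force field is translation-equivariant (no absolute-position forces —
containment is relative to the container center); temperature strictly
decreases and bounds every node's own-frame displacement. Coincident
nodes are separated by a small deterministic offset ordered by id, so no
seed is needed for tie-breaking. Layout is 2-D only; `layout_circle()`
and `layout_grid()` are provided as trivial static alternatives.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters (seed included) and
define the study conditions for the end-to-end tests.

`gen_modular_graph(m = 5, nmax = 30, p_in = 0.3, p_out = 0.01)` is a
planted-partition graph: modules are separable at these defaults (about
30% intra-module density versus 1% between), which is what makes
clustering the adjacency or expression rows recover them. The planted
label is a node attribute, not a container — nesting is the pipeline's
job.

`gen_scalefree(n)` implements the preferential-attachment step model: one
vertex and no edge first, then one vertex per step attached to an
existing vertex with probability proportional to degree + 1 (the +1 makes
the second vertex reachable). It always yields exactly $n-1$ edges and a
connected, right-skewed network — a tree, which is sparser than a real
protein–protein interactome of the same size.

`gen_expression()` draws one latent profile per module and adds gene-level
noise; at the default `effect = 4`, `noise = 1` the within-module
correlation is $\approx 16/17$, comfortably above the 0.7 co-expression
threshold. Log fold-changes are a module-level mean ($\sigma = 1.5$) plus
gene scatter ($\sigma = 0.3$); binding-site distances are exponential
with rate $\ln(1.5)/50$ per kb, so a third of genes fall within 50 kb —
mimicking the empirical observation that most regulatory binding sites
are distal.

`gen_timecourse()` draws the first DE set as a *connected snowball* (a
degree-biased seed vertex grown through random frontier expansion) and
tops up later sets uniformly from non-members after applying the
persistence probability `nested_fraction`. The snowball choice is
deliberate: differential expression mapped onto an interactome forms
largely connected neighborhoods (that is why selecting the largest
subnetwork per time point is informative at all), whereas a uniform
sample on a sparse scale-free tree induces near-empty subgraphs. With
`nested_fraction = 1` this makes the fully nested container chain a
structural consequence, not a lucky draw, while uniform top-ups keep the
zero-persistence overlap at its hypergeometric expectation. What the
generators do **not** emulate: real interactome density and clustering
coefficients, correlated noise between samples, microarray normalization
artifacts, or genuine differential-expression calling — passing tests
show the machinery is correct on data of the declared shape, not that any
biological conclusion transfers.

## The two workflows

`coexpression_pipeline()` builds the co-expression graph with a hard
threshold on absolute Pearson correlation (the simplest faithful method;
the threshold is exposed), drops zero-variance rows with a warning,
clusters the expression rows, superimposes the dendrogram (by default a
height cut tuned to `k = 5` clusters), aggregates module edges and styles
nodes by `logfc` and `kb_dist`. `module_recovery()` scores the result by
majority-label agreement between containers and planted modules; unnested
genes count as failures.

`timecourse_pipeline()` selects the largest connected component $L(t)$
per time point (ties broken by smallest lexicographic member) and chains
containers innermost-first: the container of $t$ nests inside that of
$t+1$ when $L(t) \subseteq L(t+1)$; otherwise the two sit side by side
joined by an association edge weighted by their overlap count, and
members already claimed by a later container stay where they are (the
containment forest forbids overlapping sibling containers). Empty
components are skipped with a warning. The consecutive overlap table
$|L(t) \cap L(t+1)|$ accompanies the graph.

## Numerical and interface choices

* Ties are broken lexicographically by id throughout (component
  selection, container ordering, coincident-node separation) — full
  reproducibility without hidden seeds.
* Duplicate edges keep the latest weight; directed input collapses to
  undirected on import, with a warning when the two orientations carry
  different weights.
* GraphML uses the compound dialect (a `<graph>` element inside each
  container's `<node>`), which preserves arbitrary nesting depth and is
  readable by standard tools; a childless container still gets an empty
  `<graph>` so kinds survive the round trip. Numeric attributes are
  written at full precision; GraphML, JSON and linkage-table round-trips
  are tested property-style on random graphs.
* SVG output flips the y axis (layout coordinates are Cartesian, screen
  y points down) and draws container circles before member glyphs, so
  containers sit beneath their contents; output bytes are deterministic.
* Test problem sizes are the package's own choices, kept deliberately
  small (operation sequences on graphs of up to 50 nodes, clustering
  oracles at up to 12 rows, 30-gene expression matrices, 200-node
  interactomes, 1000-vertex scale-free graphs) — large enough to exercise
  every contract, small enough that the whole suite runs in about a
  minute.

## Limitations

* Only complete linkage and Euclidean distance are built in; the cut
  semantics of `rootdist` are this package's formalization of an
  otherwise informal notion.
* The layout has no spatial acceleration structure; it is quadratic per
  sibling frame and intended for networks of hundreds, not hundreds of
  thousands, of visible nodes.
* Association-edge semantics beyond aggregated module links (e.g.
  reassigning an edge between layers) are minimal: the layer flag is
  stored, round-trips, and influences rendering, nothing more.
* The statistical significance of inter-module densities is out of
  scope; the density is a descriptive visual quantity.
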