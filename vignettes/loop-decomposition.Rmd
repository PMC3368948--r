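---
title: "Hierarchical loop decomposition: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical loop decomposition: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopnest)
```

## The problem and the model

Planar transport networks in biology — leaf venation, cortical arterial
vasculature, insect wing veins — are full of closed loops nested across
scales. The architecture of such a network is carried less by the exact
position of its elements than by *which loops sit inside which*, and how
strongly they are separated. `loopnest` quantifies this by mapping the
weighted planar graph to a binary *nesting tree* and measuring the tree.

Terminology: a **link** is a single graph element with a positive weight
(vessel width); an **edge** is a maximal chain of links whose interior
vertices have degree 2, with an aggregate **strength** (by default the
weakest member link; median and maximum are available); a **loop** is a
face of the embedding, and terminal loops (areoles, in a leaf) are the
faces of the full graph.

The decomposition deletes the globally weakest edge, merging the two loops
it separates into a node of the nesting tree whose height is the removed
strength, re-collapses any chains that meet at a now-degree-2 junction
(re-aggregating their strength), and repeats until one loop remains.
Under the minimum-strength rule the removal sequence is non-decreasing in
strength, so the tree reads as a filtration: cutting it at height *h*
shows the loop structure of the graph restricted to links thicker than
*h*.

Two exterior conventions are provided. In `single_exterior` mode the
unbounded region is one zero-area leaf; every boundary loop that loses its
outermost edge merges with it. In `phantom_boundary` mode an enclosing
polygon (the perimeter scaled by 1.2 about its centroid — the scale only
needs to keep the polygon clear of the graph) is connected to every
perimeter junction by an infinite-weight link, fragmenting the outside
into one phantom loop per junction. Phantom links are never removed, so
boundary neighborhood information survives in the tree. We take the
number of phantom loops from the perimeter junctions; each phantom loop
faces exactly one perimeter edge, which is the count of boundary faces on
convex patches such as the lattice fixtures.

Edges whose removal would disconnect the graph (bridges) do not merge two
loops. They are neutralized up front: each bridge weight is raised
infinitesimally above the maximum link weight of the component that would
be detached (the side with the smaller maximum, which finishes merging
first), so by the time the bridge could be removed it dangles and is
pruned. Disconnecting events that arise mid-decomposition (a chain whose
two sides have already merged) are deleted without a merge event and
counted in the tree's provenance; they are rare on the fixtures used here
and on digitized venation.

Areas: every node's area is the summed area of its constituent internal
faces; exterior and phantom leaves carry area 0, so area is additive at
every merge. The exterior flag propagates upward, letting topology metrics
keep exterior-containing subtrees while area metrics drop only zero-area
nodes. Treating composites that contain the exterior as area-less instead
would discard nearly every composite of an additive architecture (whose
merges all pass through the exterior) and would destroy the linear
cumulative size distribution that such architectures are known for.

## Metrics

**Partition asymmetry.** At a bifurcation with subtree degrees $r, s$
(degree = number of leaf descendants, exterior leaves included),

$$q = \frac{|r - s|}{r + s - 2}, \qquad q(1, 1) = 0.$$

The subtree asymmetry $A(n)$ is the weighted mean of $q$ over the
subtree's bifurcations; the default weights are uniform over all of them,
and a `weight_fn` argument accepts alternatives (e.g. no averaging). The
caterpillar tree of degree $d$ — the shape produced by a pure weight
gradient — has $A = (d-2)/(d-1)$ exactly, which the test suite uses as a
closed-form oracle; a complete binary tree has $A = 0$. The averaged
asymmetry $\Lambda(d)$ is the mean of $A$ over all bifurcations within
$\pm\delta$ of $d$ on the $\log_2$ axis, $\delta = 0.5$ by default. The
window is log-scaled because degrees of a balanced hierarchy are spread
geometrically; an unwindowed variant is recovered by shrinking $\delta$.

**Cumulative size distribution.** $P(A > a)$ over the areas of all
positive-area tree nodes, with total area normalized to 1. Additive
architectures give a straight line of slope $-1/2$ on linear axes (the
composite areas are uniformly spread, and composites make up half the
nodes); self-similar architectures give $P \propto 1/a$, so the adjusted
distribution $\tilde P(a) = a\,P(A>a)$ fluctuates about a constant, with
a periodicity reflecting the size of the architectural unit.

**Strahler.** Leaves have order 1; a parent takes the larger child order,
incremented when the children tie. $N_\omega$ counts maximal same-order
paths. $R_B$ is fitted by least squares on $\log N_\omega$ vs $\omega$,
constrained through $(1, \log N_1)$ because $N_1$ (the terminal-loop
count) is exact, with the highest order dropped as noise-dominated; with
fewer than three orders the two-point ratio is reported and flagged. The
logarithm base cancels in $R_B$.

## The generated models

All models share one weight multiset (ranks $1..L$ by default) on the same
hexagonal patch of the triangular lattice; `rings = 16` gives the
817-vertex substrate used for the headline figures. The lattice's three
families of parallel lines underlie the line-based models: lines are
ordered by recursive bisection (boundary and central lines order 0,
bisectors of order-$k$ spans order $k+1$, lower midpoint on odd spans),
and descending weights are dealt line by line in that order (`nested`),
after swapping the positions of 5 or 10 random line pairs (`nested5`,
`nested10`), or in a fully permuted line order (`random_lines`).
`gradient` sorts weights by distance from the left-most vertex (nearest =
thickest); `random_links` permutes weights uniformly; `peaks` places seven
peak points (centre plus a half-radius hexagon) and *grows* weights with
distance from the nearest peak.

The peaks orientation deserves a note: with the thickest links at the
peaks, the weakest-edge removal would start on the inter-peak ridges and
the peak neighborhoods would never form subtrees. With weights growing
away from the peaks, each peak seeds a radially growing basin — the same
dynamics as the single-source gradient model — the basins join at a
characteristic scale where $\Lambda(d)$ changes monotonicity, and a
seven-way cut of the tree reproduces the nearest-peak (Voronoi) partition
of the faces to within a few percent. Only this orientation yields the
documented phenomenology of the model, so it is the default; the
`peak_points` argument and a custom weight vector allow any other
arrangement.

Equal weights are made strictly orderable at load time by a seeded
perturbation of relative magnitude $10^{-9}$, small enough never to
reorder distinct widths from a digitization but sufficient to make the
removal order, and hence the tree, reproducible from the seed.

## Segmentation and cleaning

Cutting the nesting tree below its strongest merges segments the graph
into sectors. The `h_cutoff` criterion takes the maximal subtrees whose
root merge is weaker than the cutoff. The `k` criterion scans all cutoffs
and keeps the k maximal subtrees at the cutoff that maximizes the k-th
largest segment's face count: this targets the *major sectors* even when
the strongest merges are late-joining single loops (as in the peaks model,
where strong minor loops join after the basins), which a literal "cut the
k−1 strongest merges" would return as singleton segments. Faces outside
the k chosen subtrees stay unassigned.

Cleaning targets digitization artifacts: non-uniform staining inflates the
widths of small loops near major veins, which then survive to the end of
the decomposition and join through maximally asymmetric partitions. The
histogram of $q$ then shows a spike at $q = 1$ separated by a valley from
the bulk; `q_histogram()` reports the last robust interior minimum (a
smoothed local minimum at most half the height of its flanking maxima —
the robustness bar keeps featureless histograms from yielding spurious
thresholds) and `clean_tree()` removes, for every bifurcation with $q$
above the threshold (default 0.97), the smaller-degree child subtree, then
contracts the marked node and recomputes degrees and areas.

Because $q = 1$ for *every* partition that joins a single terminal loop to
a larger subtree, a 0.97 threshold also removes the genuine sequential
(1, k) joins present in additive and nested architectures — cleaning is a
normalizing transform, not a pure denoiser. Recovery is therefore assessed
between identically processed trees: the test fixture plants strong minor
loops along the major lines of a nested lattice, and after cleaning both
the contaminated and the pristine lattice at 0.97, their $\Lambda(d)$
agree to well within 0.05 at mid degrees while every planted face is
purged.

## Numerical and testing choices

Faces are extracted geometrically from the straight-line embedding by
half-edge traversal with counter-clockwise angular ordering; the face of
largest absolute signed area is the outer face. Face count obeys Euler's
formula and face areas sum to the hull area to $10^{-9}$ relative, both
asserted in the tests. The decomposition is validated against a
brute-force oracle that re-extracts faces and chains from scratch after
every single removal and identifies loops by point-in-polygon containment
of the original face centroids — no state shared with the incremental
implementation — and must agree exactly in topology and removal-strength
sequence on all small fixtures.

Problem sizes in the test suite: the analytic CSD signatures are checked
on the 16-ring lattice (1536 faces), decompose in under a second each;
ensemble comparisons of the stochastic models use 20 seeds on the 8-ring
lattice (384 faces) with mid-degrees defined as the central third of the
log₂-degree axis; the oracle runs on graphs of at most 8 faces, where the
from-scratch recomputation is exact and fast. The synthetic lattice models
emulate the *architectural* features of real venation — ordered vs
disordered weight fields on a fixed loopy topology — but not its
geometric irregularity, polydisperse areole sizes, measurement noise in
widths, or imaging artifacts other than the planted strong-loop
contamination; conclusions from passing tests transfer to real data only
at the level of the topological machinery, not as statements about any
species' venation.

One reproduction caveat is documented rather than hidden: among the
line-based models, increasing line-order disorder lowers the measured
mid-degree asymmetry slightly (by breaking small-scale order) before the
large-scale imbalance overtakes it, so the fine ordering
nested < nested5 < nested10 expected of progressively disordered variants
does not emerge at these lattice sizes under any construction we
implemented, while the coarse separations (the nested family vs
`random_lines` at upper-mid degrees, and `random_links` above
`random_lines`) are robust. The corresponding ensemble assertions are kept
in the acceptance tests at their stated thresholds and currently fail for
the fine chain.

## Limitations

Inputs must be straight-line planar embeddings with coordinates;
non-planar graphs and 3-D vasculature are out of scope, as are the
image-processing steps that digitize a specimen into an edge list.
Strongest-first or stochastic merge orders are not implemented. The
phantom-boundary construction assumes a simple perimeter; graphs whose
outer walk repeats vertices (cut vertices on the hull) must be decomposed
in single-exterior mode.
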