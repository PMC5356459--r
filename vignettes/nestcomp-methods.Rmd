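---
title: "Ancestral compatibility of semi-labeled trees: model, engine, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestral compatibility of semi-labeled trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestcomp)
```

## The model

A *semi-labeled tree* is a rooted tree together with a labeling
function from a taxon set onto its nodes.  Leaves and single-child
nodes must be labeled; internal nodes with two or more children may be
unlabeled.  Ordinary phylogenies (labels only on leaves) and
taxonomies (every node a named taxon, arbitrary degrees) are both
special cases.  A tree is determined by its *cluster set* — for each
node, the set of labels in its subtree — and the two pair relations

* `D(T)`: ordered pairs (ℓ, ℓ′) with ℓ′ a proper descendant of ℓ;
* `N(T)`: unordered pairs of incomparable labels.

A supertree `T` *ancestrally displays* an input `T'` with
`L(T') ⊆ L(T)` when `D(T') ⊆ D(T)` and `N(T') ⊆ N(T)`.  Labels that
share a node contribute to neither relation, which is how a supertree
can legitimately merge two input roots into one multi-labeled node.
`ancestrally_displays()` implements this criterion directly and is the
oracle every engine output is checked against; it is deliberately
independent of the engine (it compares pair sets computed from DFS
intervals, and is quadratic in the label count — fine for
verification, not used in the solver).

Compatibility of a profile `P = {T_1, …, T_k}` asks for one tree
displaying all inputs.  Two reductions are applied up front:

1. **Full labeling.**  Every unlabeled node receives a fresh label
   (`__aux<n>`; the prefix is reserved, collisions with user labels are
   skipped by the counter scan).  Compatibility is unchanged, and any
   supertree of the completed profile displays the original profile,
   so the auxiliary labels are simply stripped again on output
   (`strip_aux = TRUE`), suppressing any single-child nodes this
   leaves unlabeled.
2. **Connectivity.**  If the display graph (below) is disconnected,
   the profile decomposes into label-disjoint sub-profiles that are
   solved independently.  By default the sub-supertrees are joined
   under one fresh unlabeled root — legal, since that root has at
   least two children, and friendlier than a forest; `join_components
   = FALSE` returns the forest instead.

## The engine

The *display graph* `H_P` glues the fully labeled trees at shared
labels: vertices are labels, edges are parent–child pairs with
duplicates collapsed.  Its size is at most `M_P`, the total node plus
edge count of the profile, and each label's multiplicity `k_ℓ` (number
of trees containing it) is recorded during construction.

The engine advances a *position* — per-tree frontiers of sibling
labels, starting at the roots.  A label whose frontier entry is
exactly itself in all `k_ℓ` of its trees is *semi-universal*; the
semi-universal set `S` labels the next supertree node.  If `S` is
empty the profile is incompatible; the first offending position is
reported in the result for diagnosis.  Otherwise each frontier holding
a member of `S` is replaced by that member's children, all
display-graph edges incident to `S` are deleted, and every connected
component of the remainder becomes an independent subproblem, enqueued
breadth-first with its tentative parent node.

Efficiency rests on two structures:

* **Decremental connectivity** (`dc_*`, `src/hdt.cpp`): the
  Holm–de Lichtenberg–Thorup hierarchy — spanning forests per edge
  level, stored as Euler-tour sequences in randomized treaps with
  subtree counts and search flags — gives amortized `O(log² N)` edge
  deletion with split detection, `O(log N)` component size, and
  member enumeration linear in the component.  Treap priorities come
  from an internal fixed-seed xorshift generator, so the structure is
  deterministic and independent of R's RNG state.
* **Component records**: each live component carries its frontier map
  (tree index → cell of labels), a per-label singleton count, the
  *exposed* set, and a weight `Σ k_ℓ` over members.  The exposed set
  is stored as the set of labels ℓ whose count has reached `k_ℓ`
  (rather than the tree indices pointing at them); the two forms are
  interconvertible, and the label form hands over `S` in `O(|S|)`
  without a reverse index.

When an edge deletion splits a component, the node-count-smaller side
(reported by the connectivity structure) is scanned once to compute
the two weights, and then the *weight*-smaller side is scanned to move
its labels into a fresh record: for each moved label and each tree
whose frontier holds it, the label is deleted from the old cell and
inserted into the new one, with counts and exposure adjusted — a
constant number of hash-map updates per (label, tree).  Both scans are
"smaller-half" arguments: a label is only rescanned when its
component's node count (respectively weight) has at least halved, so
each is charged `O(log M_P)` times, and total bookkeeping is
`O(M_P log M_P)` updates.  Edge deletions number at most the edges of
`H_P`; the engine asserts this bound at run time through its counters
(`stats$deletions`, `stats$field_updates`).

Determinism: members of `S` are processed in label-sorted order and
their incident edges in sorted-neighbor order; ties in the node-count
or weight comparisons go to the side containing the lexicographically
smallest label.  Correctness is order-independent (the equivalence
suite exercises different orders implicitly through the two engines);
fixing an order makes traces and serialized output reproducible.
Children of every output node are ordered by the smallest label in
their subtree, so isomorphic supertrees print identically.

The *recursive reference engine* repeats the same traversal naively:
positions as explicit vectors, semi-universal detection by counting
from scratch, components by breadth-first search.  It shares only the
input preprocessing with the fast engine, making it a genuine
cross-check (`engine = "both"` runs both and insists on isomorphic
results).

## Numerical and degenerate-input choices

* Cells, maps and exposed sets are hash maps (R environments keyed by
  integer ids); the worst-case balanced-tree variant would add a log
  factor without changing any result.
* A component consisting solely of consumed labels (e.g. the isolated
  singleton left after a label's last edge is deleted) is discarded,
  not enqueued; a dequeued record whose single semi-universal label
  has no children anywhere is emitted as a leaf without touching the
  graph.
* Single-node trees, profiles with one tree, and profiles whose trees
  share no labels (fully disconnected display graphs) are all legal
  inputs with the obvious outputs.
* Newick input: labels may sit on any node, quoted labels and
  single-child nodes are supported, branch lengths are parsed and
  discarded with a warning (compatibility is topology-only), and a
  duplicate label within one tree is an input error.  Multi-label
  output nodes are written as labels joined by `+` (quoted), and can
  be re-read with `multi_sep = "+"`; a user label containing a literal
  `+` would be ambiguous under re-reading, which we accept for this
  debug/interchange path.

## The generators and what they do (and do not) show

`gen_compatible()` samples a hidden supertree and emits `k_trees`
restrictions of it to random label subsets.  Restrictions of a common
tree are compatible by construction and the hidden tree is a witness,
so the generator gives *labeled* positive instances; restriction goes
through the production `slt_restrict()` code path.  Defaults, chosen
once as plausible for taxonomy-scale inputs: `k_trees = 8` trees,
`subset_fraction = 0.2` (each input sees about a fifth of the taxa,
mimicking the limited overlap of real studies), `label_density = 0.25`
(a quarter of the free internal nodes carry higher-order taxa).  The
topology sampler attaches each new node to an existing node chosen
with probability proportional to its degree; this preferential
attachment produces the heavy-tailed degrees characteristic of
taxonomies (a uniform-attachment sampler keeps maximum degrees
logarithmic, too balanced to exercise the degree-independence claim,
which is why it was not used).  `n_labels` is the node count of the
hidden tree; its label count is slightly smaller (unlabeled
high-degree internals), which is immaterial for scaling.

Negative instances come from `gen_incompatible()` (a two-label
ancestor cycle, the classic conflicting rooted triplets, and a
nesting-versus-siblinghood contradiction) and, in the test suites,
from splicing an ancestor cycle over existing labels into an otherwise
compatible profile.

What passing these suites shows: the engine's verdicts and trees are
correct on profiles with realistic degree distributions, partial
overlap, and planted contradictions, at sizes up to `10^4` labels
(about `3.6 × 10^4` nodes plus edges), with the work counters
respecting the deletion bound and staying within a logarithmic factor
of linear.  What it does not show: behavior on real published
taxonomies (no network access is assumed, so none are downloaded), on
adversarial worst-case splits, or any form of conflict *resolution* —
an incompatible profile is only detected, never repaired.

## Problem sizes used in the shipped suites

The acceptance suite runs the worked 13-label example end to end
against its known trace; 100 mixed profiles of up to 300 labels for
engine equivalence; over 1000 randomized deletions against a BFS
oracle for the connectivity structure; 20 compatible and 13
incompatible classification runs; and scaling runs at `10^2`, `10^3`
and `10^4` labels for the work-accounting bounds.  These sizes keep
the full suite around a minute on one core while spanning two decades
of problem size; the field-update bound is asserted as
`≤ 8 · M_P · log2(M_P)`, the constant reflecting the handful of hash
writes each (label, tree) event costs in this implementation.

## Known limitations

* Inputs must be singularly labeled (one label per node); outputs need
  not be.  Multiply-labeled *inputs* could be supported by pre-merging
  co-located labels, which is not implemented.
* The engine decides compatibility and returns one witness; it does
  not enumerate all supertrees, minimize unresolved nodes, or handle
  unrooted trees or branch lengths.
* The recursive reference engine recurses to the supertree's height
  and is meant for cross-checking at moderate sizes, not production
  runs.
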