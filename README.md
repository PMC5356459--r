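# nestcomp

Ancestral compatibility testing and supertree construction for rooted
**semi-labeled trees** — phylogenies and taxonomies in which internal
nodes may carry higher-order taxon labels (a genus, a family, …), so
that taxa can be *nested* inside one another.

## The problem

Given a profile P = {T₁, …, T_k} of rooted semi-labeled trees over
partially overlapping label sets, is there a single tree T on the union
of the labels that *ancestrally displays* every input?  Writing

- D(Tᵢ) for the set of ordered pairs (ℓ, ℓ′) with ℓ′ a proper
  descendant of ℓ in Tᵢ, and
- N(Tᵢ) for the set of unordered pairs {ℓ, ℓ′} of incomparable labels,

T ancestrally displays Tᵢ exactly when D(Tᵢ) ⊆ D(T) and N(Tᵢ) ⊆ N(T):
every claimed ancestor/descendant relation and every claimed
divergence is preserved.  If such a T exists the profile is
*ancestrally compatible*, and `nestcomp` constructs a witness; if not,
it reports the incompatibility.  This is the decision problem at the
heart of taxonomy-aware supertree synthesis (e.g. combining published
phylogenies with the NCBI or Open Tree taxonomy).

## The algorithm

The engine works on the **display graph** H_P: after giving every
unlabeled node a fresh auxiliary label, the input trees are glued at
shared labels; vertices are labels, edges are parent–child pairs,
de-duplicated.  A *position* assigns each tree a frontier of sibling
labels, starting at the roots.  A label ℓ is **semi-universal** when
its frontier entry is exactly {ℓ} in all k_ℓ trees that contain it; the
semi-universal set S labels the next supertree node, the frontiers of S
are replaced by their children, the display-graph edges at S are
deleted, and each connected component of what remains is processed
independently.  An empty S proves incompatibility.

Component splits are detected by a decremental dynamic-connectivity
structure (the Holm–de Lichtenberg–Thorup hierarchy of Euler-tour
forests, implemented in C++), and per-component bookkeeping — frontier
map, singleton counts, exposed set, and a multiplicity weight used to
pick which side of a split to rescan — keeps the total work
near-linear: O(M_P log² M_P) time for M_P the total number of nodes
and edges in the profile, *independent of node degrees*, which matters
because taxonomies have nodes of very high degree.

A naive recursive implementation of the same traversal (explicit
positions, from-scratch counting, BFS components) is included as a
cross-check oracle, and every returned supertree can be verified
directly against the D/N criterion with `ancestrally_displays()`.

## A worked example

```r
library(nestcomp)

p <- example_profile()   # three small semi-labeled trees over a..i, 1..4
write_profile(p)
#> [1] "(((b,c)a,d,e)3,f)1;" "((a,d)g,e,(h,i)f)2;" "((b,c)4,d)g;"

res <- build_supertree(p, engine = "both")   # iterative + recursive cross-check
res
#> Profile is ancestrally compatible.
#>  Supertree: ((((b,c)'4+a',d)g,e)3,(h,i)f)'1+2';
#>  work: 17 edge deletions, 88 field updates

all(sapply(p$trees, function(t) ancestrally_displays(res$tree, t)))
#> [1] TRUE
```

The supertree's root carries the label set {1, 2} (the two input roots
turn out to name the same clade), `4+a` is a node labeled by both the
higher-order taxon `4` and the taxon `a`, and every ancestor/descendant
and incomparability relation of the three inputs is preserved.  A
contradictory profile is rejected:

```r
build_supertree(gen_incompatible("ancestor-cycle"))$compatible
#> [1] FALSE
```

There is also a command-line interface (installed under `exec/`):

```sh
nestcomp check profile.nwk          # prints supertree, exit 0; or INCOMPATIBLE, exit 1
nestcomp verify supertree.nwk profile.nwk
nestcomp gen --n-labels 100 --seed 1 --out profile.nwk
```

## Package layout

- `R/sltree.R` — semi-labeled tree model: clusters, restriction, D/N
  pair sets, the display oracle, full labeling.
- `R/displaygraph.R` — display graph and label multiplicities.
- `R/dyncon.R`, `src/hdt.cpp` — decremental dynamic connectivity.
- `R/engine.R` — the compatibility engine (iterative and recursive).
- `R/io.R`, `R/cli.R` — Newick I/O for labels on arbitrary nodes,
  command-line interface.
- `R/fixtures.R` — deterministic generators of compatible and
  incompatible profiles.
- `vignettes/nestcomp-methods.Rmd` — the model, the data structures,
  parameter choices, and known limitations.
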