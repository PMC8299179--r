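---
title: "Hierarchical scaffold networks: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical scaffold networks: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffnet)
```

## The problem

High-throughput screens and vendor libraries mix many chemotypes. Scaffold
analysis groups molecules by their ring-and-linker cores, but any *single*
scaffold definition fails in one of two ways: a concrete Bemis-Murcko
scaffold scatters closely related series into many clusters, while a fully
abstracted cyclic skeleton collapses unrelated chemistry into one. scaffnet
implements a multi-dimensional compromise: every molecule is described at
nine correlated abstraction levels simultaneously, the levels are connected
into one directed network, and activity enrichment is computed per node so
that an analyst can slide between abstraction levels along the
structure-activity signal.

## The nine representations

Two orthogonal axes define a 3 x 3 grid.

*Decoration* (how much side-chain context is kept on the core):

* **basic** — iterative deletion of all terminal atoms; the classical
  Bemis-Murcko scaffold: every ring plus the acyclic linkers between rings.
* **decorated** — terminal atoms attached through a bond of order greater
  than one (carbonyl, sulfonyl, imine-type decorations) are never pruned.
  Pruning of order-1 terminals iterates to a fixpoint, so a chain that ends
  in a protected atom survives in full.
* **augmented** — after iteratively removing terminal non-carbon atoms
  bonded by order 1, the single longest remaining side chain that ends in a
  carbon atom is retained on top of the decorated baseline. If the first
  step leaves no order-1 terminal atom, augmented and decorated coincide.

*Abstraction* (how much chemical labelling is kept):

* **scaffold** — element labels and bond orders kept;
* **framework** — every atom becomes the any-atom wildcard `*`, bond orders
  (including aromaticity) kept;
* **wireframe** — any-atom and any-bond: the pure cyclic skeleton.

Each grid step is a deterministic function of the less abstract cell, so
the grid commutes and representation sharing is monotone: molecules equal
at any cell are equal at every more abstract cell. This is what makes the
undirected component structure of the final network coincide exactly with
the clusters of the most abstracted (basic wireframe) representation — a
property the test-suite asserts on every generated library.

## Fragmentation rules

Three unbiased rules decompose any representation, exhaustively and
progressively (children of children, breadth-first, deduplicated by
canonical key):

1. **internal chain removal** — every maximal acyclic connector adjacent to
   at least two ring systems (or a direct ring-ring bond) is deleted; each
   ring-containing component of the remainder is a child.
2. **fused ring opening** — for each ring of a fused or spiro system, the
   atoms exclusive to that ring are deleted; shared atoms stay.
3. **internal ring removal** — a ring system whose deletion splits the rest
   of the graph into two or more ring-containing pieces is deleted, each
   piece becoming a child.

After a deletion, connector stubs left dangling toward the removed part are
pruned back to the nearest ring; decorations protected at the originator's
decoration level survive because protection is keyed on bond order, not on
bookkeeping. Fragments must contain at least one ring: chain-only leftovers
are discarded, since fragments exist to interconnect ring chemistry and
free chains would flood every cluster with trivial links.

Two readings of "internal chain" were possible: the strict one (a path of
degree-2 non-ring atoms) fails as soon as a connector carries a protected
decoration, e.g. a bridging carbonyl, whose carbon has degree 3. scaffnet
therefore treats a chain as a maximal connected set of non-ring atoms
together with whatever rides on it. Likewise, whether rule 1 deletes one
linker at a time or several at once changes only intermediate depths, never
the closed fragment set; one-at-a-time children are generated and the
breadth-first closure supplies the combinations.

Termination is structural: every child has strictly fewer atoms than its
originator. The default depth cap equals the ring count (enough for full
closure); `max_fragments` (default 5000) guards against pathological cages
and marks results truncated rather than failing.

## Canonical keys for wildcard graphs

Deduplication across molecules and levels needs a key that is equal exactly
when two graphs are isomorphic under (atom label, bond order) equality.
InChI-style identifiers cannot express any-atom/any-bond structures, so the
package computes its own canonical code: iterative colour refinement over
(label, bond order, neighbour colour) signatures, with backtracking
individualisation on the first non-singleton colour class and a
lexicographic-minimum rule over the resulting codes. The code doubles as
the node key; concrete structures additionally carry an OpenBabel canonical
SMILES and an InChIKey. Keys are validated in the tests against a
brute-force isomorphism oracle on random small graphs.

A human-readable linear encoding (a SMILES-like depth-first string over the
canonical atom order, with `*` for any atom and `~` for any bond) labels
network nodes and table rows; it is write-only and the canonical key stays
authoritative.

Aromatic bonds are preserved as a distinct order and never kekulized in
frameworks, so an aromatic six-ring framework and its saturated counterpart
remain distinct — bond-order information is exactly what the framework
level is meant to keep. Aromaticity is perceived once, at standardization
time, through ChemmineR/OpenBabel ring perception.

## Standardization

Input SMILES are neutralized (OpenBabel `neutralize`), reduced to the
largest covalent component (heavy-atom count, ties by molecular weight —
the screening-library convention for salts and solvates), and stripped of
stereochemistry and isotopes by round-tripping through the package's own
connectivity-only molblock. Acyclic molecules have no scaffold and are
skipped with a count rather than an error. These rules are declared
package policy: upstream protocols rarely publish their exact
standardization settings, so reproducibility is anchored to the rules
above rather than to any external tool's defaults.

## The network

Nodes are unique structures: one MOLECULE node per compound, one FRAMEWORK
node per unique representation key, FRAGMENT nodes after extension. When
several kinds collapse onto one key, the node records the least abstract
kind, ordering the axes as scaffold < framework < wireframe first and
augmented < decorated < basic second — the abstraction axis destroys
strictly more information than decoration pruning, so it dominates.
ABSTRACTION edges follow the grid toward increasing abstraction (12 per
molecule when all nine keys are distinct, fewer as cells collapse);
MEMBERSHIP edges attach each molecule to its least abstract node only,
keeping the table linear in the number of molecules (`dense_membership =
TRUE` restores all nine links when a strict flat edge dump is wanted);
FRAGMENTATION edges run originator to fragment. Everything except
MEMBERSHIP is a DAG, which the suite asserts with igraph.

Fragments are generated by default from the basic wireframe of each
cluster — the level at which small shared rings reconnect otherwise
disjoint clusters into a single navigable network — and any other kind can
be requested. Node and edge tables are written as Cytoscape-importable CSV
(`source,target,interaction`), plus optional GraphML.

## Activity classes and enrichment

Percent-inhibition values are stratified as inactive < 19, weak 19-33,
moderate 33-50, strong 50-80, very strong >= 80; moderate and above count
as active. Printed boundary pairs overlap in the source convention
(19-33, 33-50), so the package fixes half-open intervals with boundary
values assigned upward; 33 is moderate and therefore active, 80 is very
strong. Binary active flags are accepted directly and bypass the scheme.

For a node with molecule set M in a library with `A` actives and `I`
inactives (unclassified molecules excluded everywhere):

    EF(M) = (actives(M) / |M|) / (A / (A + I))

EF ranges from 0 to (A+I)/A. When several representation kinds collapse
onto one node, the per-kind molecule sets are nested, and the highest
per-kind EF is retained — the purest view of the chemotype wins, rather
than the union average. Fragment nodes aggregate the molecules of all
frameworks containing them (their superframeworks, found by reverse
reachability over fragmentation edges), each molecule counted once.
`filter_ef_zero()` removes EF = 0 nodes and re-attaches surviving
molecules to their least abstract surviving representation; since an
active molecule forces EF > 0 on every node it touches, filtering can
never disconnect an active path, and the suite asserts exactly that.
EF is displayed with one decimal; stored values keep full precision.

## The synthetic generator and what passing tests mean

`synthetic_library()` builds decorated variants of up to twelve template
ring systems (diaryl-pyrazole and furanone cores, biaryls, benzimidazoles,
piperazine amides, and similar drug-like templates) with substituents drawn
from a small palette, then plants activity: molecules of enriched scaffolds
draw percent inhibition uniformly in 40-95, all others in 0-15. The bands
sit clearly on either side of the 33 percent activity threshold, so the
planted enrichment factor of an enriched scaffold is analytically
1 / (fraction of molecules planted active) and recovery can be checked
exactly. Defaults (8 scaffolds, 10 molecules each, a quarter of scaffolds
enriched) give a small library with the two features the method needs:
several chemotypes per library and clean per-scaffold activity structure.

What the generator does *not* emulate: assay noise near the class
boundaries, activity cliffs inside a scaffold series, promiscuous
frequent-hitters, and the long-tailed scaffold-size distribution of real
vendor libraries. Passing the planted-recovery tests therefore shows the
bookkeeping — representation keys, membership, EF arithmetic, ranking — is
correct, not that the method separates signal from noise in a real
campaign.

The bundled `synthetic_cox2_library.csv` is a 35-compound stand-in
assembled from published COX-2 inhibitor structures (polmacoxib,
celecoxib, valdecoxib, and other marketed or clinical coxibs) plus
unrelated filler drugs; it exercises the full pipeline, including the
any-atom/any-bond wireframe query that retrieves exactly the
diaryl-heterocycle subset. It is a synthetic fixture, not the historical
816-compound development-phase dataset, whose published summary statistics
are therefore not reproducible from this package alone; drop a copy of
that table at `inst/extdata/cox2_table_s1.csv` (columns `smiles,id`) and
the acceptance tests will run the full published analysis against it.

## Numerical and scale choices

* Ring perception is a minimum cycle basis (Horton candidates, greedy GF(2)
  selection); ring membership for the matcher uses bridge detection, so it
  is basis-independent. The ring count is the cyclomatic number, computed
  on the basic scaffold, which books fused systems the way medicinal
  chemists count rings (naphthalene: 2).
* The augmented-scaffold "first identified" tie-break orders candidate
  chains by the canonical atom ranks of the pruned molecule, making the
  choice reproducible across input atom orders; equal-length automorphic
  chains give isomorphic results either way.
* The wildcard matcher constrains query ring bonds to target ring bonds, so
  a cyclic skeleton can never match an open chain of the same length.
* Test and acceptance problem sizes: the bundled 35-compound library for
  pipeline-level checks, random graphs of 4-10 atoms against brute-force
  oracles, synthetic libraries of 4 scaffolds x 5 molecules across 20 seeds
  for enrichment recovery. These sizes exercise every code path while
  keeping the default test run in the low minutes.

## Limitations

* Standardization is connectivity-level: tautomers remain distinct,
  protonation states beyond trivial neutralization are kept, and 3D/stereo
  information is deliberately discarded.
* The canonical-code search has no automorphism pruning; highly regular
  graphs far beyond drug size (hundreds of atoms of one element) would be
  slow. Drug-like molecules refine to discrete colourings almost
  immediately.
* Fragmentation of very dense fused cages can grow combinatorially; the
  fragment cap truncates with a warning instead of exhausting memory.
* EF carries no significance test; a node with one active molecule can top
  the maximum EF. Ranking therefore sorts by EF and then by the number of
  connected actives, and analysts should read both.
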