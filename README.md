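# scaffnet — multi-dimensional hierarchical scaffold network analysis

scaffnet is an R package for scaffold-centric structure-activity analysis
of screening libraries. Instead of committing to one scaffold definition,
it describes every molecule at **nine correlated abstraction levels** — the
3 × 3 grid of decoration (basic / decorated / augmented) × abstraction
(scaffold / framework / wireframe) — fragments those representations with
three unbiased rules, links everything into one oriented network, and
annotates each node with an activity **enrichment factor** so that hit
series, latent series and activity-carrying decorations can be read off the
network.

For a node with molecule set *M* in a library of *A* actives and *I*
inactives:

    MF ratio   = actives(M) / |M|
    Total ratio = A / (A + I)
    EF          = MF ratio / Total ratio

EF > 1 marks activity-enriched chemotypes; EF = 0 nodes can be filtered to
leave only the SAR-relevant paths. Frameworks (`*` any-atom, bond orders
kept) and wireframes (any-atom + any-bond cyclic skeletons) double as
wildcard substructure queries: a wireframe query clusters molecules with
the same ring topology regardless of heteroatom placement or bond order.

## Worked example

```r
library(scaffnet)

pol <- standardize("CC1(C)OC(c2ccc(S(N)(=O)=O)cc2)=C(c2cccc(F)c2)C1=O",
                   "polmacoxib")
nine_representations(pol)
#> <representation_set polmacoxib: 3 rings>
#>   augmented_scaffold   CC3C(C(C1:C:C:C:C:C:1)=C(C2:C:C:C(:C:C:2)S(=O)=O)O3)=O
#>   decorated_scaffold   C3(C1:C:C:C:C:C:1)=C(C2:C:C:C(:C:C:2)S(=O)=O)OCC3=O
#>   basic_scaffold       C3C(C1:C:C:C:C:C:1)=C(C2:C:C:C:C:C:2)OC3
#>   augmented_framework  **1**(=*(*1=*)*2:*:*:*:*:*:2)*3:*:*:*(*(=*)=*):*:*:3
#>   decorated_framework  *1**(=*(*1=*)*2:*:*:*:*:*:2)*3:*:*:*(*(=*)=*):*:*:3
#>   basic_framework      *1**(=*(*1)*2:*:*:*:*:*:2)*3:*:*:*:*:*:3
#>   augmented_wireframe  *~*(~*)~*1~*~*~*(~*~*~1)~*3~*~*(~*)~*(~*)~*~3~*2~*~*~*~*~*~2
#>   decorated_wireframe  *~*(~*)~*1~*~*~*(~*~*~1)~*3~*~*~*(~*)~*~3~*2~*~*~*~*~*~2
#>   basic_wireframe      *1~*~*~*(~*~*~1)~*3~*~*~*~*~3~*2~*~*~*~*~*~2
```

Reading the panel: the basic scaffold is polmacoxib's three-ring
Bemis-Murcko core; the decorated scaffold keeps the lactone C=O and the
sulfone oxygens; the augmented scaffold additionally keeps one methyl (the
longest carbon side chain). Frameworks replace elements by `*` but keep
aromatic/double bonds (`:`/`=`); wireframes keep only the skeleton (`~`).

The basic wireframe used as a generic query retrieves exactly the
diaryl-five-ring chemotype from the bundled 35-compound coxib-style
library:

```r
lib  <- read_compounds(synthetic_cox2_path())
wf   <- to_wireframe(basic_scaffold(pol$graph))
hits <- match_set(wf, lib)
length(hits)
#> [1] 12
head(hits, 4)
#> [1] "polmacoxib" "celecoxib"  "valdecoxib" "rofecoxib"

res <- run_scaffold_analysis(lib, output_dir = "out")
#> parsed 35 molecule(s)
#> unique frameworks: 203; connected components: 15
```

The 15 connected components equal the number of distinct basic wireframes
— the structural invariant of the network. `run_scaffold_analysis()`
writes the four Cytoscape-ready tables (`molecular_frameworks_per_smiles`,
`molecular_frameworks_list`, `network_attributes`, `network_edges`);
`run_enrichment_analysis()` adds `n_molecules`, `n_actives` and `EF` per
node, a framework ranking, optional EF = 0 filtering and optional fragment
extension (`fragments = TRUE`), which merges the components into one fully
connected network through shared ring fragments.

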