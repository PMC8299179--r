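test_that("percent inhibition classifies into the five activity classes", {
  got <- classify_activity(c(45, 10, 33, 19, 50, 80, 95, 18.9, NA))
  expect_equal(got$class,
               c("moderate", "inactive", "moderate", "weak", "strong",
                 "very strong", "very strong", "inactive", NA))
  expect_equal(got$is_active,
               c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, NA))
})

test_that("the enrichment factor follows the MF ratio / total ratio formula", {
  acts <- data.frame(
    compound_id = sprintf("m%03d", 1:100),
    is_active = c(rep(TRUE, 10), rep(FALSE, 90)),
    stringsAsFactors = FALSE)
  # node with 3 actives and 1 inactive in a 10/90 library: EF = 0.75/0.10
  ef <- enrichment_factor(c("m001", "m002", "m003", "m011"), acts)
  expect_equal(ef$ef, 7.5)
  expect_equal(ef$mf_ratio, 0.75)
  expect_equal(ef$total_ratio, 0.1)
  # the node holding every molecule has EF = 1
  expect_equal(enrichment_factor(acts$compound_id, acts)$ef, 1)
  # an all-inactive node has EF = 0
  expect_equal(enrichment_factor(c("m050", "m051"), acts)$ef, 0)
  # molecules are counted once even if listed twice
  expect_equal(enrichment_factor(c("m001", "m001", "m011"), acts)$mf_actives, 1)
  # no actives in the library: undefined denominator
  none <- data.frame(compound_id = c("a", "b"), is_active = FALSE)
  expect_error(enrichment_factor("a", none),
               class = "scaffnet_no_actives_error")
})

test_that("annotation keeps the highest EF when kinds collapse onto one key", {
  # toluene's basic/decorated scaffold and benzene's whole grid share keys:
  # the benzene-only kind (augmented, through toluene's chain) is purer
  cps <- standardize_smiles(c("Cc1ccccc1", "c1ccccc1"), ids = c("tol", "benz"),
                            is_active = c(FALSE, TRUE))
  repsets <- lapply(cps, nine_representations)
  net <- build_framework_network(repsets)
  net <- annotate_network(net, activity_map(cps))
  benz_key <- structure_key(cps[[2]]$graph)
  row <- net$nodes[net$nodes$key == benz_key, ]
  # union membership is both molecules, but the max-EF rule keeps the pure
  # benzene-only kind: EF = (1/1)/(1/2) = 2
  expect_equal(row$n_molecules, 2)
  expect_equal(row$EF, 2)
})

test_that("annotated EFs match a per-node recount oracle", {
  lib <- synthetic_library(n_scaffolds = 4, n_per_scaffold = 5, seed = 7)
  repsets <- lapply(lib, nine_representations)
  net <- annotate_network(build_framework_network(repsets), activity_map(lib))
  acts <- activity_map(lib)
  total_ratio <- mean(acts$is_active)
  mem <- net$memberships
  for (r in sample(which(net$nodes$node_class == "FRAMEWORK"), 10)) {
    key <- net$nodes$key[r]
    ix <- mem$key == key
    # recount: per contributing kind, max EF
    want <- max(vapply(unique(mem$representation_kind[ix]), function(k) {
      ids <- unique(mem$compound_id[ix & mem$representation_kind == k])
      frac <- mean(acts$is_active[acts$compound_id %in% ids])
      frac / total_ratio
    }, 0))
    expect_equal(net$nodes$EF[r], want, info = key)
    mols <- unique(mem$compound_id[ix])
    expect_equal(net$nodes$n_molecules[r], length(mols))
    expect_equal(net$nodes$n_actives[r],
                 sum(acts$is_active[acts$compound_id %in% mols]))
  }
  # activity totals are conserved across the node table
  expect_equal(sum(net$nodes$n_actives[net$nodes$node_class == "MOLECULE"]),
               sum(acts$is_active))
})

test_that("superframework EF aggregates molecules across containing frameworks", {
  # one all-active and one all-inactive scaffold of equal size sharing a ring
  cps <- standardize_smiles(
    c("c1ccc2ccccc2c1", "c1ccc2ccccc2c1C", "C1CCc2ccncc2C1", "CC1CCc2ccncc2C1"),
    ids = c("a1", "a2", "i1", "i2"),
    is_active = c(TRUE, TRUE, FALSE, FALSE))
  repsets <- lapply(cps, nine_representations)
  net <- build_framework_network(repsets)
  net <- extend_with_fragments(net, generate_fragments(repsets))
  acts <- activity_map(cps)
  ring6 <- structure_key(make_cycle(6, "*", "any"))
  ef <- superframework_ef(net, ring6, acts)
  # the shared 6-ring skeleton collects both wireframes: EF strictly between
  expect_equal(ef$mf_actives, 2)
  expect_equal(ef$mf_inactives, 2)
  expect_equal(ef$ef, 1)
  expect_error(superframework_ef(net, "missing", acts), "not present")
  # a fragment with a single containing framework inherits its molecule set
  net2 <- annotate_network(net, acts)
  frag_rows <- net2$nodes[net2$nodes$node_class == "FRAGMENT", ]
  expect_true(all(!is.na(frag_rows$EF)))
})

test_that("EF-zero filtering removes inactive branches and preserves actives", {
  lib <- synthetic_library(n_scaffolds = 4, n_per_scaffold = 5, seed = 3)
  repsets <- lapply(lib, nine_representations)
  net <- annotate_network(build_framework_network(repsets), activity_map(lib))
  filt <- filter_ef_zero(net)
  expect_true(all(filt$nodes$EF[filt$nodes$node_class != "MOLECULE"] > 0))
  expect_equal(sum(filt$nodes$node_class != "MOLECULE"),
               sum(net$nodes$node_class != "MOLECULE" &
                     !is.na(net$nodes$EF) & net$nodes$EF > 0))
  # no node on a path from an active molecule disappears
  acts <- activity_map(lib)
  active_ids <- acts$compound_id[acts$is_active]
  mem <- net$memberships
  active_keys <- unique(mem$key[mem$compound_id %in% active_ids])
  expect_true(all(active_keys %in% filt$nodes$key))
  expect_true(all(active_ids %in% filt$nodes$key))
  # all-active library: filtering is the identity on nodes
  lib2 <- synthetic_library(n_scaffolds = 2, n_per_scaffold = 4,
                            active_scaffold_fraction = 1, seed = 5)
  net2 <- annotate_network(
    build_framework_network(lapply(lib2, nine_representations)),
    activity_map(lib2))
  expect_equal(nrow(filter_ef_zero(net2)$nodes), nrow(net2$nodes))
})
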