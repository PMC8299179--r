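test_that("internal chain removal splits connectors between ring systems", {
  ex <- worked_examples()
  dpe <- basic_scaffold(ex$internal_chain$graph)
  ch <- remove_internal_chains(dpe)
  expect_length(ch, 1)  # both halves are benzene, deduplicated
  expect_true(graphs_isomorphic(ch[[1]], standardize("c1ccccc1")$graph))
  # direct ring-ring bonds count as zero-atom linkers
  biph <- standardize("c1ccccc1-c1ccccc1")$graph
  ch2 <- remove_internal_chains(biph)
  expect_length(ch2, 1)
  # a lone ring has no internal chain
  expect_length(remove_internal_chains(standardize("c1ccccc1")$graph), 0)
})

test_that("fused ring opening deletes ring-exclusive atoms only", {
  nap <- standardize("c1ccc2ccccc2c1")$graph
  ch <- open_fused_rings(nap)
  expect_length(ch, 1)
  expect_true(graphs_isomorphic(ch[[1]], standardize("c1ccccc1")$graph))
  # indole-like 6-5 skeleton opens into a 6-ring and a 5-ring
  ind <- mol_graph(rep("*", 9),
                   data.frame(i = c(1, 2, 3, 4, 5, 6, 6, 7, 8, 9),
                              j = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 5),
                              order = "any"))
  ch2 <- open_fused_rings(ind)
  expect_setequal(vapply(ch2, n_atoms, 0L), c(6L, 5L))
  # single isolated ring: nothing to open
  expect_length(open_fused_rings(standardize("C1CCCCC1")$graph), 0)
})

test_that("internal ring removal splits the remainder or emits nothing", {
  ter <- standardize("c1ccc(-c2ccc(-c3ccccc3)cc2)cc1")$graph
  ch <- remove_internal_rings(ter)
  expect_length(ch, 1)  # two identical terminal benzenes, deduplicated
  expect_true(graphs_isomorphic(ch[[1]], standardize("c1ccccc1")$graph))
  # neither ring of biphenyl is internal
  biph <- standardize("c1ccccc1-c1ccccc1")$graph
  expect_length(remove_internal_rings(biph), 0)
  # wireframe-level: same topology, same behaviour
  terw <- to_wireframe(ter)
  chw <- remove_internal_rings(terw)
  expect_length(chw, 1)
  expect_identical(structure_key(chw[[1]]),
                   structure_key(to_wireframe(standardize("c1ccccc1")$graph)))
})

test_that("fragments embed into their originators and strictly shrink", {
  pol <- worked_examples()$polmacoxib
  for (g in list(basic_scaffold(pol$graph),
                 to_wireframe(basic_scaffold(pol$graph)))) {
    frs <- enumerate_fragments(g)
    expect_gt(length(frs), 0)
    key2graph <- stats::setNames(lapply(frs, `[[`, "graph"),
                                 vapply(frs, `[[`, "", "key"))
    key2graph[[structure_key(g)]] <- g
    for (fr in frs) {
      orig <- key2graph[[fr$originator_key]]
      expect_lt(n_atoms(fr$graph), n_atoms(orig))
      expect_true(isTRUE(generic_match(fr$graph, orig)))
    }
  }
})

test_that("the closure is deduplicated soundly and order-independent", {
  # independent closure: depth-first, shuffled rule order, brute-force
  # isomorphism dedup instead of canonical keys
  brute_closure <- function(g, seed) {
    set.seed(seed)
    acc <- list()
    visit <- function(h) {
      rules <- list(remove_internal_chains, open_fused_rings,
                    remove_internal_rings)
      for (rule in sample(rules)) {
        for (child in rule(h)) {
          dup <- any(vapply(acc, function(x) brute_iso(x, child), TRUE))
          if (!dup) {
            acc[[length(acc) + 1L]] <<- child
            visit(child)
          }
        }
      }
    }
    visit(g)
    acc
  }
  cases <- list(
    to_wireframe(standardize("c1ccc(-c2ccc(-c3ccccc3)cc2)cc1")$graph),
    to_wireframe(standardize("c1ccc2ccccc2c1CC1CCC1")$graph),
    standardize("C1CC1c1ccccc1")$graph)
  for (g in cases) {
    frs <- enumerate_fragments(g)
    keys <- sort(vapply(frs, `[[`, "", "key"))
    for (seed in c(1, 2)) {
      bc <- brute_closure(g, seed)
      expect_identical(sort(vapply(bc, structure_key, "")), keys)
    }
    # dedup soundness: all pairs are non-isomorphic
    gs <- lapply(frs, `[[`, "graph")
    for (a in seq_along(gs)) for (b in seq_along(gs)) {
      if (a < b && n_atoms(gs[[a]]) <= 8 && n_atoms(gs[[b]]) <= 8)
        expect_false(brute_iso(gs[[a]], gs[[b]]))
    }
  }
})

test_that("irreducible graphs yield an empty closure and depth caps bite", {
  expect_length(enumerate_fragments(standardize("c1ccccc1")$graph), 0)
  ter <- to_wireframe(standardize("c1ccc(-c2ccc(-c3ccccc3)cc2)cc1")$graph)
  d1 <- enumerate_fragments(ter, max_depth = 1)
  expect_true(all(vapply(d1, `[[`, 0L, "depth") == 1L))
  full <- enumerate_fragments(ter)
  expect_gte(length(full), length(d1))
  expect_warning(enumerate_fragments(ter, max_fragments = 1L), "truncated")
})
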