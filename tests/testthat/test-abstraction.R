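test_that("basic scaffold prunes terminal atoms down to rings and linkers", {
  tol <- standardize("Cc1ccccc1")$graph
  benzene <- standardize("c1ccccc1")$graph
  expect_true(graphs_isomorphic(basic_scaffold(tol), benzene))
  # no terminal atoms: the scaffold is the molecule itself
  dpe <- standardize("c1ccccc1CCc1ccccc1")$graph
  expect_true(graphs_isomorphic(basic_scaffold(dpe), dpe))
  expect_error(basic_scaffold(standardize("CCO")$graph),
               class = "scaffnet_no_ring_error")
})

test_that("decorated scaffold protects terminal atoms bonded by order > 1", {
  aceto <- standardize("CC(=O)c1ccccc1")$graph
  dec <- decorated_scaffold(aceto)
  # methyl pruned; carbonyl O protected, so its carbon is retained
  expect_equal(n_atoms(dec), 8)
  expect_true(graphs_isomorphic(dec, standardize("O=Cc1ccccc1")$graph))
  # no multi-order terminals: decorated equals basic
  tol <- standardize("Cc1ccccc1")$graph
  expect_identical(structure_key(decorated_scaffold(tol)),
                   structure_key(basic_scaffold(tol)))
})

test_that("augmented scaffold retains the longest carbon side chain", {
  ex <- worked_examples()
  # three candidate paths of different length: the longest survives
  aug <- augmented_scaffold(ex$chains_three_paths$graph)
  expect_true(graphs_isomorphic(aug, standardize("CCCCc1ccccc1")$graph))
  # two equal-length longest paths: deterministic tie-break, one survives
  aug2 <- augmented_scaffold(ex$chains_tied_paths$graph)
  expect_true(graphs_isomorphic(aug2, standardize("CCCc1ccccc1")$graph))
  # and the tie-break does not depend on the input atom order
  alt <- standardize("c1ccccc1C(CC)CC")$graph
  expect_identical(structure_key(augmented_scaffold(alt)),
                   structure_key(aug2))
  # a single path is kept whole
  aug3 <- augmented_scaffold(ex$chain_single_path$graph)
  expect_true(graphs_isomorphic(aug3, ex$chain_single_path$graph))
  # a lone -OH is removed in step 1: augmented equals basic
  phen <- standardize("Oc1ccccc1")$graph
  expect_identical(structure_key(augmented_scaffold(phen)),
                   structure_key(basic_scaffold(phen)))
})

test_that("abstraction operators are idempotent", {
  for (smi in c("CC(=O)c1ccccc1", "CCCC(C)(CC)c1ccccc1",
                "CC1(C)OC(c2ccc(S(N)(=O)=O)cc2)=C(c2cccc(F)c2)C1=O")) {
    g <- standardize(smi)$graph
    for (f in list(basic_scaffold, decorated_scaffold, augmented_scaffold)) {
      s <- f(g)
      expect_identical(structure_key(f(s)), structure_key(s))
    }
    w <- to_wireframe(g)
    expect_identical(structure_key(to_wireframe(w)), structure_key(w))
  }
})

test_that("the nine-representation grid commutes", {
  for (cp in cox2_library()[c(1, 2, 17, 25)]) {
    g <- cp$graph
    expect_identical(structure_key(to_wireframe(to_framework(basic_scaffold(g)))),
                     structure_key(to_wireframe(basic_scaffold(g))))
    expect_identical(structure_key(basic_scaffold(decorated_scaffold(g))),
                     structure_key(basic_scaffold(g)))
    expect_identical(structure_key(decorated_scaffold(augmented_scaffold(g))),
                     structure_key(decorated_scaffold(g)))
  }
})

test_that("nine_representations returns all nine kinds with coherent keys", {
  pol <- worked_examples()$polmacoxib
  rs <- nine_representations(pol)
  expect_named(rs$reps, representation_kinds()$kind, ignore.order = TRUE)
  expect_equal(rs$ring_count, 3)
  # decoration axis is genuinely three-levelled for polmacoxib
  expect_gt(length(unique(vapply(rs$reps, `[[`, "", "key"))), 6)
  # benzene: the decoration axis degenerates, three distinct keys remain
  benz <- nine_representations(standardize("c1ccccc1", "benzene"))
  expect_length(unique(vapply(benz$reps, `[[`, "", "key")), 3)
  expect_error(nine_representations(standardize("CCO", "ethanol")),
               class = "scaffnet_no_ring_error")
})

test_that("representation sharing is monotone along abstraction steps", {
  repsets <- cox2_repsets()
  kinds <- representation_kinds()
  # if two molecules share a key at one kind they share the basic wireframe
  keytab <- sapply(repsets, function(rs) vapply(rs$reps, `[[`, "", "key"))
  for (k in kinds$kind) {
    kk <- keytab[k, ]
    for (key in unique(kk[duplicated(kk)])) {
      members <- which(kk == key)
      expect_length(unique(keytab["basic_wireframe", members]), 1)
    }
  }
})

test_that("scaffolds embed into their more decorated versions", {
  for (cp in cox2_library()[c(1, 3, 19)]) {
    g <- cp$graph
    b <- basic_scaffold(g); d <- decorated_scaffold(g)
    a <- augmented_scaffold(g)
    expect_true(isTRUE(generic_match(b, d)))
    expect_true(isTRUE(generic_match(d, a)))
    expect_true(isTRUE(generic_match(to_wireframe(b), g)))
  }
})
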