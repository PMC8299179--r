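test_that("a molecule with nine distinct keys yields the full grid", {
  pol <- worked_examples()$polmacoxib
  rs <- nine_representations(pol)
  expect_length(unique(vapply(rs$reps, `[[`, "", "key")), 9)
  net <- build_framework_network(list(rs))
  expect_equal(sum(net$nodes$node_class == "FRAMEWORK"), 9)
  expect_equal(sum(net$nodes$node_class == "MOLECULE"), 1)
  expect_equal(sum(net$edges$edge_class == "ABSTRACTION"), 12)
  expect_equal(sum(net$edges$edge_class == "MEMBERSHIP"), 1)
  # membership points to the least abstract representation
  m <- net$edges[net$edges$edge_class == "MEMBERSHIP", ]
  expect_equal(m$target_key, rs$reps$augmented_scaffold$key)
})

test_that("degenerate decoration axes collapse nodes and edges", {
  rs <- nine_representations(standardize("c1ccccc1", "benzene"))
  net <- build_framework_network(list(rs))
  expect_equal(sum(net$nodes$node_class == "FRAMEWORK"), 3)
  expect_equal(sum(net$edges$edge_class == "ABSTRACTION"), 2)
  # node kind records the least abstract origin
  expect_setequal(
    net$nodes$representation_kind[net$nodes$node_class == "FRAMEWORK"],
    c("augmented_scaffold", "augmented_framework", "augmented_wireframe"))
})

test_that("empty input gives empty tables", {
  net <- build_framework_network(list())
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("component count equals the number of unique basic wireframes", {
  repsets <- cox2_repsets()
  net <- build_framework_network(repsets)
  wf_keys <- unique(vapply(repsets, function(rs) rs$reps$basic_wireframe$key, ""))
  expect_equal(network_components(net)$count, length(wf_keys))
  # and it agrees with an independent union-find over the same edge list
  expect_equal(network_components(net)$count,
               uf_components(net$nodes$key,
                             net$edges$source_key, net$edges$target_key))
})

test_that("components agree with union-find on random edge sets", {
  set.seed(31)
  for (rep in 1:10) {
    nv <- sample(5:20, 1)
    keys <- paste0("n", seq_len(nv))
    ne <- sample(1:(nv + 3), 1)
    from <- sample(keys, ne, replace = TRUE)
    to <- sample(keys, ne, replace = TRUE)
    net <- structure(list(
      nodes = data.frame(key = keys, node_class = "FRAMEWORK",
                         representation_kind = "", structure = "",
                         stringsAsFactors = FALSE),
      edges = data.frame(source_key = from, target_key = to,
                         edge_class = "ABSTRACTION", stringsAsFactors = FALSE),
      memberships = data.frame()), class = "scaffold_network")
    expect_equal(network_components(net)$count,
                 uf_components(keys, from, to))
  }
})

test_that("the abstraction/fragmentation graph is a DAG", {
  repsets <- cox2_repsets()[1:12]
  net <- build_framework_network(repsets)
  net <- extend_with_fragments(net, generate_fragments(repsets))
  e <- net$edges[net$edges$edge_class != "MEMBERSHIP", ]
  ig <- igraph::graph_from_data_frame(
    e[, c("source_key", "target_key")], directed = TRUE,
    vertices = data.frame(name = net$nodes$key))
  expect_true(igraph::is_dag(ig))
})

test_that("fragment extension merges components through shared fragments", {
  # two fused bicyclics with no common representation but a shared 6-ring
  a <- standardize("c1ccc2ccccc2c1", "naphthalene")        # 6-6
  d <- standardize("c1ccc2[nH]ccc2c1", "indole_like")      # 6-5
  repsets <- lapply(list(a, d), nine_representations)
  net <- build_framework_network(repsets)
  expect_equal(network_components(net)$count, 2)
  frs <- generate_fragments(repsets)
  net2 <- extend_with_fragments(net, frs)
  expect_equal(network_components(net2)$count, 1)
  expect_true(any(net2$nodes$node_class == "FRAGMENT"))
  # fragments identical to existing frameworks must reuse the node
  expect_false(any(duplicated(net2$nodes$key)))
  # dangling originators are a consistency error
  fake <- structure(list(graph = make_cycle(6, "*", "any"),
                         key = structure_key(make_cycle(6, "*", "any")),
                         rule = "CHAIN_REMOVAL", depth = 1L,
                         originator_key = "nonexistent"),
                    class = "fragment_record")
  expect_error(extend_with_fragments(net, list(fake)), "originator")
})

test_that("small rings collect the highest indegree in the extended network", {
  repsets <- cox2_repsets()
  net <- extend_with_fragments(build_framework_network(repsets),
                               generate_fragments(repsets))
  deg <- fragment_indegree(net)
  expect_gt(nrow(deg), 0)
  # the top in-degree fragment is a plain small ring
  g6 <- structure_key(make_cycle(6, "*", "any"))
  g5 <- structure_key(make_cycle(5, "*", "any"))
  expect_true(deg$key[1] %in% c(g5, g6))
})

test_that("network writers emit Cytoscape-compatible CSV", {
  repsets <- cox2_repsets()[1:5]
  net <- build_framework_network(repsets)
  nfile <- tempfile(fileext = ".csv"); efile <- tempfile(fileext = ".csv")
  write_network_csv(net, nfile, efile)
  nodes <- read.csv(nfile, stringsAsFactors = FALSE)
  edges <- read.csv(efile, stringsAsFactors = FALSE)
  expect_true(all(c("key", "node_class", "structure") %in% names(nodes)))
  expect_identical(names(edges)[1:3], c("source", "target", "interaction"))
  expect_true(all(edges$source %in% nodes$key))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_true(file.size(gml) > 0)
})
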