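#' Oriented framework network
#'
#' Nodes are unique structures: one MOLECULE node per compound, one
#' FRAMEWORK node per unique representation key (annotated with the least
#' abstract kind that produced it), and, after extension, FRAGMENT nodes.
#' ABSTRACTION edges follow the 3 x 3 representation grid in the direction
#' of increasing abstraction, collapsing when adjacent representations share
#' a key; MEMBERSHIP edges attach each molecule to its least abstract
#' representation; FRAGMENTATION edges run from an originator structure to
#' its fragments. The graph restricted to non-membership edges is acyclic.
#'
#' @name framework-network
NULL

grid_steps <- function() {
  # (from_kind, to_kind) pairs, one per adjacent grid step, oriented toward
  # increasing abstraction
  steps <- list()
  for (a in c("scaffold", "framework", "wireframe")) {
    steps[[length(steps) + 1L]] <- c(paste0("augmented_", a), paste0("decorated_", a))
    steps[[length(steps) + 1L]] <- c(paste0("decorated_", a), paste0("basic_", a))
  }
  for (d in c("augmented", "decorated", "basic")) {
    steps[[length(steps) + 1L]] <- c(paste0(d, "_scaffold"), paste0(d, "_framework"))
    steps[[length(steps) + 1L]] <- c(paste0(d, "_framework"), paste0(d, "_wireframe"))
  }
  steps
}

#' Build the framework network from representation sets
#'
#' @param repsets list of `representation_set` objects (see
#'   [nine_representations()]).
#' @param dense_membership if `TRUE`, each molecule is attached to every one
#'   of its distinct representation nodes instead of only the least abstract
#'   one.
#' @return a `scaffold_network`: list with data frames `nodes` (`key`,
#'   `node_class`, `representation_kind`, `structure`), `edges`
#'   (`source_key`, `target_key`, `edge_class`) and `memberships`
#'   (`compound_id`, `representation_kind`, `key`).
#' @export
build_framework_network <- function(repsets, dense_membership = FALSE) {
  kinds <- representation_kinds()
  if (length(repsets) == 0) {
    return(structure(list(
      nodes = data.frame(key = character(), node_class = character(),
                         representation_kind = character(),
                         structure = character(), stringsAsFactors = FALSE),
      edges = data.frame(source_key = character(), target_key = character(),
                         edge_class = character(), stringsAsFactors = FALSE),
      memberships = data.frame(compound_id = character(),
                               representation_kind = character(),
                               key = character(), stringsAsFactors = FALSE)),
      class = "scaffold_network"))
  }
  mem <- do.call(rbind, lapply(repsets, function(rs) {
    data.frame(compound_id = rs$compound_id,
               representation_kind = names(rs$reps),
               key = vapply(rs$reps, `[[`, "", "key"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  # framework nodes: unique key, least abstract contributing kind
  mem$abstractness <- kinds$abstractness[match(mem$representation_kind, kinds$kind)]
  ord <- order(mem$key, mem$abstractness)
  first <- mem[ord, ][!duplicated(mem$key[ord]), , drop = FALSE]
  # structures for node labels (from the first contributing repset)
  key_graph <- new.env(parent = emptyenv())
  for (rs in repsets) for (k in names(rs$reps)) {
    key <- rs$reps[[k]]$key
    if (!exists(key, envir = key_graph, inherits = FALSE))
      assign(key, rs$reps[[k]]$graph, envir = key_graph)
  }
  fw_nodes <- data.frame(
    key = first$key, node_class = "FRAMEWORK",
    representation_kind = first$representation_kind,
    structure = vapply(first$key,
                       function(k) encode_structure(get(k, envir = key_graph)),
                       "", USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
  mol_nodes <- data.frame(
    key = vapply(repsets, `[[`, "", "compound_id"),
    node_class = "MOLECULE", representation_kind = "",
    structure = "", stringsAsFactors = FALSE)
  nodes <- rbind(mol_nodes, fw_nodes[order(fw_nodes$key), , drop = FALSE])
  # abstraction edges along the grid, collapsed and deduplicated
  steps <- grid_steps()
  e_src <- character(); e_tgt <- character()
  for (rs in repsets) {
    keys <- vapply(rs$reps, `[[`, "", "key")
    for (st in steps) {
      a <- keys[[st[1]]]; b <- keys[[st[2]]]
      if (a != b) { e_src <- c(e_src, a); e_tgt <- c(e_tgt, b) }
    }
  }
  edges <- unique(data.frame(source_key = e_src, target_key = e_tgt,
                             edge_class = "ABSTRACTION",
                             stringsAsFactors = FALSE))
  # membership edges
  if (dense_membership) {
    mm <- unique(mem[, c("compound_id", "key")])
    medges <- data.frame(source_key = mm$compound_id, target_key = mm$key,
                         edge_class = "MEMBERSHIP", stringsAsFactors = FALSE)
  } else {
    least <- mem[mem$representation_kind == "augmented_scaffold", , drop = FALSE]
    medges <- data.frame(source_key = least$compound_id,
                         target_key = least$key,
                         edge_class = "MEMBERSHIP", stringsAsFactors = FALSE)
  }
  edges <- rbind(edges, medges)
  rownames(edges) <- NULL
  mem$abstractness <- NULL
  structure(list(nodes = nodes, edges = edges, memberships = mem),
            class = "scaffold_network")
}

#' @export
print.scaffold_network <- function(x, ...) {
  tab <- table(x$nodes$node_class)
  cat(sprintf("<scaffold_network: %s; %d edges; %d components>\n",
              paste(names(tab), tab, sep = "=", collapse = ", "),
              nrow(x$edges), network_components(x)$count))
  invisible(x)
}

#' Connected components of the network
#'
#' Components are computed on the undirected graph over all edges (isolated
#' nodes count as their own component). Without fragment nodes the component
#' count equals the number of distinct basic-wireframe keys.
#'
#' @param network a `scaffold_network`.
#' @return list with `count` and `membership` (data frame `key`,
#'   `component`).
#' @export
network_components <- function(network) {
  keys <- network$nodes$key
  if (length(keys) == 0) return(list(count = 0L, membership = data.frame(
    key = character(), component = integer(), stringsAsFactors = FALSE)))
  ig <- igraph::graph_from_data_frame(
    network$edges[, c("source_key", "target_key")],
    directed = FALSE, vertices = data.frame(name = keys))
  comp <- igraph::components(ig)
  list(count = comp$no,
       membership = data.frame(key = keys,
                               component = as.integer(comp$membership),
                               stringsAsFactors = FALSE))
}

#' Generate fragments for network representations
#'
#' Runs the fragmentation closure on each unique representation structure of
#' the requested kinds, so the records can be merged into the network with
#' [extend_with_fragments()].
#'
#' @param repsets list of `representation_set` objects.
#' @param kinds representation kinds to fragment (default the basic
#'   wireframe, which is what interconnects the clusters; use
#'   `representation_kinds()$kind` for all nine).
#' @param max_depth,max_fragments passed to [enumerate_fragments()].
#' @return list of `fragment_record` objects.
#' @export
generate_fragments <- function(repsets, kinds = "basic_wireframe",
                               max_depth = NULL, max_fragments = 5000L) {
  seen <- character()
  records <- list()
  for (rs in repsets) {
    for (k in intersect(kinds, names(rs$reps))) {
      key <- rs$reps[[k]]$key
      if (key %in% seen) next
      seen <- c(seen, key)
      records <- c(records, enumerate_fragments(rs$reps[[k]]$graph,
                                                max_depth = max_depth,
                                                max_fragments = max_fragments))
    }
  }
  records
}

#' Extend the network with fragment nodes and fragmentation edges
#'
#' Fragment nodes are merged by key: a fragment identical to an existing
#' framework reuses that node. Edges run from the originator structure to
#' the fragment. Components can merge, since small fragments are shared by
#' many molecules.
#'
#' @param network a `scaffold_network`.
#' @param fragments list of `fragment_record` objects whose originator keys
#'   are present in the network (directly or as earlier fragments).
#' @return the extended network.
#' @export
extend_with_fragments <- function(network, fragments) {
  if (length(fragments) == 0) return(network)
  known <- c(network$nodes$key, vapply(fragments, `[[`, "", "key"))
  orig <- vapply(fragments, `[[`, "", "originator_key")
  dangling <- setdiff(orig, known)
  if (length(dangling) > 0)
    stop("fragment originator key(s) absent from the network: ",
         paste(utils::head(dangling, 3), collapse = ", "))
  new_keys <- setdiff(vapply(fragments, `[[`, "", "key"), network$nodes$key)
  if (length(new_keys) > 0) {
    idx <- match(new_keys, vapply(fragments, `[[`, "", "key"))
    add <- data.frame(
      key = new_keys, node_class = "FRAGMENT",
      representation_kind = vapply(fragments[idx], `[[`, "", "rule"),
      structure = vapply(fragments[idx],
                         function(f) encode_structure(f$graph), ""),
      stringsAsFactors = FALSE)
    network$nodes <- rbind(network$nodes, add)
  }
  fedges <- unique(data.frame(
    source_key = orig,
    target_key = vapply(fragments, `[[`, "", "key"),
    edge_class = "FRAGMENTATION", stringsAsFactors = FALSE))
  fedges <- fedges[fedges$source_key != fedges$target_key, , drop = FALSE]
  network$edges <- rbind(network$edges, fedges)
  rownames(network$edges) <- NULL
  network
}

#' In-degree ranking of fragment nodes
#'
#' Number of incoming fragmentation edges per node, i.e. how many distinct
#' originator structures share each fragment; small common rings rank top.
#'
#' @param network an extended `scaffold_network`.
#' @return data frame `key`, `structure`, `indegree`, sorted decreasing.
#' @export
fragment_indegree <- function(network) {
  fe <- network$edges[network$edges$edge_class == "FRAGMENTATION", ,
                      drop = FALSE]
  tab <- table(fe$target_key)
  out <- data.frame(key = names(tab), indegree = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$structure <- network$nodes$structure[match(out$key, network$nodes$key)]
  out[order(-out$indegree, out$key), c("key", "structure", "indegree")]
}

# ---- writers ----------------------------------------------------------------

#' Write the Cytoscape-style node attribute and edge tables
#'
#' The attribute file is keyed on the node key column; the edge file uses
#' `source,target,interaction` columns, both directly loadable through
#' Cytoscape's table import.
#'
#' @param network a `scaffold_network` (annotated or not).
#' @param nodes_path,edges_path output CSV paths.
#' @return invisibly, the two data frames.
#' @export
write_network_csv <- function(network, nodes_path, edges_path) {
  nodes <- network$nodes
  if ("EF" %in% names(nodes)) nodes$EF_label <- ifelse(is.na(nodes$EF), "",
                                                       sprintf("%.1f", nodes$EF))
  utils::write.csv(nodes, nodes_path, row.names = FALSE, quote = TRUE)
  edges <- network$edges
  names(edges) <- c("source", "target", "interaction")
  utils::write.csv(edges, edges_path, row.names = FALSE, quote = TRUE)
  invisible(list(nodes = nodes, edges = edges))
}

#' Export the network as GraphML
#'
#' @param network a `scaffold_network`.
#' @param path output file.
#' @return invisibly, the igraph object.
#' @export
write_network_graphml <- function(network, path) {
  ig <- igraph::graph_from_data_frame(
    network$edges, directed = TRUE,
    vertices = network$nodes[, c("key", "node_class", "representation_kind",
                                 "structure")])
  igraph::write_graph(ig, path, format = "graphml")
  invisible(ig)
}
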