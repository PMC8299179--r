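#' Unbiased fragmentation of scaffold representations
#'
#' Three rules decompose any representation exhaustively and progressively:
#' removal of internal chains (acyclic connectors between ring systems),
#' opening of fused rings (deleting the atoms exclusive to one ring of a
#' fused system), and removal of internal rings (ring systems whose deletion
#' splits the remainder). Children of children are generated breadth-first up
#' to a depth cap, deduplicated by canonical key. Fragments must contain at
#' least one ring; pure-chain leftovers are discarded.
#'
#' @name fragmentation
NULL

# per-atom ring system id (0 = not in a ring)
ring_system_membership <- function(g, rings = NULL, systems = NULL) {
  if (is.null(rings)) rings <- sssr(g)
  if (is.null(systems)) systems <- ring_systems(rings)
  mem <- integer(n_atoms(g))
  for (s in seq_along(systems))
    for (r in systems[[s]]) mem[rings[[r]]$atoms] <- s
  mem
}

# delete atom set D, then drop former-connector stubs: maximal non-ring
# components that touched D and are left hanging from at most one remaining
# ring system ("pruned to the nearest ring")
delete_atoms_prune_stubs <- function(g, D) {
  adjD <- unique(c(g$bonds$j[g$bonds$i %in% D], g$bonds$i[g$bonds$j %in% D]))
  adjD <- setdiff(adjD, D)
  keep <- setdiff(seq_len(n_atoms(g)), D)
  g2 <- mg_induced(g, keep)
  old_of <- keep                       # g2 index -> g index
  touched2 <- which(old_of %in% adjD)
  sysmem <- ring_system_membership(g2)
  nonring <- which(sysmem == 0)
  if (length(nonring) > 0) {
    sub <- mg_induced(g2, nonring)
    cm <- mg_components(sub)
    drop2 <- integer()
    for (cc in unique(cm)) {
      S2 <- nonring[cm == cc]
      if (!any(S2 %in% touched2)) next        # side chain untouched by the cut
      nb <- unique(c(g2$bonds$j[g2$bonds$i %in% S2],
                     g2$bonds$i[g2$bonds$j %in% S2]))
      nsys <- unique(sysmem[setdiff(nb, S2)])
      nsys <- nsys[nsys != 0]
      if (length(nsys) <= 1) drop2 <- c(drop2, S2)
    }
    if (length(drop2) > 0) g2 <- mg_delete_atoms(g2, drop2)
  }
  g2
}

# split a graph into its ring-containing connected components
ring_components <- function(g) {
  if (n_atoms(g) == 0) return(list())
  cm <- mg_components(g)
  out <- list()
  for (cc in unique(cm)) {
    sub <- mg_induced(g, cm == cc)
    if (ring_count(sub) > 0) out[[length(out) + 1L]] <- sub
  }
  out
}

#' Rule 1: remove internal chains
#'
#' An internal chain is a maximal acyclic connector (all non-ring atoms,
#' including any decorations riding on it) adjacent to at least two distinct
#' ring systems, or a direct bond between two ring systems. Each chain is
#' deleted independently and every ring-containing component of the
#' remainder becomes a child.
#'
#' @param g a `mol_graph`.
#' @return list of `mol_graph` children (possibly empty), deduplicated by key.
#' @export
remove_internal_chains <- function(g) {
  if (ring_count(g) == 0) return(list())
  rings <- sssr(g); systems <- ring_systems(rings)
  sysmem <- ring_system_membership(g, rings, systems)
  children <- list()
  # atom chains
  nonring <- which(sysmem == 0)
  if (length(nonring) > 0) {
    sub <- mg_induced(g, nonring)
    cm <- mg_components(sub)
    for (cc in unique(cm)) {
      S <- nonring[cm == cc]
      nb <- unique(c(g$bonds$j[g$bonds$i %in% S], g$bonds$i[g$bonds$j %in% S]))
      nsys <- unique(sysmem[setdiff(nb, S)])
      nsys <- nsys[nsys != 0]
      if (length(nsys) >= 2)
        children <- c(children, ring_components(mg_delete_atoms(g, S)))
    }
  }
  # direct ring-ring bonds between different systems
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    si <- sysmem[b$i[k]]; sj <- sysmem[b$j[k]]
    if (si != 0 && sj != 0 && si != sj) {
      g2 <- g; g2$bonds <- b[-k, , drop = FALSE]
      children <- c(children, ring_components(g2))
    }
  }
  dedup_graphs(children)
}

#' Rule 2: open fused rings
#'
#' For each ring of a fused (or spiro) ring system, the atoms exclusive to
#' that ring are deleted; atoms shared with other rings of the system are
#' retained, dangling connector stubs are pruned, and each ring-containing
#' component of the remainder becomes a child.
#'
#' @param g a `mol_graph`.
#' @return list of `mol_graph` children, deduplicated by key.
#' @export
open_fused_rings <- function(g) {
  if (ring_count(g) == 0) return(list())
  rings <- sssr(g); systems <- ring_systems(rings)
  children <- list()
  for (sys in systems) {
    if (length(sys) < 2) next
    for (r in sys) {
      others <- unlist(lapply(setdiff(sys, r), function(q) rings[[q]]$atoms))
      excl <- setdiff(rings[[r]]$atoms, others)
      if (length(excl) == 0) next
      g2 <- delete_atoms_prune_stubs(g, excl)
      children <- c(children, ring_components(g2))
    }
  }
  dedup_graphs(children)
}

#' Rule 3: remove internal rings
#'
#' A ring system is internal when deleting all of its atoms (with dangling
#' connector stubs pruned to the nearest ring) splits the remainder into two
#' or more ring-containing components; each such component becomes a child.
#'
#' @param g a `mol_graph`.
#' @return list of `mol_graph` children, deduplicated by key.
#' @export
remove_internal_rings <- function(g) {
  if (ring_count(g) == 0) return(list())
  rings <- sssr(g); systems <- ring_systems(rings)
  children <- list()
  for (sys in systems) {
    D <- unique(unlist(lapply(sys, function(r) rings[[r]]$atoms)))
    g2 <- delete_atoms_prune_stubs(g, D)
    comps <- ring_components(g2)
    if (length(comps) >= 2) children <- c(children, comps)
  }
  dedup_graphs(children)
}

dedup_graphs <- function(graphs) {
  if (length(graphs) <= 1) return(graphs)
  keys <- vapply(graphs, structure_key, "")
  graphs[!duplicated(keys)]
}

#' Exhaustive progressive fragmentation
#'
#' Breadth-first closure of the three fragmentation rules, deduplicated by
#' canonical key. Each record keeps the generating rule, the depth at which
#' the fragment first appeared and the key of its immediate originator.
#'
#' @param g a `mol_graph` (any representation).
#' @param max_depth maximum closure depth; default is the ring count of `g`
#'   (full closure, since every rule removes at least one ring).
#' @param max_fragments combinatorial safety cap; exceeding it truncates the
#'   closure with a warning and sets the `truncated` attribute.
#' @return list of `fragment_record` objects (`graph`, `key`, `rule`,
#'   `depth`, `originator_key`), with attribute `truncated`.
#' @export
enumerate_fragments <- function(g, max_depth = NULL, max_fragments = 5000L) {
  if (is.null(max_depth)) max_depth <- max(1L, ring_count(g))
  stopifnot(max_depth >= 1)
  root_key <- structure_key(g)
  seen <- new.env(parent = emptyenv())
  assign(root_key, TRUE, envir = seen)
  records <- list()
  queue <- list(list(graph = g, key = root_key, depth = 0L))
  truncated <- FALSE
  rules <- list(CHAIN_REMOVAL = remove_internal_chains,
                FUSED_RING_OPENING = open_fused_rings,
                INTERNAL_RING_REMOVAL = remove_internal_rings)
  while (length(queue) > 0) {
    cur <- queue[[1]]; queue <- queue[-1]
    if (cur$depth >= max_depth) next
    for (rule in names(rules)) {
      for (child in rules[[rule]](cur$graph)) {
        key <- structure_key(child)
        if (exists(key, envir = seen, inherits = FALSE)) next
        if (length(records) >= max_fragments) { truncated <- TRUE; break }
        assign(key, TRUE, envir = seen)
        rec <- structure(list(graph = child, key = key, rule = rule,
                              depth = cur$depth + 1L,
                              originator_key = cur$key),
                         class = "fragment_record")
        records[[length(records) + 1L]] <- rec
        queue[[length(queue) + 1L]] <- list(graph = child, key = key,
                                            depth = cur$depth + 1L)
      }
      if (truncated) break
    }
    if (truncated) break
  }
  if (truncated)
    warning("fragment closure truncated at ", max_fragments, " fragments")
  attr(records, "truncated") <- truncated
  records
}

#' @export
print.fragment_record <- function(x, ...) {
  cat(sprintf("<fragment depth %d via %s: %s>\n", x$depth, x$rule,
              encode_structure(x$graph)))
  invisible(x)
}

#' Fragment table
#'
#' @param fragments list of `fragment_record` objects.
#' @return data frame with columns `originator_key`, `fragment_key`, `rule`,
#'   `depth`, `structure`.
#' @export
fragments_table <- function(fragments) {
  if (length(fragments) == 0)
    return(data.frame(originator_key = character(), fragment_key = character(),
                      rule = character(), depth = integer(),
                      structure = character(), stringsAsFactors = FALSE))
  data.frame(
    originator_key = vapply(fragments, `[[`, "", "originator_key"),
    fragment_key = vapply(fragments, `[[`, "", "key"),
    rule = vapply(fragments, `[[`, "", "rule"),
    depth = vapply(fragments, `[[`, 0L, "depth"),
    structure = vapply(fragments, function(f) encode_structure(f$graph), ""),
    stringsAsFactors = FALSE)
}
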