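#' The nine correlated molecular representations
#'
#' A molecule is decomposed along two independent axes. The *decoration* axis
#' controls how much side-chain information is kept on the ring/linker core:
#' `basic` (nothing beyond rings and linkers), `decorated` (terminal atoms
#' attached by a bond of order > 1, e.g. carbonyl or sulfone oxygens, are
#' kept), `augmented` (additionally, the single longest side chain ending in
#' a carbon atom is kept). The *abstraction* axis removes chemical labels:
#' `scaffold` (elements and bond orders kept), `framework` (any-atom, bond
#' orders kept), `wireframe` (any-atom and any-bond: the cyclic skeleton).
#' The 3 x 3 grid commutes: each cell is a deterministic function of any less
#' abstract cell.
#'
#' @name nine-representations
NULL

no_ring_error <- function(id = NULL) {
  msg <- if (is.null(id)) "molecule contains no ring" else
    paste0("molecule ", id, " contains no ring")
  stop(errorCondition(msg, class = c("scaffnet_no_ring_error", "error")))
}

#' @export
representation_kinds <- function() {
  grid <- expand.grid(
    decoration = c("augmented", "decorated", "basic"),
    abstraction = c("scaffold", "framework", "wireframe"),
    stringsAsFactors = FALSE)
  grid$kind <- paste(grid$decoration, grid$abstraction, sep = "_")
  # ranks increase with abstraction; used for "least abstract" dedup order:
  # the abstraction axis dominates, decoration breaks ties
  grid$abs_rank <- match(grid$abstraction, c("scaffold", "framework", "wireframe"))
  grid$dec_rank <- match(grid$decoration, c("augmented", "decorated", "basic"))
  grid$abstractness <- (grid$abs_rank - 1) * 3 + grid$dec_rank
  grid[order(grid$abstractness), c("kind", "decoration", "abstraction",
                                   "abs_rank", "dec_rank", "abstractness")]
}

# iteratively remove degree-1 atoms selected by `prunable(g, idx)`;
# confluent, so the fixpoint is unique
prune_terminals <- function(g, prunable) {
  repeat {
    deg <- mg_degree(g)
    term <- which(deg == 1)
    if (length(term) == 0) return(g)
    drop <- term[prunable(g, term)]
    if (length(drop) == 0) return(g)
    g <- mg_delete_atoms(g, drop)
  }
}

terminal_bond_order <- function(g, idx) {
  vapply(idx, function(v) {
    k <- which(g$bonds$i == v | g$bonds$j == v)[1]
    g$bonds$order[k]
  }, "")
}

#' Basic scaffold (Bemis-Murcko)
#'
#' Iteratively deletes all terminal (degree-1) atoms, leaving every ring and
#' the acyclic linkers connecting rings.
#'
#' @param g a `mol_graph` with at least one ring.
#' @return a `mol_graph`.
#' @export
basic_scaffold <- function(g) {
  if (ring_count(g) == 0) no_ring_error()
  prune_terminals(g, function(g, idx) rep(TRUE, length(idx)))
}

#' Decorated scaffold
#'
#' Like [basic_scaffold()], but terminal atoms attached by a bond of order
#' greater than one (e.g. exocyclic `C=O`) are never pruned; only order-1
#' terminals are removed, iterated to the fixpoint.
#'
#' @param g a `mol_graph` with at least one ring.
#' @return a `mol_graph`.
#' @export
decorated_scaffold <- function(g) {
  if (ring_count(g) == 0) no_ring_error()
  prune_terminals(g, function(g, idx) terminal_bond_order(g, idx) == "1")
}

#' Augmented scaffold
#'
#' Two-step rule. Step 1 iteratively removes terminal non-carbon atoms bonded
#' by order 1. Step 2 identifies, among the remaining side chains, the
#' longest path that ends in a carbon atom and retains it; every other
#' side-chain atom is pruned down to the decorated-scaffold baseline. When
#' step 1 leaves no order-1 terminal atoms, the decorated and augmented
#' scaffolds coincide. Equal-length candidate paths are broken by the
#' lexicographically smallest canonical atom-rank sequence, which makes the
#' "first identified" path independent of input atom order.
#'
#' @param g a `mol_graph` with at least one ring.
#' @return a `mol_graph`.
#' @export
augmented_scaffold <- function(g) {
  if (ring_count(g) == 0) no_ring_error()
  # step 1: drop terminal non-carbon atoms attached by order-1 bonds
  g1 <- prune_terminals(g, function(g, idx)
    g$atoms[idx] != "C" & terminal_bond_order(g, idx) == "1")
  deg <- mg_degree(g1)
  term1 <- which(deg == 1)
  open_term <- term1[terminal_bond_order(g1, term1) == "1"]
  if (length(open_term) == 0) return(g1)  # coincides with decorated scaffold
  # core = ring/linker atoms (basic scaffold of g1)
  core_mask <- rep(TRUE, n_atoms(g1))
  gg <- g1
  idx_map <- seq_len(n_atoms(g1))
  repeat {
    d <- mg_degree(gg)
    t <- which(d == 1)
    if (length(t) == 0) break
    core_mask[idx_map[t]] <- FALSE
    keep <- setdiff(seq_len(n_atoms(gg)), t)
    idx_map <- idx_map[keep]
    gg <- mg_induced(gg, keep)
  }
  core <- which(core_mask)
  side <- which(!core_mask)
  # candidate chains: simple paths from a core atom through side atoms to a
  # terminal carbon; the side subgraph is a forest, so paths are unique per
  # (attachment, leaf) pair
  adj <- mg_adjlist(g1)
  ranks <- canonical_ranks(g1)
  ends <- open_term[g1$atoms[open_term] == "C" & !core_mask[open_term]]
  best <- NULL  # list(atoms, len, rankseq)
  for (leaf in ends) {
    # walk from leaf toward the core
    path <- leaf; prev <- -1L; cur <- leaf
    repeat {
      nbrs <- setdiff(adj[[cur]]$nbr, prev)
      # move toward the core through side atoms
      nxt <- nbrs[core_mask[nbrs]]
      if (length(nxt) > 0) { path <- c(path, nxt[1]); break }
      nxt <- nbrs[!core_mask[nbrs]]
      if (length(nxt) == 0) break  # isolated side tree (no core) - skip
      # in a tree walk toward the root: the unique neighbour on the path to
      # the core is found by following each branch; use BFS distance to core
      nxt <- nxt[which.min(vapply(nxt, function(u)
        side_dist_to_core(adj, core_mask, u, cur), 0L))]
      prev <- cur; cur <- nxt; path <- c(path, cur)
    }
    if (!core_mask[path[length(path)]]) next
    chain <- path[-length(path)]           # side atoms only, leaf..attachment
    rankseq <- ranks[rev(chain)]           # attachment outward
    cand <- list(atoms = chain, len = length(chain), rankseq = rankseq)
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len &&
         paste(sprintf("%06d", cand$rankseq), collapse = ",") <
         paste(sprintf("%06d", best$rankseq), collapse = ","))) best <- cand
  }
  dec_fix <- decorated_keep_mask(g1)
  keep <- union(which(dec_fix), if (is.null(best)) integer() else best$atoms)
  mg_induced(g1, sort(keep))
}

# BFS distance from side atom u (coming from 'from') to the nearest core atom
side_dist_to_core <- function(adj, core_mask, u, from) {
  seen <- c(from, u); frontier <- u; d <- 0L
  repeat {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, function(v) adj[[v]]$nbr)))
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0) return(10000L)
    if (any(core_mask[nxt])) return(d)
    seen <- c(seen, nxt); frontier <- nxt
  }
}

# mask of atoms surviving decorated-scaffold pruning, in the indexing of g
decorated_keep_mask <- function(g) {
  mask <- rep(TRUE, n_atoms(g))
  idx_map <- seq_len(n_atoms(g))
  gg <- g
  repeat {
    d <- mg_degree(gg)
    t <- which(d == 1)
    t <- t[terminal_bond_order(gg, t) == "1"]
    if (length(t) == 0) return(mask)
    mask[idx_map[t]] <- FALSE
    keep <- setdiff(seq_len(n_atoms(gg)), t)
    idx_map <- idx_map[keep]
    gg <- mg_induced(gg, keep)
  }
}

#' Framework abstraction: drop atom types
#'
#' Every atom label becomes the any-atom wildcard; bond orders and topology
#' are unchanged (aromatic bonds stay aromatic).
#'
#' @param g a `mol_graph`.
#' @return a `mol_graph`.
#' @export
to_framework <- function(g) {
  mol_graph(rep("*", n_atoms(g)), g$bonds)
}

#' Wireframe abstraction: drop atom types and bond orders
#'
#' The cyclic skeleton: any-atom labels and any-order bonds, topology only.
#'
#' @param g a `mol_graph`.
#' @return a `mol_graph`.
#' @export
to_wireframe <- function(g) {
  b <- g$bonds
  if (nrow(b) > 0) b$order <- "any"
  mol_graph(rep("*", n_atoms(g)), b)
}

#' Generate the nine representations of a compound
#'
#' @param compound a `compound` (see [standardize_smiles()]) or a concrete
#'   `mol_graph`.
#' @return a `representation_set`: list with `compound_id`, `ring_count` and
#'   `reps`, a named list (one entry per representation kind) of
#'   `list(graph, key)`.
#' @export
nine_representations <- function(compound) {
  if (inherits(compound, "mol_graph")) {
    g <- compound; id <- NA_character_
  } else {
    g <- compound$graph; id <- compound$compound_id
  }
  if (ring_count(g) == 0) no_ring_error(id)
  scaff <- list(basic = basic_scaffold(g),
                decorated = decorated_scaffold(g),
                augmented = augmented_scaffold(g))
  reps <- list()
  for (dec in c("augmented", "decorated", "basic")) {
    s <- scaff[[dec]]
    reps[[paste0(dec, "_scaffold")]] <- s
    reps[[paste0(dec, "_framework")]] <- to_framework(s)
    reps[[paste0(dec, "_wireframe")]] <- to_wireframe(s)
  }
  kinds <- representation_kinds()$kind
  reps <- reps[kinds]
  out <- lapply(reps, function(gr) list(graph = gr, key = structure_key(gr)))
  structure(list(compound_id = id, ring_count = ring_count(scaff$basic),
                 reps = out),
            class = "representation_set")
}

#' @export
print.representation_set <- function(x, ...) {
  cat(sprintf("<representation_set %s: %d rings>\n", x$compound_id,
              x$ring_count))
  for (k in names(x$reps))
    cat(sprintf("  %-20s %s\n", k, encode_structure(x$reps[[k]]$graph)))
  invisible(x)
}

#' Long table of representations
#'
#' One row per compound and representation kind, with the linear structure
#' encoding and the canonical key. Concrete (scaffold-level) rows also carry
#' a canonical SMILES.
#'
#' @param repsets list of `representation_set` objects.
#' @return data frame with columns `compound_id`, `representation_kind`,
#'   `structure`, `smiles`, `key`.
#' @export
representations_long <- function(repsets) {
  rows <- list()
  for (rs in repsets) {
    for (k in names(rs$reps)) {
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = rs$compound_id, representation_kind = k,
        structure = encode_structure(rs$reps[[k]]$graph),
        key = rs$reps[[k]]$key, stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, rows)
  conc <- grepl("_scaffold$", long$representation_kind)
  long$smiles <- NA_character_
  if (any(conc)) {
    graphs <- list()
    for (rs in repsets) for (k in names(rs$reps))
      if (grepl("_scaffold$", k)) graphs[[length(graphs) + 1L]] <- rs$reps[[k]]$graph
    long$smiles[conc] <- mg_to_can_smiles(graphs)
  }
  long[, c("compound_id", "representation_kind", "structure", "smiles", "key")]
}
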