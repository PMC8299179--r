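#' Canonical keys for (possibly wildcard) molecular graphs
#'
#' Standard chemical identifiers (canonical SMILES, InChIKey) cannot represent
#' any-atom/any-bond structures, but frameworks and wireframes still need a
#' deduplication key. The key used here is a canonical graph code computed by
#' colour refinement with backtracking individualisation: two graphs receive
#' the same key exactly when they are isomorphic under (atom label, bond
#' order) equality. Concrete molecules go through the same code path, so keys
#' are comparable across all nine representations and all fragments.
#'
#' @name canonical-keys
NULL

.order_char <- c("1" = "1", "2" = "2", "3" = "3", "ar" = "a", "any" = "x")
.order_int <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L, "any" = 5L)

# precomputed edge structure for refinement: both directions of every bond
refine_env <- function(g) {
  n <- n_atoms(g)
  vv <- c(g$bonds$i, g$bonds$j)
  uu <- c(g$bonds$j, g$bonds$i)
  oo <- rep(.order_int[g$bonds$order], 2)
  deg <- tabulate(vv, nbins = n)
  ordv <- order(vv)
  list(n = n, v = vv[ordv], u = uu[ordv], o = oo[ordv], deg = deg,
       maxd = if (length(deg) > 0 && max(deg) > 0) max(deg) else 0L)
}


canon_code_of <- function(g, colors) {
  # colors is a discrete colouring: rank 1..n, one atom each
  lab <- g$atoms[order(colors)]
  b <- g$bonds
  if (nrow(b) > 0) {
    a1 <- pmin(colors[b$i], colors[b$j])
    a2 <- pmax(colors[b$i], colors[b$j])
    o <- .order_char[b$order]
    ord <- order(a1, a2)
    edges <- paste0(a1[ord], ".", a2[ord], ".", o[ord], collapse = ";")
  } else edges <- ""
  paste0(length(lab), "|", paste(lab, collapse = "."), "|", edges)
}

# vectorized stable colour refinement (1-WL with edge orders)
refine_colors <- function(re, colors) {
  n <- re$n
  if (re$maxd == 0L) return(colors)
  repeat {
    k_old <- length(unique(colors))
    code <- colors[re$u] * 6 + re$o       # neighbour colour + bond order
    ord2 <- order(re$v, -code)
    sig <- matrix(0, n, re$maxd + 1L)
    sig[, 1] <- colors
    pres <- unique(re$v)
    pos <- sequence(re$deg[pres])
    sig[cbind(re$v[ord2], pos + 1L)] <- code[ord2]
    od <- do.call(order, lapply(seq_len(ncol(sig)), function(cc) sig[, cc]))
    m2 <- sig[od, , drop = FALSE]
    changed <- c(TRUE, rowSums(abs(m2[-1, , drop = FALSE] -
                                     m2[-n, , drop = FALSE])) > 0)
    colors[od] <- cumsum(changed)
    if (length(unique(colors)) == k_old) return(colors)
  }
}

.canon_cache <- new.env(parent = emptyenv())

graph_content_id <- function(g) {
  paste0(paste(g$atoms, collapse = ","), "/",
         paste(g$bonds$i, g$bonds$j, g$bonds$order, collapse = ";"))
}

canon_search <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return(list(code = "0||", ranks = integer()))
  cid <- graph_content_id(g)
  hit <- get0(cid, envir = .canon_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  re <- refine_env(g)
  init <- match(g$atoms, sort(unique(g$atoms)))
  best <- NULL
  best_ranks <- NULL
  recurse <- function(colors) {
    colors <- refine_colors(re, colors)
    if (length(unique(colors)) == n) {
      code <- canon_code_of(g, colors)
      if (is.null(best) || code < best) {
        best <<- code
        best_ranks <<- colors
      }
      return(invisible(NULL))
    }
    tab <- tabulate(colors)
    cell <- which(tab > 1)[1]
    for (v in which(colors == cell)) {
      c2 <- colors * 2L
      c2[v] <- c2[v] - 1L
      recurse(match(c2, sort(unique(c2))))
    }
    invisible(NULL)
  }
  recurse(init)
  res <- list(code = best, ranks = best_ranks)
  if (length(ls(.canon_cache)) > 30000) .canon_cache_clear()
  assign(cid, res, envir = .canon_cache)
  res
}

.canon_cache_clear <- function() {
  rm(list = ls(.canon_cache, all.names = TRUE), envir = .canon_cache)
}

#' Canonical structure key of a molecular graph
#'
#' @param g a `mol_graph`.
#' @return a string; equal for two graphs iff they are isomorphic with equal
#'   atom labels and bond orders.
#' @export
structure_key <- function(g) canon_search(g)$code

#' Canonical atom ranks
#'
#' A deterministic total ordering of the atoms of `g`, invariant (up to graph
#' automorphism) under relabelling of the input atom order. Used for
#' reproducible "first identified" tie-breaks.
#'
#' @param g a `mol_graph`.
#' @return integer vector of ranks 1..n.
#' @export
canonical_ranks <- function(g) canon_search(g)$ranks

#' Test two molecular graphs for isomorphism
#' @param g1,g2 `mol_graph` objects.
#' @return logical.
#' @export
graphs_isomorphic <- function(g1, g2) {
  if (n_atoms(g1) != n_atoms(g2) || n_bonds(g1) != n_bonds(g2)) return(FALSE)
  structure_key(g1) == structure_key(g2)
}

.bond_sym <- c("1" = "", "2" = "=", "3" = "#", "ar" = ":", "any" = "~")

#' Human-readable linear encoding of a molecular graph
#'
#' A SMILES-like depth-first string over the canonical atom order. Wildcard
#' atoms are written `*`; bond symbols are `=`, `#`, `:` (aromatic) and `~`
#' (any order); single bonds are implicit. The encoding is deterministic and
#' write-only: it is meant for table columns and network node labels, the
#' canonical key being the authoritative identifier.
#'
#' @param g a `mol_graph`.
#' @return a string.
#' @export
encode_structure <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return("")
  ranks <- canonical_ranks(g)
  perm <- order(ranks)              # perm[r] = original atom with rank r
  adj <- mg_adjlist(g)
  visited <- rep(FALSE, n)
  ring_num <- 0L
  open_ring <- new.env()
  # pre-pass: DFS to find ring-closure bonds, then emit
  emitted <- character(0)
  atom_tok <- function(v) {
    a <- g$atoms[v]
    if (a == "*") "*" else if (nchar(a) > 1 || !a %in% c("B","C","N","O","P","S","F","I")) paste0("[", a, "]") else a
  }
  closures <- vector("list", n)     # per atom: list of (label, ordersym)
  tree_child <- vector("list", n)
  seen_edge <- matrix(FALSE, n, n)
  dfs_order <- integer(0)
  parent <- rep(NA_integer_, n)
  build <- function(v) {
    visited[v] <<- TRUE
    dfs_order <<- c(dfs_order, v)
    nb <- adj[[v]]
    ordn <- order(ranks[nb$nbr])
    for (k in ordn) {
      u <- nb$nbr[k]; o <- nb$order[k]
      if (seen_edge[v, u]) next
      seen_edge[v, u] <<- TRUE; seen_edge[u, v] <<- TRUE
      if (!visited[u]) {
        parent[u] <<- v
        tree_child[[v]] <<- c(tree_child[[v]], list(list(u = u, o = o)))
        build(u)
      } else {
        ring_num <<- ring_num + 1L
        lbl <- if (ring_num > 9) paste0("%", ring_num) else as.character(ring_num)
        closures[[v]] <<- c(closures[[v]], list(list(lbl = lbl, o = .bond_sym[o])))
        closures[[u]] <<- c(closures[[u]], list(list(lbl = lbl, o = "")))
      }
    }
  }
  emit <- function(v) {
    s <- atom_tok(v)
    for (cl in closures[[v]]) s <- paste0(s, cl$o, cl$lbl)
    kids <- tree_child[[v]]
    if (length(kids) > 0) {
      for (k in seq_along(kids)[-length(kids)]) {
        kid <- kids[[k]]
        s <- paste0(s, "(", .bond_sym[kid$o], emit(kid$u), ")")
      }
      last <- kids[[length(kids)]]
      s <- paste0(s, .bond_sym[last$o], emit(last$u))
    }
    s
  }
  parts <- character(0)
  for (r in seq_len(n)) {
    v <- perm[r]
    if (!visited[v]) {
      build(v)
      parts <- c(parts, emit(v))
    }
  }
  paste(parts, collapse = ".")
}
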