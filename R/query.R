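#' Generic ("any atom / any bond") substructure matching
#'
#' Subgraph matching where wildcard query atoms match any element and
#' wildcard query bonds match any order, while concrete query labels must
#' match exactly. Query bonds that are part of a ring must map onto target
#' ring bonds, so a cyclic skeleton query cannot match an open chain. All
#' matching is on heavy-atom graphs.
#'
#' @name generic-matching
NULL

atom_compatible <- function(q, t) q == "*" | q == t

bond_compatible <- function(qo, to) qo == "any" | qo == to

#' Match a (possibly wildcard) query graph against a target graph
#'
#' @param query,target `mol_graph` objects; wildcards are allowed in the
#'   query only.
#' @return `TRUE`/`FALSE`; when `TRUE`, the attribute `embedding` holds one
#'   witness mapping (integer vector: query atom -> target atom).
#' @export
generic_match <- function(query, target) {
  nq <- n_atoms(query); nt <- n_atoms(target)
  if (nq == 0) return(structure(TRUE, embedding = integer()))
  if (nq > nt) return(FALSE)
  # target adjacency as order-labelled matrix; ring-bond lookup
  tadj <- matrix("", nt, nt)
  for (k in seq_len(n_bonds(target))) {
    i <- target$bonds$i[k]; j <- target$bonds$j[k]
    tadj[i, j] <- target$bonds$order[k]; tadj[j, i] <- target$bonds$order[k]
  }
  tring <- matrix(FALSE, nt, nt)
  for (k in ring_bond_idx(target)) {
    i <- target$bonds$i[k]; j <- target$bonds$j[k]
    tring[i, j] <- TRUE; tring[j, i] <- TRUE
  }
  qring <- matrix(FALSE, nq, nq)
  for (k in ring_bond_idx(query)) {
    i <- query$bonds$i[k]; j <- query$bonds$j[k]
    qring[i, j] <- TRUE; qring[j, i] <- TRUE
  }
  qadj <- matrix("", nq, nq)
  for (k in seq_len(n_bonds(query))) {
    i <- query$bonds$i[k]; j <- query$bonds$j[k]
    qadj[i, j] <- query$bonds$order[k]; qadj[j, i] <- query$bonds$order[k]
  }
  qdeg <- mg_degree(query); tdeg <- mg_degree(target)
  # visit order: each component's atoms in a connectivity-respecting order,
  # starting from the rarest-labelled highest-degree atom
  comp <- mg_components(query)
  order_q <- integer(0)
  for (cc in unique(comp)) {
    atoms <- which(comp == cc)
    seed <- atoms[order(-qdeg[atoms])][1]
    vis <- seed
    while (length(vis) < length(atoms)) {
      frontier <- setdiff(atoms[vapply(atoms, function(a)
        any(qadj[a, vis] != ""), TRUE)], vis)
      frontier <- frontier[order(-qdeg[frontier])]
      vis <- c(vis, frontier[1])
    }
    order_q <- c(order_q, vis)
  }
  map <- integer(nq); used <- rep(FALSE, nt)
  found <- FALSE
  assign_next <- function(pos) {
    if (found) return(invisible(NULL))
    if (pos > nq) { found <<- TRUE; return(invisible(NULL)) }
    qa <- order_q[pos]
    earlier <- order_q[seq_len(pos - 1)]
    anchors <- earlier[qadj[qa, earlier] != ""]
    cands <- if (length(anchors) == 0) which(!used) else {
      ta <- map[anchors[1]]
      which(tadj[, ta] != "" & !used)
    }
    for (tc in cands) {
      if (!atom_compatible(query$atoms[qa], target$atoms[tc])) next
      if (tdeg[tc] < qdeg[qa]) next
      ok <- TRUE
      for (e in earlier) {
        qo <- qadj[qa, e]
        if (qo == "") next
        to <- tadj[tc, map[e]]
        if (to == "" || !bond_compatible(qo, to)) { ok <- FALSE; break }
        if (qring[qa, e] && !tring[tc, map[e]]) { ok <- FALSE; break }
      }
      if (!ok) next
      map[qa] <<- tc; used[tc] <<- TRUE
      assign_next(pos + 1)
      if (found) return(invisible(NULL))
      used[tc] <<- FALSE; map[qa] <<- 0L
    }
    invisible(NULL)
  }
  assign_next(1L)
  if (found) structure(TRUE, embedding = map) else FALSE
}

#' Match a query against a compound set
#'
#' @param query a `mol_graph` (typically an abstracted representation used as
#'   a wildcard query).
#' @param compounds list of `compound` objects (or `mol_graph`s).
#' @return character vector of matching compound ids (or indices when plain
#'   graphs are given), in stable input order.
#' @export
match_set <- function(query, compounds) {
  if (length(compounds) == 0) return(character())
  hits <- character()
  for (k in seq_along(compounds)) {
    x <- compounds[[k]]
    g <- if (inherits(x, "mol_graph")) x else x$graph
    id <- if (inherits(x, "mol_graph")) as.character(k) else x$compound_id
    if (isTRUE(generic_match(query, g))) hits <- c(hits, id)
  }
  hits
}

.smarts_bond <- c("1" = "-", "2" = "=", "3" = "#", "ar" = ":", "any" = "~")

#' Export a query graph as a SMARTS pattern
#'
#' Wildcard atoms become `*`, bond orders use explicit SMARTS bond
#' primitives (`-`, `=`, `#`, `:`, `~`). Ring-membership constraints of the
#' matcher are not encoded in the pattern.
#'
#' @param g a `mol_graph`.
#' @return a SMARTS string.
#' @export
query_to_smarts <- function(g) {
  n <- n_atoms(g)
  if (n == 0) return("")
  ranks <- canonical_ranks(g)
  perm <- order(ranks)
  adj <- mg_adjlist(g)
  visited <- rep(FALSE, n)
  seen_edge <- matrix(FALSE, n, n)
  closures <- vector("list", n)
  tree_child <- vector("list", n)
  ring_num <- 0L
  atom_tok <- function(v) if (g$atoms[v] == "*") "*" else paste0("[", g$atoms[v], ",", tolower(g$atoms[v]), "]")
  build <- function(v) {
    visited[v] <<- TRUE
    nb <- adj[[v]]
    for (k in order(ranks[nb$nbr])) {
      u <- nb$nbr[k]; o <- nb$order[k]
      if (seen_edge[v, u]) next
      seen_edge[v, u] <<- TRUE; seen_edge[u, v] <<- TRUE
      if (!visited[u]) {
        tree_child[[v]] <<- c(tree_child[[v]], list(list(u = u, o = o)))
        build(u)
      } else {
        ring_num <<- ring_num + 1L
        lbl <- if (ring_num > 9) paste0("%", ring_num) else as.character(ring_num)
        closures[[v]] <<- c(closures[[v]], list(list(lbl = lbl, o = .smarts_bond[o])))
        closures[[u]] <<- c(closures[[u]], list(list(lbl = lbl, o = "")))
      }
    }
  }
  emit <- function(v) {
    s <- atom_tok(v)
    for (cl in closures[[v]]) s <- paste0(s, cl$o, cl$lbl)
    kids <- tree_child[[v]]
    if (length(kids) > 0) {
      for (k in seq_along(kids)[-length(kids)])
        s <- paste0(s, "(", .smarts_bond[kids[[k]]$o], emit(kids[[k]]$u), ")")
      last <- kids[[length(kids)]]
      s <- paste0(s, .smarts_bond[last$o], emit(last$u))
    }
    s
  }
  parts <- character(0)
  for (r in seq_len(n)) {
    v <- perm[r]
    if (!visited[v]) { build(v); parts <- c(parts, emit(v)) }
  }
  paste(parts, collapse = ".")
}
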