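#' Molecular graphs with wildcard atoms and bonds
#'
#' `mol_graph` is the structure carrier used throughout the package for
#' molecules, scaffolds, frameworks, wireframes and fragments. Atoms are
#' labelled with an element symbol or the wildcard `"*"` ("any atom"); bonds
#' carry an order from `"1"`, `"2"`, `"3"`, `"ar"` (aromatic) or `"any"`.
#' Hydrogens are never represented: all graphs are heavy-atom graphs.
#'
#' @param atoms character vector of element symbols, or `"*"` for any-atom.
#' @param bonds data frame with integer columns `i`, `j` and character column
#'   `order`; one row per bond. Self-loops and parallel bonds are rejected.
#' @param charges optional integer vector of formal charges (default all 0).
#' @return an object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds = NULL, charges = NULL) {
  atoms <- as.character(atoms)
  n <- length(atoms)
  if (is.null(bonds) || NROW(bonds) == 0) {
    bonds <- data.frame(i = integer(), j = integer(), order = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                        order = as.character(bonds$order),
                        stringsAsFactors = FALSE)
  }
  if (is.null(charges)) charges <- integer(n)
  if (nrow(bonds) > 0) {
    if (any(bonds$i < 1 | bonds$i > n | bonds$j < 1 | bonds$j > n))
      stop("bond endpoint out of range")
    if (any(bonds$i == bonds$j)) stop("self-loop bonds are not allowed")
    # normalize i < j and forbid parallel bonds
    swap <- bonds$i > bonds$j
    tmp <- bonds$i[swap]; bonds$i[swap] <- bonds$j[swap]; bonds$j[swap] <- tmp
    if (anyDuplicated(bonds[, c("i", "j")]))
      stop("parallel bonds are not allowed")
    bad <- !bonds$order %in% c("1", "2", "3", "ar", "any")
    if (any(bad)) stop("unknown bond order: ", bonds$order[bad][1])
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  structure(list(atoms = atoms, bonds = bonds, charges = as.integer(charges)),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph: %d atoms, %d bonds, %d ring(s)>\n",
              n_atoms(x), n_bonds(x), ring_count(x)))
  invisible(x)
}

#' Number of atoms / bonds of a molecular graph
#' @param g a `mol_graph`.
#' @return integer count.
#' @export
n_atoms <- function(g) length(g$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$bonds)

#' @export
format.mol_graph <- function(x, ...) encode_structure(x)

is_wildcard_graph <- function(g) {
  any(g$atoms == "*") || any(g$bonds$order == "any")
}

mg_degree <- function(g) {
  d <- integer(n_atoms(g))
  if (n_bonds(g) > 0) {
    t1 <- tabulate(g$bonds$i, nbins = n_atoms(g))
    t2 <- tabulate(g$bonds$j, nbins = n_atoms(g))
    d <- t1 + t2
  }
  d
}

# adjacency list: for each atom, data frame of (nbr, order, bond row index)
mg_adjlist <- function(g) {
  n <- n_atoms(g)
  adj <- vector("list", n)
  for (k in seq_len(n)) adj[[k]] <- list(nbr = integer(), order = character())
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    i <- b$i[k]; j <- b$j[k]; o <- b$order[k]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$order <- c(adj[[i]]$order, o)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$order <- c(adj[[j]]$order, o)
  }
  adj
}

#' Induced subgraph on a set of atoms
#' @param g a `mol_graph`.
#' @param keep integer or logical index of atoms to keep.
#' @return a `mol_graph` on the kept atoms (reindexed).
#' @export
mg_induced <- function(g, keep) {
  if (is.logical(keep)) keep <- which(keep)
  keep <- sort(unique(as.integer(keep)))
  map <- integer(n_atoms(g)); map[keep] <- seq_along(keep)
  b <- g$bonds
  sel <- b$i %in% keep & b$j %in% keep
  b <- b[sel, , drop = FALSE]
  if (nrow(b) > 0) { b$i <- map[b$i]; b$j <- map[b$j] }
  mol_graph(g$atoms[keep], b, g$charges[keep])
}

#' Delete atoms from a molecular graph
#' @param g a `mol_graph`.
#' @param drop integer index of atoms to delete.
#' @return a `mol_graph` without the dropped atoms and their incident bonds.
#' @export
mg_delete_atoms <- function(g, drop) {
  mg_induced(g, setdiff(seq_len(n_atoms(g)), drop))
}

#' Convert to an igraph object (connectivity only)
#' @param g a `mol_graph`.
#' @return an undirected `igraph` graph with `n_atoms(g)` vertices.
#' @export
as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (n_bonds(g) > 0) g$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

# component membership vector (integer labels 1..k)
mg_components <- function(g) {
  if (n_atoms(g) == 0) return(integer())
  comp <- igraph::components(as_igraph(g))
  as.integer(comp$membership)
}

#' Cyclomatic ring count
#'
#' Number of smallest rings of a graph: bonds - atoms + connected components.
#' Agrees with the size of the smallest set of smallest rings.
#'
#' @param g a `mol_graph`.
#' @return integer ring count (0 for acyclic graphs).
#' @export
ring_count <- function(g) {
  if (n_atoms(g) == 0) return(0L)
  ncomp <- max(mg_components(g))
  n_bonds(g) - n_atoms(g) + ncomp
}

# bond row indices that lie on some cycle (non-bridge edges)
ring_bond_idx <- function(g) {
  if (n_bonds(g) == 0) return(integer())
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  setdiff(seq_len(n_bonds(g)), as.integer(br))
}

# atoms that lie on some cycle
ring_atom_idx <- function(g) {
  rb <- ring_bond_idx(g)
  sort(unique(c(g$bonds$i[rb], g$bonds$j[rb])))
}

#' Smallest set of smallest rings
#'
#' Computes a minimum cycle basis by Horton's algorithm (candidate cycles from
#' shortest-path trees, greedy GF(2) independence selection). Molecular graphs
#' are small and sparse, so the quadratic candidate enumeration is immaterial.
#'
#' @param g a `mol_graph`.
#' @return a list of rings; each ring is a list with `atoms` (integer vector,
#'   in ring order) and `bonds` (integer vector of bond row indices).
#' @export
sssr <- function(g) {
  mu <- ring_count(g)
  if (mu == 0) return(list())
  n <- n_atoms(g); m <- n_bonds(g)
  ig <- as_igraph(g)
  # restrict attention to ring atoms to cut candidates
  ra <- ring_atom_idx(g)
  bond_id <- matrix(0L, n, n)
  for (k in seq_len(m)) {
    bond_id[g$bonds$i[k], g$bonds$j[k]] <- k
    bond_id[g$bonds$j[k], g$bonds$i[k]] <- k
  }
  cand <- list()
  for (v in ra) {
    sp <- suppressWarnings(
      igraph::shortest_paths(ig, from = v, to = ra, output = "vpath"))$vpath
    paths <- lapply(sp, function(p) as.integer(igraph::as_ids(p)))
    names(paths) <- as.character(ra)
    for (k in ring_bond_idx(g)) {
      x <- g$bonds$i[k]; y <- g$bonds$j[k]
      if (!(x %in% ra) || !(y %in% ra)) next
      px <- paths[[as.character(x)]]; py <- paths[[as.character(y)]]
      if (is.null(px) || is.null(py) || length(px) == 0 || length(py) == 0) next
      if (length(intersect(px, py)) != 1L) next  # must meet only at v
      verts <- c(px, rev(py))  # v..x, y..v
      ex <- bond_id[cbind(px[-length(px)], px[-1])]
      ey <- bond_id[cbind(py[-1], py[-length(py)])]
      edges <- c(ex, k, ey)
      if (k %in% c(ex, ey) || anyDuplicated(edges)) next  # degenerate
      ev <- rep(FALSE, m); ev[edges] <- TRUE
      cand[[length(cand) + 1L]] <- list(atoms = verts[-length(verts)],
                                        bonds = edges, len = length(edges),
                                        evec = ev)
    }
  }
  if (length(cand) == 0) stop("internal error: no candidate rings found")
  cand <- cand[order(vapply(cand, `[[`, 0L, "len"))]
  # greedy selection of mu independent cycles over GF(2)
  basis <- matrix(FALSE, nrow = 0, ncol = m)
  pivots <- integer()
  rings <- list()
  for (cc in cand) {
    v <- cc$evec
    for (r in seq_len(nrow(basis))) {
      if (v[pivots[r]]) v <- xor(v, basis[r, ])
    }
    if (any(v)) {
      basis <- rbind(basis, v)
      pivots <- c(pivots, which(v)[1])
      rings[[length(rings) + 1L]] <- cc[c("atoms", "bonds")]
      if (length(rings) == mu) break
    }
  }
  if (length(rings) != mu) stop("internal error: incomplete cycle basis")
  rings
}

# group SSSR rings into ring systems: rings sharing >=1 atom (covers both
# bond-fused and spiro systems); returns list of integer vectors of ring ids
ring_systems <- function(rings) {
  nr <- length(rings)
  if (nr == 0) return(list())
  parent <- seq_len(nr)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(nr)) for (b in seq_len(nr)) {
    if (a < b && length(intersect(rings[[a]]$atoms, rings[[b]]$atoms)) > 0) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nr), find, 0L)
  unname(split(seq_len(nr), roots))
}
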