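# Independent brute-force oracles used to validate the package's graph
# machinery on small instances. These deliberately avoid the canonical-code
# and matcher code paths they are used to check.

all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

# order-labelled adjacency matrix ("" = no bond)
adj_mat <- function(g) {
  n <- n_atoms(g)
  m <- matrix("", n, n)
  for (k in seq_len(n_bonds(g))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    m[i, j] <- g$bonds$order[k]; m[j, i] <- g$bonds$order[k]
  }
  m
}

# exhaustive isomorphism test under (label, order) equality
brute_iso <- function(g1, g2) {
  n <- n_atoms(g1)
  if (n != n_atoms(g2) || n_bonds(g1) != n_bonds(g2)) return(FALSE)
  if (n == 0) return(TRUE)
  a1 <- adj_mat(g1); a2 <- adj_mat(g2)
  for (p in all_perms(n)) {
    if (!all(g2$atoms[p] == g1$atoms)) next
    if (all(a2[p, p] == a1)) return(TRUE)
  }
  FALSE
}

# an edge lies on a cycle iff removing it leaves its endpoints connected
brute_ring_bonds <- function(g) {
  out <- logical(n_bonds(g))
  for (k in seq_len(n_bonds(g))) {
    b <- g$bonds[-k, , drop = FALSE]
    src <- g$bonds$i[k]; dst <- g$bonds$j[k]
    reach <- src
    repeat {
      nxt <- unique(c(b$j[b$i %in% reach], b$i[b$j %in% reach]))
      nxt <- setdiff(nxt, reach)
      if (length(nxt) == 0) break
      reach <- c(reach, nxt)
    }
    out[k] <- dst %in% reach
  }
  out
}

# exhaustive wildcard subgraph-monomorphism oracle (target <= ~9 atoms),
# with the same ring-bond restriction as the matcher under test
brute_generic_match <- function(q, t) {
  nq <- n_atoms(q); nt <- n_atoms(t)
  if (nq == 0) return(TRUE)
  if (nq > nt) return(FALSE)
  aq <- adj_mat(q); at <- adj_mat(t)
  qr <- matrix(FALSE, nq, nq); tr <- matrix(FALSE, nt, nt)
  qrb <- brute_ring_bonds(q)
  for (k in which(qrb)) {
    qr[q$bonds$i[k], q$bonds$j[k]] <- TRUE; qr[q$bonds$j[k], q$bonds$i[k]] <- TRUE
  }
  trb <- brute_ring_bonds(t)
  for (k in which(trb)) {
    tr[t$bonds$i[k], t$bonds$j[k]] <- TRUE; tr[t$bonds$j[k], t$bonds$i[k]] <- TRUE
  }
  maps <- utils::combn(nt, nq, simplify = FALSE)
  for (sel in maps) {
    for (p in all_perms(nq)) {
      m <- sel[p]  # query atom i -> target atom m[i]
      ok <- TRUE
      for (i in seq_len(nq)) {
        if (q$atoms[i] != "*" && q$atoms[i] != t$atoms[m[i]]) { ok <- FALSE; break }
      }
      if (!ok) next
      for (i in seq_len(nq)) {
        for (j in seq_len(nq)) {
          if (j <= i || aq[i, j] == "") next
          to <- at[m[i], m[j]]
          if (to == "" || (aq[i, j] != "any" && aq[i, j] != to)) { ok <- FALSE; break }
          if (qr[i, j] && !tr[m[i], m[j]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

# random connected molecule-like graph
random_mol_graph <- function(n, labels = c("C", "N", "O", "S"),
                             orders = c("1", "1", "2", "ar"),
                             extra_edges = 1L) {
  stopifnot(n >= 2)
  i <- integer(); j <- integer()
  for (v in 2:n) { u <- sample.int(v - 1L, 1L); i <- c(i, u); j <- c(j, v) }
  tries <- 0L
  while (extra_edges > 0 && tries < 50) {
    a <- sample.int(n, 2L)
    if (a[1] != a[2] &&
        !any((i == min(a) & j == max(a)) | (i == max(a) & j == min(a)))) {
      i <- c(i, min(a)); j <- c(j, max(a)); extra_edges <- extra_edges - 1L
    }
    tries <- tries + 1L
  }
  mol_graph(sample(labels, n, replace = TRUE),
            data.frame(i = i, j = j,
                       order = sample(orders, length(i), replace = TRUE)))
}

# apply a relabelling permutation: atom k becomes p[k]
permute_graph <- function(g, p) {
  b <- g$bonds; b$i <- p[b$i]; b$j <- p[b$j]
  mol_graph(g$atoms[order(p)], b, g$charges[order(p)])
}

make_cycle <- function(n, lab = "C", ord = "1") {
  mol_graph(rep(lab, n), data.frame(i = seq_len(n), j = c(2:n, 1L), order = ord))
}

# independent union-find component counter over an edge list
uf_components <- function(vertices, from, to) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(vertices, find, "")))
}

# library cached per test session (standardization is the slow part)
cox2_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_compounds(synthetic_cox2_path())
    cache
  }
})

cox2_repsets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- lapply(cox2_library(), nine_representations)
    cache
  }
})
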