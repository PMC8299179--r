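#' Activity classification and enrichment factors
#'
#' Percent-inhibition values are stratified into five classes (inactive,
#' weak, moderate, strong, very strong); molecules in the moderate, strong
#' and very strong classes count as active. The enrichment factor of a node
#' is the ratio between the active fraction of the molecules carrying that
#' framework and the active fraction of the whole library:
#' EF = (MF actives / (MF actives + MF inactives)) /
#'      (Total actives / (Total actives + Total inactives)).
#' Molecules with no activity information are excluded from both numerator
#' and denominator.
#'
#' @name enrichment
NULL

#' Default activity scheme (percent inhibition at a single concentration)
#'
#' Boundaries 19 / 33 / 50 / 80; intervals are closed below and open above,
#' boundary values are assigned to the class upward. Active classes are
#' moderate, strong and very strong (>= 33 percent inhibition).
#'
#' @return an `activity_scheme` list with `breaks`, `classes`,
#'   `active_classes`.
#' @export
default_activity_scheme <- function() {
  structure(list(
    breaks = c(19, 33, 50, 80),
    classes = c("inactive", "weak", "moderate", "strong", "very strong"),
    active_classes = c("moderate", "strong", "very strong")),
    class = "activity_scheme")
}

#' Classify percent-inhibition values
#'
#' @param values numeric vector (percent).
#' @param scheme an `activity_scheme`.
#' @return data frame with columns `class` and `is_active`; `NA` values give
#'   class `NA` (unclassified) and are excluded from enrichment denominators.
#' @export
classify_activity <- function(values, scheme = default_activity_scheme()) {
  stopifnot(all(diff(scheme$breaks) > 0))
  idx <- findInterval(values, scheme$breaks, left.open = FALSE) + 1L
  cls <- scheme$classes[idx]
  data.frame(class = cls,
             is_active = ifelse(is.na(cls), NA, cls %in% scheme$active_classes),
             stringsAsFactors = FALSE)
}

#' Enrichment factor of a molecule set
#'
#' @param member_ids compound ids belonging to the node.
#' @param activities data frame as from [activity_map()]: `compound_id`,
#'   `is_active`.
#' @return an `enrichment_result` list: `mf_actives`, `mf_inactives`,
#'   `total_actives`, `total_inactives`, `mf_ratio`, `total_ratio`, `ef`.
#' @export
enrichment_factor <- function(member_ids, activities) {
  cls <- activities$is_active[!is.na(activities$is_active)]
  ids <- activities$compound_id[!is.na(activities$is_active)]
  total_actives <- sum(cls)
  total_inactives <- sum(!cls)
  if (total_actives == 0)
    stop(errorCondition(
      "enrichment factor undefined: the library contains no active molecule",
      class = c("scaffnet_no_actives_error", "error")))
  member_ids <- unique(member_ids)
  inset <- ids %in% member_ids
  mf_actives <- sum(cls[inset])
  mf_inactives <- sum(!cls[inset])
  mf_ratio <- if (mf_actives + mf_inactives == 0) 0 else
    mf_actives / (mf_actives + mf_inactives)
  total_ratio <- total_actives / (total_actives + total_inactives)
  structure(list(mf_actives = mf_actives, mf_inactives = mf_inactives,
                 total_actives = total_actives,
                 total_inactives = total_inactives,
                 mf_ratio = mf_ratio, total_ratio = total_ratio,
                 ef = mf_ratio / total_ratio),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<EF = %.1f (%d/%d actives in node; library ratio %.3f)>\n",
              x$ef, x$mf_actives, x$mf_actives + x$mf_inactives,
              x$total_ratio))
  invisible(x)
}

#' Annotate network nodes with enrichment factors
#'
#' Framework nodes receive `n_molecules`, `n_actives` and `EF`. The EF of a
#' node is computed per representation kind contributing to the node and the
#' maximum is kept when several kinds collapse onto one key (duplicate
#' structures keep the highest EF). Fragment nodes aggregate the molecules
#' of all the frameworks containing them (their superframeworks) before the
#' EF is computed.
#'
#' @param network a `scaffold_network` (see [build_framework_network()]).
#' @param activities data frame from [activity_map()].
#' @return the network with annotated node table.
#' @export
annotate_network <- function(network, activities) {
  nodes <- network$nodes
  mem <- network$memberships
  act <- activities[!is.na(activities$is_active), ]
  nodes$n_molecules <- 0L
  nodes$n_actives <- 0L
  nodes$EF <- NA_real_
  active_ids <- act$compound_id[act$is_active]
  for (r in seq_len(nrow(nodes))) {
    if (nodes$node_class[r] == "MOLECULE") {
      nodes$n_molecules[r] <- 1L
      nodes$n_actives[r] <- as.integer(nodes$key[r] %in% active_ids)
      next
    }
    if (nodes$node_class[r] == "FRAGMENT") {
      mols <- superframework_molecules(network, nodes$key[r])
    } else {
      mols <- unique(mem$compound_id[mem$key == nodes$key[r]])
    }
    nodes$n_molecules[r] <- length(mols)
    nodes$n_actives[r] <- length(intersect(mols, active_ids))
  }
  # per-kind EF, max on key collision (framework nodes)
  fw <- nodes$node_class == "FRAMEWORK"
  if (any(fw)) {
    ef_by_key <- tapply(seq_len(nrow(mem)), mem$key, function(ix) {
      kinds <- unique(mem$representation_kind[ix])
      max(vapply(kinds, function(k) {
        ids <- unique(mem$compound_id[ix][mem$representation_kind[ix] == k])
        enrichment_factor(ids, act)$ef
      }, 0))
    })
    nodes$EF[fw] <- as.numeric(ef_by_key[nodes$key[fw]])
  }
  frg <- nodes$node_class == "FRAGMENT"
  for (r in which(frg))
    nodes$EF[r] <- enrichment_factor(
      superframework_molecules(network, nodes$key[r]), act)$ef
  mol <- nodes$node_class == "MOLECULE"
  tr <- sum(act$is_active) / nrow(act)
  nodes$EF[mol] <- ifelse(nodes$key[mol] %in% act$compound_id,
                          ifelse(nodes$key[mol] %in% active_ids, 1 / tr, 0),
                          NA_real_)
  network$nodes <- nodes
  network$activities <- activities
  network
}

# all molecules attached to any FRAGMENTATION ancestor (superframework) of a
# fragment node; a fragment that is itself a framework node contributes its
# own membership too
superframework_molecules <- function(network, key) {
  edges <- network$edges
  frag_edges <- edges[edges$edge_class == "FRAGMENTATION", , drop = FALSE]
  anc <- character(0)
  frontier <- key
  while (length(frontier) > 0) {
    parents <- unique(frag_edges$source_key[frag_edges$target_key %in% frontier])
    parents <- setdiff(parents, c(anc, key))
    anc <- c(anc, parents)
    frontier <- parents
  }
  mem <- network$memberships
  unique(mem$compound_id[mem$key %in% c(anc, key)])
}

#' Recompute a fragment's enrichment factor over its superframeworks
#'
#' The molecule set is the union, each molecule counted once, of the
#' molecules of every framework that contains the fragment (all its
#' ancestors through fragmentation edges); the EF is then computed on that
#' union.
#'
#' @param network an annotated or plain `scaffold_network`.
#' @param fragment_key node key of the fragment.
#' @param activities data frame from [activity_map()].
#' @return an `enrichment_result`.
#' @export
superframework_ef <- function(network, fragment_key, activities) {
  if (!fragment_key %in% network$nodes$key)
    stop("fragment key not present in the network: ", fragment_key)
  enrichment_factor(superframework_molecules(network, fragment_key),
                    activities[!is.na(activities$is_active), ])
}

#' Filter out nodes with zero enrichment
#'
#' Removes framework and fragment nodes with EF = 0 together with their
#' incident edges, and molecule nodes left with no surviving representation
#' (inactive-only ancestry). Membership edges re-attach each surviving
#' molecule to its least abstract surviving representation.
#'
#' @param network an annotated `scaffold_network`.
#' @return the filtered network.
#' @export
filter_ef_zero <- function(network) {
  if (!"EF" %in% names(network$nodes))
    stop("network must be annotated (see annotate_network) before filtering")
  nodes <- network$nodes
  drop_keys <- nodes$key[nodes$node_class != "MOLECULE" &
                           !is.na(nodes$EF) & nodes$EF == 0]
  keep <- !(nodes$key %in% drop_keys)
  nodes <- nodes[keep, , drop = FALSE]
  mem <- network$memberships[!(network$memberships$key %in% drop_keys), ,
                             drop = FALSE]
  # molecules with no surviving representation disappear
  molrows <- nodes$node_class == "MOLECULE"
  orphan <- nodes$key[molrows & !(nodes$key %in% mem$compound_id)]
  nodes <- nodes[!(nodes$key %in% orphan), , drop = FALSE]
  edges <- network$edges
  edges <- edges[!(edges$source_key %in% c(drop_keys, orphan)) &
                   !(edges$target_key %in% c(drop_keys, orphan)), ,
                 drop = FALSE]
  # rebuild membership edges toward the least abstract surviving node
  edges <- edges[edges$edge_class != "MEMBERSHIP", , drop = FALSE]
  kinds <- representation_kinds()
  mem2 <- mem[mem$key %in% nodes$key, , drop = FALSE]
  if (nrow(mem2) > 0) {
    mem2$rank <- kinds$abstractness[match(mem2$representation_kind, kinds$kind)]
    for (id in unique(mem2$compound_id)) {
      if (!id %in% nodes$key) next
      sub <- mem2[mem2$compound_id == id, , drop = FALSE]
      tgt <- sub$key[which.min(sub$rank)]
      edges <- rbind(edges, data.frame(source_key = id, target_key = tgt,
                                       edge_class = "MEMBERSHIP",
                                       stringsAsFactors = FALSE))
    }
  }
  network$nodes <- nodes
  network$edges <- edges
  network$memberships <- mem
  network
}
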