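#' End-to-end scaffold analysis
#'
#' Reproduces the four-table output of the analysis protocol: a wide
#' per-molecule table with all nine representations, a long
#' molecule-by-representation table, a deduplicated node attribute file and
#' an edge (network) file for Cytoscape import.
#'
#' @param input path to a SMILES/CSV file, or a list of `compound` objects.
#' @param output_dir directory for the four CSV files; `NULL` skips writing.
#' @param fragments if `TRUE`, the network is extended with fragment nodes.
#' @param fragment_kinds representation kinds to fragment (default the basic
#'   wireframe).
#' @param max_depth fragmentation depth cap (default: full closure).
#' @param dense_membership passed to [build_framework_network()].
#' @param on_error `"stop"` or `"skip"` for unparseable records.
#' @param verbose log per-stage counts to stderr.
#' @return invisibly, a list: `compounds`, `repsets`, `network`, `tables`
#'   (wide, long, nodes, edges), `counts` (parsed, skipped_invalid,
#'   skipped_acyclic, unique_frameworks, components).
#' @export
run_scaffold_analysis <- function(input, output_dir = NULL, fragments = FALSE,
                                  fragment_kinds = "basic_wireframe",
                                  max_depth = NULL, dense_membership = FALSE,
                                  on_error = c("stop", "skip"),
                                  verbose = TRUE) {
  on_error <- match.arg(on_error)
  say <- function(...) if (verbose) message(...)
  if (is.character(input)) {
    compounds <- read_compounds(input, on_error = on_error)
    n_records <- attr(compounds, "n_records")
    if (is.null(n_records)) n_records <- length(compounds)
  } else {
    compounds <- input
    n_records <- length(compounds)
  }
  say("parsed ", length(compounds), " molecule(s)")
  repsets <- list()
  acyclic <- character()
  for (cp in compounds) {
    rs <- tryCatch(nine_representations(cp),
                   scaffnet_no_ring_error = function(e) NULL)
    if (is.null(rs)) acyclic <- c(acyclic, cp$compound_id) else
      repsets[[length(repsets) + 1L]] <- rs
  }
  if (length(acyclic) > 0)
    say("skipped ", length(acyclic), " acyclic molecule(s): ",
        paste(utils::head(acyclic, 5), collapse = ", "))
  if (length(repsets) == 0) stop("no molecule with at least one ring in input")
  long <- representations_long(repsets)
  wide <- representations_wide(repsets, compounds)
  network <- build_framework_network(repsets,
                                     dense_membership = dense_membership)
  if (fragments) {
    frags <- generate_fragments(repsets, kinds = fragment_kinds,
                                max_depth = max_depth)
    network <- extend_with_fragments(network, frags)
    say("fragment nodes: ",
        sum(network$nodes$node_class == "FRAGMENT"))
  }
  comps <- network_components(network)
  counts <- list(records = n_records, parsed = length(compounds),
                 skipped_invalid = n_records - length(compounds),
                 skipped_acyclic = length(acyclic),
                 unique_frameworks = sum(network$nodes$node_class == "FRAMEWORK"),
                 components = comps$count)
  say("unique frameworks: ", counts$unique_frameworks,
      "; connected components: ", counts$components)
  tables <- list(wide = wide, long = long, nodes = network$nodes,
                 edges = network$edges)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(wide, file.path(output_dir, "molecular_frameworks_per_smiles.csv"),
                     row.names = FALSE)
    utils::write.csv(long, file.path(output_dir, "molecular_frameworks_list.csv"),
                     row.names = FALSE)
    write_network_csv(network,
                      file.path(output_dir, "network_attributes.csv"),
                      file.path(output_dir, "network_edges.csv"))
  }
  invisible(list(compounds = compounds, repsets = repsets, network = network,
                 tables = tables, counts = counts))
}

# wide per-molecule table: identity columns + structure and key per kind
representations_wide <- function(repsets, compounds) {
  cmap <- stats::setNames(compounds,
                          vapply(compounds, `[[`, "", "compound_id"))
  kinds <- representation_kinds()$kind
  rows <- lapply(repsets, function(rs) {
    cp <- cmap[[rs$compound_id]]
    row <- data.frame(compound_id = rs$compound_id,
                      input_smiles = cp$input_smiles,
                      canonical_smiles = cp$canonical_smiles,
                      inchikey = cp$inchikey,
                      ring_count = rs$ring_count,
                      stringsAsFactors = FALSE)
    for (k in kinds) {
      row[[k]] <- encode_structure(rs$reps[[k]]$graph)
      row[[paste0(k, "_key")]] <- rs$reps[[k]]$key
    }
    row
  })
  do.call(rbind, rows)
}

#' Enrichment-annotated scaffold analysis
#'
#' Runs [run_scaffold_analysis()], derives the activity map, annotates every
#' node with molecule counts and enrichment factors, optionally removes
#' EF = 0 nodes, and reports frameworks ranked by EF and number of connected
#' active molecules.
#'
#' @inheritParams run_scaffold_analysis
#' @param scheme activity scheme for percent-inhibition input.
#' @param filter_zero if `TRUE`, apply [filter_ef_zero()].
#' @return invisibly, the [run_scaffold_analysis()] result extended with
#'   `activities`, the annotated `network` and the `ranking` data frame.
#' @export
run_enrichment_analysis <- function(input, output_dir = NULL,
                                    scheme = default_activity_scheme(),
                                    filter_zero = FALSE, fragments = FALSE,
                                    fragment_kinds = "basic_wireframe",
                                    max_depth = NULL,
                                    dense_membership = FALSE,
                                    on_error = c("stop", "skip"),
                                    verbose = TRUE) {
  res <- run_scaffold_analysis(input, output_dir = NULL,
                               fragments = fragments,
                               fragment_kinds = fragment_kinds,
                               max_depth = max_depth,
                               dense_membership = dense_membership,
                               on_error = on_error, verbose = verbose)
  acts <- activity_map(res$compounds, scheme)
  if (all(is.na(acts$is_active)))
    stop("no activity information in input (activity or active column needed)")
  if (!any(acts$is_active, na.rm = TRUE))
    stop(errorCondition(paste0(
      "enrichment factor undefined: Total actives = 0 makes the Total ",
      "ratio denominator zero"), class = c("scaffnet_no_actives_error", "error")))
  network <- annotate_network(res$network, acts)
  if (filter_zero) network <- filter_ef_zero(network)
  fw <- network$nodes[network$nodes$node_class != "MOLECULE", , drop = FALSE]
  ranking <- fw[order(-fw$EF, -fw$n_actives, fw$key), ,
                drop = FALSE]
  rownames(ranking) <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$tables$wide,
                     file.path(output_dir, "molecular_frameworks_per_smiles.csv"),
                     row.names = FALSE)
    utils::write.csv(res$tables$long,
                     file.path(output_dir, "molecular_frameworks_list.csv"),
                     row.names = FALSE)
    write_network_csv(network,
                      file.path(output_dir, "network_attributes.csv"),
                      file.path(output_dir, "network_edges.csv"))
    utils::write.csv(ranking, file.path(output_dir, "framework_ranking.csv"),
                     row.names = FALSE)
  }
  res$network <- network
  res$activities <- acts
  res$ranking <- ranking
  invisible(res)
}
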