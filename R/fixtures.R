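#' Worked-example structures and synthetic screening libraries
#'
#' Everything the test-suite needs is generated in code or read from the
#' small plain-text library bundled with the package, so no download is ever
#' required. The bundled file `synthetic_cox2_library.csv` is a synthetic
#' stand-in assembled from published COX-2 inhibitor structures plus
#' unrelated filler drugs; it is NOT the historical screening dataset.
#'
#' @name fixtures
NULL

#' Path to the bundled synthetic COX-2-style library
#' @return file path.
#' @export
synthetic_cox2_path <- function() {
  p <- system.file("extdata", "synthetic_cox2_library.csv",
                   package = "scaffnet")
  if (p == "") {
    # running from a source checkout (tests via pkgload, etc.)
    p <- file.path("inst", "extdata", "synthetic_cox2_library.csv")
  }
  if (!file.exists(p))
    stop("bundled fixture synthetic_cox2_library.csv not found")
  p
}

#' Worked-example compounds
#'
#' A named list of standardized compounds used throughout the documentation
#' and tests: polmacoxib (read from the bundled library, a three-ring
#' diaryl-furanone sulfonamide), branched side-chain cases for the augmented
#' scaffold rule (three candidate paths; two equal-length longest paths;
#' a single path), and the three fragmentation-rule topologies (an internal
#' chain, a fused ring pair, an internal ring).
#'
#' @return named list of `compound` objects.
#' @export
worked_examples <- function() {
  lib <- read_compounds(synthetic_cox2_path())
  ids <- vapply(lib, `[[`, "", "compound_id")
  pol <- lib[[match("polmacoxib", ids)]]
  if (is.null(pol)) stop("polmacoxib missing from the bundled fixture")
  ex <- standardize_smiles(
    c("CCCC(C)(CC)c1ccccc1",            # three candidate paths, one longest
      "CCC(CC)c1ccccc1",                # two equal-length longest paths
      "CCCc1ccccc1",                    # a single path
      "c1ccccc1CCc1ccccc1",             # internal chain between two rings
      "c1ccc2ccccc2c1",                 # fused ring pair
      "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1"  # internal (middle) ring
    ),
    ids = c("chains_three_paths", "chains_tied_paths", "chain_single_path",
            "internal_chain", "fused_pair", "internal_ring"))
  c(list(polmacoxib = pol), stats::setNames(ex, vapply(ex, `[[`, "", "compound_id")))
}

# substitution sites get one decoration from this palette
.substituents <- c("C", "CC", "CCC", "OC", "O", "Cl", "F", "C(F)(F)F",
                   "C(C)C", "CCO", "N", "C(=O)C")

# diverse ring-system templates; %s is the decoration point
.templates <- c(
  "Cc1ccc(-c2cc(%s)nn2-c2ccc(S(N)(=O)=O)cc2)cc1",
  "O=C1OCC(c2ccc(%s)cc2)=C1c1ccccc1",
  "c1ccc(-c2ccc(%s)cn2)cc1",
  "O=C(Nc1ccc(%s)cc1)c1ccccn1",
  "c1ccc2[nH]c(-c3ccc(%s)cc3)nc2c1",
  "C(%s)c1ccc2ccccc2c1",
  "O=S(=O)(N)c1ccc(-c2csc(%s)n2)cc1",
  "c1ccc(-c2nnc(%s)o2)cc1",
  "O=C(%s)N1CCN(c2ccccc2)CC1",
  "c1ccc(OCC(%s)N2CCCCC2)cc1",
  "Clc1ccc(C(%s)c2ccccn2)cc1",
  "Cc1oc(-c2ccccc2)cc1C(=O)N%s")

#' Synthetic screening library with planted enrichment
#'
#' Generates decorated variants of template ring systems and assigns percent
#' inhibition so that a chosen fraction of the scaffolds is enriched in
#' actives: molecules from enriched scaffolds draw inhibition in 40-95
#' percent, all others in 0-15 percent (clearly inside/outside the >= 33
#' percent active classes). The planted enrichment factor of an enriched
#' scaffold is therefore exactly (1) / (fraction of molecules active).
#'
#' @param n_scaffolds number of template scaffolds to use (max 12).
#' @param n_per_scaffold molecules generated per scaffold.
#' @param active_scaffold_fraction fraction of scaffolds planted as active.
#' @param seed integer seed; the library is reproducible per seed.
#' @return list of `compound` objects with `activity_value` set; the planted
#'   truth is attached as attributes `enriched_templates` (template indices)
#'   and `planted_ef` (the analytic EF of an enriched scaffold's molecules).
#' @export
synthetic_library <- function(n_scaffolds = 8, n_per_scaffold = 10,
                              active_scaffold_fraction = 0.25, seed = 1) {
  stopifnot(n_scaffolds >= 2, n_scaffolds <= length(.templates),
            n_per_scaffold >= 1)
  set.seed(seed)
  n_active_sc <- max(1L, round(n_scaffolds * active_scaffold_fraction))
  enriched <- seq_len(n_active_sc)  # deterministic choice; decorations vary
  smis <- character(); ids <- character(); act <- numeric()
  for (s in seq_len(n_scaffolds)) {
    subs <- sample(.substituents, n_per_scaffold, replace = TRUE)
    for (m in seq_len(n_per_scaffold)) {
      smis <- c(smis, sprintf(.templates[s], subs[m]))
      ids <- c(ids, sprintf("S%02d_M%02d", s, m))
      act <- c(act, if (s %in% enriched) stats::runif(1, 40, 95)
               else stats::runif(1, 0, 15))
    }
  }
  lib <- standardize_smiles(smis, ids = ids, activity = act)
  total_ratio <- (n_active_sc * n_per_scaffold) /
    (n_scaffolds * n_per_scaffold)
  structure(lib, enriched_templates = enriched, planted_ef = 1 / total_ratio)
}
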