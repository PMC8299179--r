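#' @import ChemmineR
NULL

# monoisotopic-ish average masses for the largest-component tie-break only
.atomic_mass <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                  F = 18.998, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.45,
                  Se = 78.971, Br = 79.904, I = 126.904, As = 74.922,
                  Na = 22.99, K = 39.098, Li = 6.94, Mg = 24.305, Ca = 40.078,
                  Zn = 65.38, Fe = 55.845, Pt = 195.084)

mg_weight <- function(g) {
  m <- .atomic_mass[g$atoms]
  m[is.na(m)] <- 12
  sum(m)
}

# ---- OpenBabel bridge (via ChemmineOB) --------------------------------------

ob_convert <- function(src, from, to, genopts = character()) {
  opts <- if (length(genopts) > 0)
    data.frame(names = genopts, args = rep("", length(genopts)),
               stringsAsFactors = FALSE)
  else
    data.frame(names = character(), args = character())
  out <- ChemmineOB::convertFormat(from, to, src, options = opts)
  out
}

# Neutralize + canonicalize a vector of SMILES in one OpenBabel pass.
# Titles (indices) ride along on the SMILES line so that records skipped by
# OpenBabel are detected rather than silently misaligning the batch.
ob_smiles_clean <- function(smiles) {
  src <- paste0(smiles, " idx", seq_along(smiles), collapse = "\n")
  out <- suppressWarnings(ob_convert(paste0(src, "\n"), "SMI", "CAN",
                                     genopts = "neutralize"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(smiles))
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) >= 2 && grepl("^idx[0-9]+$", parts[length(parts)])) {
      k <- as.integer(sub("idx", "", parts[length(parts)]))
      res[k] <- paste(parts[-length(parts)], collapse = "")
    }
  }
  res
}

#' Write a molecular graph as a V2000 molblock
#'
#' Only concrete graphs (no wildcard atoms or bond orders) can be written;
#' coordinates are zero (connectivity only), aromatic bonds use type 4,
#' formal charges are emitted as `M  CHG` lines. Stereochemistry and isotopes
#' are not represented, which is what makes the molblock round-trip the
#' standardization step's stereo/isotope scrubber.
#'
#' @param g a concrete `mol_graph`.
#' @param title molblock title line.
#' @return a single string (the molblock, no trailing `$$$$`).
#' @export
mg_to_molblock <- function(g, title = "") {
  if (is_wildcard_graph(g))
    stop("cannot write a wildcard graph as molblock")
  n <- n_atoms(g); m <- n_bonds(g)
  lines <- c(title, "  scaffnet", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (k in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$atoms[k]))
  }
  btype <- c("1" = 1L, "2" = 2L, "3" = 3L, "ar" = 4L)
  for (k in seq_len(m)) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              g$bonds$i[k], g$bonds$j[k],
                              btype[[g$bonds$order[k]]]))
  }
  chg <- which(g$charges != 0)
  if (length(chg) > 0) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0(sprintf("M  CHG%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, g$charges[grp]),
                                      collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  paste(lines, collapse = "\n")
}

# concrete graph -> canonical SMILES / InChIKey, batched over OpenBabel
mg_to_can_smiles <- function(graphs) {
  if (length(graphs) == 0) return(character())
  sdf <- paste0(vapply(seq_along(graphs),
                       function(k) mg_to_molblock(graphs[[k]], paste0("idx", k)),
                       ""), "\n$$$$\n", collapse = "")
  out <- suppressWarnings(ob_convert(sdf, "SDF", "CAN"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  res <- rep(NA_character_, length(graphs))
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(parts) >= 2 && grepl("^idx[0-9]+$", parts[length(parts)])) {
      k <- as.integer(sub("idx", "", parts[length(parts)]))
      res[k] <- paste(parts[-length(parts)], collapse = "")
    }
  }
  res
}

mg_to_inchikey <- function(graphs) {
  if (length(graphs) == 0) return(character())
  res <- rep(NA_character_, length(graphs))
  for (k in seq_along(graphs)) {
    out <- try(suppressWarnings(
      ob_convert(paste0(mg_to_molblock(graphs[[k]]), "\n$$$$\n"),
                 "SDF", "INCHIKEY")), silent = TRUE)
    if (!inherits(out, "try-error")) {
      ln <- strsplit(out, "\n", fixed = TRUE)[[1]]
      ln <- ln[nzchar(ln)]
      if (length(ln) >= 1 && grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", trimws(ln[1])))
        res[k] <- trimws(ln[1])
    }
  }
  res
}

# ---- SMILES -> mol_graph ----------------------------------------------------

# single atom token, e.g. "O", "[Na+]", "[13CH4]"
.atom_token_re <- "^\\[?[0-9]*([A-Z][a-z]?)[H0-9]*[+-]?[0-9]*\\]?$"

# parse one SMILES into a concrete mol_graph; aromaticity from ring perception
graph_from_smiles <- function(smi) {
  parts <- strsplit(smi, ".", fixed = TRUE)[[1]]
  if (all(grepl(.atom_token_re, parts))) {
    # bond-less molecule (SDF readers reject an empty bond block)
    return(mol_graph(sub(.atom_token_re, "\\1", parts)))
  }
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smi))[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  atoms <- sub("_.*$", "", rownames(ab))
  n <- length(atoms)
  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- NULL
  } else {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.character(bb[, 3]),
                        stringsAsFactors = FALSE)
  }
  # formal charges from the molblock text (M  CHG lines)
  charges <- integer(n)
  sdflines <- as(sdf, "character")
  for (ln in grep("^M  CHG", sdflines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ ]+")[[1]])
    cnt <- f[1]
    for (q in seq_len(cnt)) charges[f[2 * q]] <- f[2 * q + 1]
  }
  g <- mol_graph(atoms, bonds, charges)
  # mark aromatic bonds using ChemmineR ring perception
  if (ring_count(g) > 0) {
    ri <- tryCatch(ChemmineR::rings(sdf, upper = 14, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(ri) && length(ri$RINGS) > 0) {
      arom <- names(ri$AROMATIC)[ri$AROMATIC]
      for (rn in arom) {
        idx <- as.integer(sub("^.*_", "", ri$RINGS[[rn]]))
        pairs <- cbind(idx, c(idx[-1], idx[1]))
        for (p in seq_len(nrow(pairs))) {
          a <- min(pairs[p, ]); b <- max(pairs[p, ])
          hit <- which(g$bonds$i == a & g$bonds$j == b)
          if (length(hit) == 1) g$bonds$order[hit] <- "ar"
        }
      }
    }
  }
  g
}

# ---- Standardization --------------------------------------------------------

new_compound <- function(compound_id, input_smiles, graph, canonical_smiles,
                         inchikey, structure_key, activity_value = NA_real_,
                         is_active = NA) {
  structure(list(compound_id = compound_id, input_smiles = input_smiles,
                 graph = graph, canonical_smiles = canonical_smiles,
                 inchikey = inchikey, structure_key = structure_key,
                 activity_value = activity_value, is_active = is_active),
            class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound %s: %s (%d atoms, %d rings)>\n", x$compound_id,
              x$canonical_smiles, n_atoms(x$graph), ring_count(x$graph)))
  invisible(x)
}

#' Standardize molecules from SMILES
#'
#' Standardization keeps the largest covalent component (by heavy-atom count,
#' ties broken by molecular weight), neutralizes chemically trivial formal
#' charges, and drops stereochemistry and isotope labels. The returned
#' compounds carry the heavy-atom `mol_graph`, an OpenBabel canonical SMILES,
#' an InChIKey and the package's canonical structure key.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional compound identifiers (default `M0001`, ...).
#' @param activity optional numeric vector (percent inhibition).
#' @param is_active optional logical vector (binary activity flag).
#' @param on_error `"stop"` (default) to fail on the first unparseable
#'   record, `"skip"` to drop bad records with a warning.
#' @return a list of `compound` objects.
#' @export
standardize_smiles <- function(smiles, ids = NULL, activity = NULL,
                               is_active = NULL,
                               on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  if (length(smiles) == 0) stop("empty input: no SMILES records")
  smiles <- as.character(smiles)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_along(smiles))
  if (is.null(activity)) activity <- rep(NA_real_, length(smiles))
  if (is.null(is_active)) is_active <- rep(NA, length(smiles))
  blank <- !nzchar(trimws(smiles))
  if (any(blank) && on_error == "stop")
    stop("empty SMILES for record ", ids[which(blank)[1]])
  clean <- ob_smiles_clean(smiles)
  out <- vector("list", length(smiles))
  for (k in seq_along(smiles)) {
    if (blank[k] || is.na(clean[k])) {
      if (on_error == "stop")
        stop("unparseable SMILES for record ", ids[k], ": ", smiles[k])
      warning("skipping unparseable SMILES for record ", ids[k])
      next
    }
    g <- tryCatch(graph_from_smiles(clean[k]), error = function(e) NULL)
    if (is.null(g) || n_atoms(g) == 0) {
      if (on_error == "stop")
        stop("unparseable SMILES for record ", ids[k], ": ", smiles[k])
      warning("skipping unparseable SMILES for record ", ids[k])
      next
    }
    comp <- mg_components(g)
    if (max(comp) > 1) {
      sizes <- tabulate(comp)
      cands <- which(sizes == max(sizes))
      if (length(cands) > 1) {
        wts <- vapply(cands, function(cc) mg_weight(mg_induced(g, comp == cc)), 0)
        cands <- cands[which.max(wts)]
      }
      g <- mg_induced(g, comp == cands[1])
    }
    out[[k]] <- list(g = g, id = ids[k], smi = smiles[k],
                     act = activity[k], flag = is_active[k])
  }
  kept <- !vapply(out, is.null, TRUE)
  out <- out[kept]
  graphs <- lapply(out, `[[`, "g")
  cans <- mg_to_can_smiles(graphs)
  keys <- mg_to_inchikey(graphs)
  lapply(seq_along(out), function(k) {
    new_compound(out[[k]]$id, out[[k]]$smi, graphs[[k]], cans[k], keys[k],
                 structure_key(graphs[[k]]),
                 out[[k]]$act, out[[k]]$flag)
  })
}

#' Standardize a single SMILES string
#' @inheritParams standardize_smiles
#' @param id compound identifier.
#' @return a `compound` object.
#' @export
standardize <- function(smiles, id = "M0001") {
  standardize_smiles(smiles, ids = id)[[1]]
}

#' Read a compound table
#'
#' Accepts either plain text (one SMILES per line) or a delimited table
#' (comma or tab, auto-detected). With a header, columns named (case
#' insensitively) `smiles`, `id`/`name`/`compound_id`, `activity`/`percent`/
#' `inhibition` and `active` are recognized; without one, the first column is
#' taken as SMILES.
#'
#' @param path input file.
#' @param on_error passed to [standardize_smiles()].
#' @param smiles_col,id_col,activity_col,active_col optional header names
#'   overriding the automatic column recognition.
#' @param delimiter optional field delimiter (`","` or `"\t"`); auto-detected
#'   by default.
#' @return a list of `compound` objects.
#' @export
read_compounds <- function(path, on_error = c("stop", "skip"),
                           smiles_col = NULL, id_col = NULL,
                           activity_col = NULL, active_col = NULL,
                           delimiter = NULL) {
  on_error <- match.arg(on_error)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty input file: ", path)
  sep <- if (!is.null(delimiter)) delimiter else
    if (grepl("\t", lines[1])) "\t" else if (grepl(",", lines[1])) "," else ""
  if (sep == "") {
    first <- trimws(lines[1])
    has_header <- grepl("^smiles$", first, ignore.case = TRUE)
    smis <- if (has_header) lines[-1] else lines
    out <- standardize_smiles(trimws(smis), on_error = on_error)
    attr(out, "n_records") <- length(smis)
    return(out)
  }
  df0 <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  hdr <- tolower(trimws(as.character(df0[1, ])))
  has_header <- any(hdr %in% c("smiles", "structure", "canonical_smiles")) ||
    (!is.null(smiles_col) && tolower(smiles_col) %in% hdr)
  pick <- function(override, defaults) {
    if (!is.null(override)) which(hdr == tolower(override))[1]
    else which(hdr %in% defaults)[1]
  }
  if (has_header) {
    df <- df0[-1, , drop = FALSE]
    names(df) <- hdr
    smi_col <- pick(smiles_col, c("smiles", "structure", "canonical_smiles"))
    id_col <- pick(id_col, c("id", "name", "compound_id"))
    act_col <- pick(activity_col, c("activity", "percent", "inhibition",
                                    "percent_inhibition"))
    flag_col <- pick(active_col, c("active", "is_active"))
  } else {
    df <- df0
    smi_col <- 1L; id_col <- NA_integer_
    act_col <- NA_integer_; flag_col <- NA_integer_
  }
  out <- standardize_smiles(
    trimws(as.character(df[[smi_col]])),
    ids = if (!is.na(id_col)) as.character(df[[id_col]]) else NULL,
    activity = if (!is.na(act_col)) suppressWarnings(as.numeric(df[[act_col]])) else NULL,
    is_active = if (!is.na(flag_col)) as.logical(df[[flag_col]]) else NULL,
    on_error = on_error)
  attr(out, "n_records") <- nrow(df)
  out
}

#' Activity map of a compound set
#'
#' @param compounds list of `compound` objects.
#' @param scheme an activity scheme (see [default_activity_scheme()]) used to
#'   derive the active flag from percent inhibition where no explicit flag is
#'   present.
#' @return data frame with columns `compound_id`, `activity_value`,
#'   `is_active` (logical, `NA` when unclassified).
#' @export
activity_map <- function(compounds, scheme = default_activity_scheme()) {
  id <- vapply(compounds, `[[`, "", "compound_id")
  act <- vapply(compounds, function(x) as.numeric(x$activity_value)[1], 0)
  flag <- vapply(compounds, function(x) as.logical(x$is_active)[1], TRUE)
  derived <- ifelse(!is.na(flag), flag,
                    ifelse(!is.na(act), classify_activity(act, scheme)$is_active, NA))
  data.frame(compound_id = id, activity_value = act, is_active = derived,
             stringsAsFactors = FALSE)
}
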