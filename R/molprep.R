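#' Elements excluded from the screening library
#'
#' Metals and metalloids removed from candidate libraries before screening
#' (Al, As, Ba, Bi, Cd, Co, Cr, Mn, Ni, Pb, Sb, Sn, Sr, Ti, Zr); these lack
#' force-field parameters in the downstream 3D workflows and are stripped at
#' curation time.
#'
#' @return Character vector of element symbols.
#' @export
excluded_elements_default <- function() {
  c("Al", "As", "Ba", "Bi", "Cd", "Co", "Cr", "Mn", "Ni", "Pb", "Sb", "Sn",
    "Sr", "Ti", "Zr")
}

#' Assemble a molecule table
#'
#' The pipeline represents a chemical library as a plain data frame with one
#' row per record: `id`, `smiles`, `name`, `role` (one of `candidate`,
#' `binder`, `modulator`), `potency_um` (lowest reported IC50/Ki/Kd, in
#' micromolar, `NA` when unknown) and `activity` (`active`, `inactive`,
#' `ambiguous`, or `NA`).
#'
#' @param id Character vector of identifiers (CAS-style strings).
#' @param smiles SMILES strings.
#' @param name Optional free-text names.
#' @param role Record role; recycled.
#' @param potency_um Optional positive potencies in micromolar.
#' @param activity Optional activity labels.
#' @return A `data.frame` with the columns described above.
#' @export
molecule_table <- function(id, smiles, name = "", role = "candidate",
                           potency_um = NA_real_, activity = NA_character_) {
  id <- as.character(id)
  if (any(!nzchar(id))) stop("molecule ids must be non-empty")
  ok_role <- role %in% c("candidate", "binder", "modulator")
  if (!all(ok_role)) stop("role must be candidate, binder, or modulator")
  if (any(!is.na(potency_um) & potency_um <= 0)) {
    stop("potency_um must be positive when present")
  }
  data.frame(id = id, smiles = as.character(smiles),
             name = rep_len(as.character(name), length(id)),
             role = rep_len(role, length(id)),
             potency_um = rep_len(as.numeric(potency_um), length(id)),
             activity = rep_len(as.character(activity), length(id)),
             stringsAsFactors = FALSE)
}

#' Standardize and curate a chemical library
#'
#' Applies the library pre-treatment used throughout the pipeline: counter
#' ions are removed (the largest carbon-containing fragment is kept), strong
#' acids are deprotonated and strong bases protonated, records containing
#' excluded elements are removed, and duplicates (identical canonical SMILES
#' after standardization, stereochemistry retained) are collapsed to a single
#' record. Unparseable structures are dropped with reason `parse_error`;
#' nothing is removed silently.
#'
#' Duplicate groups keep the record with the lexicographically smallest id,
#' so the output is invariant under permutation of the input. When duplicate
#' records carry several potencies, the minimum (most potent) is retained.
#'
#' @param records Molecule table (see [molecule_table()]).
#' @param excluded_elements Element symbols that disqualify a record;
#'   defaults to [excluded_elements_default()].
#' @return A list with `molecules` (standardized molecule table, column
#'   `smiles` canonical) and `report` (a `standardization_report`: counts
#'   `n_input`, `n_removed_elements`, `n_removed_duplicates`,
#'   `n_removed_parse`, `n_output`, and a `removed` table of id/reason).
#' @export
standardize_library <- function(records,
                                excluded_elements = excluded_elements_default()) {
  stopifnot(is.data.frame(records), all(c("id", "smiles") %in% names(records)))
  if (anyDuplicated(records$id)) stop("input ids must be unique")
  n_input <- nrow(records)
  if (n_input == 0L) {
    report <- new_standardization_report(0L, 0L, 0L, 0L,
                                         removed = empty_removed())
    return(list(molecules = records, report = report))
  }
  res <- run_backend("standardize", records$id, records$smiles,
                     args = c("--excluded",
                              paste(excluded_elements, collapse = ",")))
  res <- res[match(records$id, res$id), ]

  removed <- data.frame(id = character(0), reason = character(0),
                        detail = character(0), stringsAsFactors = FALSE)
  bad <- res$status != "ok"
  if (any(bad)) {
    removed <- data.frame(id = res$id[bad], reason = res$status[bad],
                          detail = res$detail[bad], stringsAsFactors = FALSE)
  }
  keep <- records[!bad, , drop = FALSE]
  keep$smiles <- res$smiles[!bad]

  # collapse duplicates by canonical structure key, survivor = smallest id
  n_dup <- 0L
  if (nrow(keep) > 0L) {
    ord <- order(keep$smiles, keep$id)
    keep <- keep[ord, , drop = FALSE]
    dup <- duplicated(keep$smiles)
    if (any(dup)) {
      n_dup <- sum(dup)
      key <- keep$smiles
      if (!is.null(keep$potency_um)) {
        pot <- tapply(keep$potency_um, key, function(p) {
          if (all(is.na(p))) NA_real_ else min(p, na.rm = TRUE)
        })
      }
      removed <- rbind(removed, data.frame(
        id = keep$id[dup], reason = "duplicate",
        detail = paste("duplicate of", key[dup]), stringsAsFactors = FALSE))
      keep <- keep[!dup, , drop = FALSE]
      if (!is.null(keep$potency_um)) {
        keep$potency_um <- as.numeric(pot[keep$smiles])
      }
    }
    keep <- keep[order(match(keep$id, records$id)), , drop = FALSE]
    rownames(keep) <- NULL
  }

  report <- new_standardization_report(
    n_input = n_input,
    n_removed_elements = sum(res$status == "excluded_element"),
    n_removed_duplicates = n_dup,
    n_removed_parse = sum(res$status == "parse_error"),
    removed = removed)
  list(molecules = keep, report = report)
}

empty_removed <- function() {
  data.frame(id = character(0), reason = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

new_standardization_report <- function(n_input, n_removed_elements,
                                       n_removed_duplicates, n_removed_parse,
                                       removed) {
  structure(list(n_input = as.integer(n_input),
                 n_removed_elements = as.integer(n_removed_elements),
                 n_removed_duplicates = as.integer(n_removed_duplicates),
                 n_removed_parse = as.integer(n_removed_parse),
                 n_output = as.integer(n_input - n_removed_elements -
                                         n_removed_duplicates - n_removed_parse),
                 removed = removed),
            class = "standardization_report")
}

#' @export
print.standardization_report <- function(x, ...) {
  cat("Library standardization report\n")
  cat(sprintf("  input records:        %d\n", x$n_input))
  cat(sprintf("  removed (elements):   %d\n", x$n_removed_elements))
  cat(sprintf("  removed (duplicates): %d\n", x$n_removed_duplicates))
  cat(sprintf("  removed (unparseable):%d\n", x$n_removed_parse))
  cat(sprintf("  output records:       %d\n", x$n_output))
  invisible(x)
}

#' Classify a compound as a reference binder
#'
#' A compound qualifies as a reference binder when its competitive-binding
#' potency (lowest of IC50, Ki, Kd) is at or below 10 micromolar; the
#' boundary is inclusive. Missing potency yields `NA` ("unknown"), and such
#' records are excluded from the binder reference set.
#'
#' @param potency_um Potency in micromolar; positive when present.
#' @param threshold_um Binder threshold, default 10.
#' @return Logical vector (`NA` where potency is missing).
#' @export
classify_binder <- function(potency_um, threshold_um = 10) {
  if (any(!is.na(potency_um) & potency_um <= 0)) {
    stop("potency_um must be positive")
  }
  ifelse(is.na(potency_um), NA, potency_um <= threshold_um)
}

#' Read a SMILES file
#'
#' One record per line: SMILES, whitespace, identifier, then an optional
#' free-text name.
#'
#' @param path File path.
#' @param role Role assigned to all records.
#' @return A molecule table.
#' @export
read_smiles <- function(path, role = "candidate") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(molecule_table(character(0), character(0)))
  }
  parts <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  smiles <- vapply(parts, `[`, "", 1L)
  rest <- trimws(vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""))
  rest_parts <- regmatches(rest, regexpr("\\s+", rest), invert = TRUE)
  ids <- vapply(rest_parts, `[`, "", 1L)
  nm <- trimws(vapply(rest_parts,
                      function(p) if (length(p) > 1) p[2] else "", ""))
  if (any(is.na(ids) | !nzchar(ids))) {
    stop("every SMILES line needs an identifier after the structure")
  }
  molecule_table(ids, smiles, name = nm, role = role)
}

#' Write a SMILES file
#'
#' @param molecules Molecule table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(molecules, path) {
  writeLines(paste(molecules$smiles, molecules$id), path)
  invisible(path)
}

#' Read an SDF file into a molecule table
#'
#' Identifiers are taken from the named SDF property, falling back to the
#' title line.
#'
#' @param path SDF path.
#' @param id_prop Property holding the identifier (e.g. `"CAS"`).
#' @param role Role assigned to all records.
#' @return Molecule table (structures re-expressed as SMILES).
#' @export
read_sdf <- function(path, id_prop = NULL, role = "candidate") {
  args <- character(0)
  if (!is.null(id_prop)) args <- c("--id-prop", id_prop)
  res <- run_backend("read_sdf", infile = path, args = args)
  bad <- startsWith(res$id, "__unparseable_")
  if (any(bad)) {
    warning(sum(bad), " SDF record(s) could not be parsed and were skipped")
    res <- res[!bad, , drop = FALSE]
  }
  molecule_table(res$id, res$smiles, name = res$name, role = role)
}

#' Write a standardization report as a tab-separated table
#'
#' @param report A `standardization_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$removed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
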