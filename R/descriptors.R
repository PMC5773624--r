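#' Default 2D descriptor registry
#'
#' Sixty-eight named 2D descriptors covering hydrophobicity (Crippen logP,
#' molar refractivity), polarity of the van der Waals surface binned by
#' partial charge (PEOE_VSA1-14), size (molecular weight, heavy atoms,
#' Labute approximate surface area), shape and branching (Balaban J, Kier
#' kappa 1-3, connectivity chi indices, Bertz complexity), aromaticity
#' (aromatic ring/bond counts), flexibility (rotatable bonds, fraction of
#' sp3 carbons), hydrogen bonding (donor/acceptor counts, topological polar
#' surface area), and composition (halogens, heteroatoms, ring-type counts,
#' SMR/SlogP surface-area bins). Names follow the RDKit descriptor
#' vocabulary plus two pipeline-defined counts (`AromaticBonds`,
#' `Halogens`); any subset or superset of resolvable names may be supplied
#' instead of the default.
#'
#' @return Character vector of 68 descriptor names.
#' @export
descriptor_registry_default <- function() {
  c("MolLogP", "MolMR", "MolWt", "TPSA", "LabuteASA", "HeavyAtomCount",
    "FractionCSP3", "NumHDonors", "NumHAcceptors", "NumRotatableBonds",
    "NumAromaticRings", "NumAliphaticRings", "NumSaturatedRings",
    "RingCount", "NumAromaticHeterocycles", "NumAromaticCarbocycles",
    "NumHeteroatoms", "NHOHCount", "NOCount", "BalabanJ", "BertzCT",
    "HallKierAlpha", "Kappa1", "Kappa2", "Kappa3",
    "Chi0", "Chi1", "Chi0n", "Chi1n", "Chi2n", "Chi3n", "Chi4n",
    "Chi0v", "Chi1v", "Chi2v", "Chi3v", "Chi4v",
    paste0("PEOE_VSA", 1:14), paste0("SMR_VSA", 1:10),
    paste0("SlogP_VSA", 1:5), "AromaticBonds", "Halogens")
}

#' Compute the 2D molecular descriptor matrix
#'
#' Computes every descriptor in the registry for every molecule. Any
#' descriptor failure or non-finite value aborts with an error naming the
#' molecule and descriptor; the returned matrix never contains missing
#' values.
#'
#' @param molecules Standardized molecule table ([standardize_library()]).
#' @param registry Ordered descriptor names; default
#'   [descriptor_registry_default()].
#' @return Numeric matrix (compounds x descriptors) with molecule ids as row
#'   names and descriptor names as column names.
#' @export
compute_descriptors <- function(molecules,
                                registry = descriptor_registry_default()) {
  stopifnot(is.data.frame(molecules), nrow(molecules) > 0L)
  reg_file <- tempfile(fileext = ".txt")
  on.exit(unlink(reg_file))
  writeLines(registry, reg_file)
  res <- run_backend("descriptors", molecules$id, molecules$smiles,
                     args = c("--registry", reg_file))
  m <- as.matrix(res[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- res$id
  m <- m[match(molecules$id, rownames(m)), , drop = FALSE]
  if (anyNA(m) || any(!is.finite(m))) {
    stop("descriptor matrix contains non-finite values")  # backend guards this
  }
  m
}

#' Compute 166-key structural fingerprints
#'
#' Public 166-bit MACCS structural keys for each molecule; deterministic for
#' a given structure. Molecules with no heavy atoms are rejected.
#'
#' @param molecules Standardized molecule table.
#' @return Integer 0/1 matrix (compounds x 166) with ids as row names,
#'   class `maccs_fps`.
#' @export
compute_fingerprints <- function(molecules) {
  stopifnot(is.data.frame(molecules), nrow(molecules) > 0L)
  res <- run_backend("maccs", molecules$id, molecules$smiles)
  res <- res[match(molecules$id, res$id), ]
  bits <- vapply(res$bits, function(b) {
    as.integer(strsplit(b, "", fixed = TRUE)[[1]])
  }, integer(166))
  m <- t(bits)
  dimnames(m) <- list(res$id, paste0("key", seq_len(166)))
  class(m) <- c("maccs_fps", class(m))
  m
}

#' Number of set keys per fingerprint
#'
#' @param fps Fingerprint matrix from [compute_fingerprints()].
#' @return Named integer vector of set-bit counts.
#' @export
fingerprint_counts <- function(fps) {
  rowSums(unclass(fps))
}

#' Log-transform a descriptor matrix
#'
#' Applies a monotone per-column natural-log transform to normalize skewed
#' descriptor distributions before distance-based analysis. Columns whose
#' name matches `already_log_pattern` (log-scaled by construction, e.g.
#' Crippen logP) pass through unchanged. Strictly positive columns are
#' transformed as `log(x)`; columns containing zeros or negative values are
#' shifted first, `log(x - min(x) + 1)`. Constant columns raise a warning
#' (a log transform cannot normalize them) but still follow the same rule.
#'
#' @param matrix Descriptor matrix.
#' @param already_log_pattern Regular expression for columns already on a
#'   log scale; default matches logP/logS-style names.
#' @return Transformed matrix with an attribute `log_transform` recording
#'   the per-column rule applied (`identity`, `log`, or `shift_log`).
#' @export
log_transform <- function(matrix, already_log_pattern = "(?i)^(mol)?log") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  rule <- character(ncol(matrix))
  names(rule) <- colnames(matrix)
  out <- matrix
  skip <- grepl(already_log_pattern, colnames(matrix), perl = TRUE)
  constant <- apply(matrix, 2, function(x) diff(range(x)) == 0)
  if (any(constant & !skip)) {
    warning("constant column(s) cannot be normalized by log transform: ",
            paste(colnames(matrix)[constant & !skip], collapse = ", "))
  }
  for (j in seq_len(ncol(matrix))) {
    if (skip[j]) {
      rule[j] <- "identity"
    } else if (min(matrix[, j]) > 0) {
      out[, j] <- log(matrix[, j])
      rule[j] <- "log"
    } else {
      out[, j] <- log(matrix[, j] - min(matrix[, j]) + 1)
      rule[j] <- "shift_log"
    }
  }
  attr(out, "log_transform") <- rule
  out
}

#' Write a descriptor matrix as a tab-separated table
#'
#' @param matrix Descriptor matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a descriptor matrix written by [write_descriptors()]
#'
#' @param path Input path.
#' @return Numeric matrix with ids as row names.
#' @export
read_descriptors <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write fingerprints as id + 166-character 0/1 strings
#'
#' @param fps Fingerprint matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  strings <- apply(unclass(fps), 1, paste, collapse = "")
  utils::write.table(data.frame(id = rownames(fps), bits = strings),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints written by [write_fingerprints()]
#'
#' @param path Input path.
#' @return Fingerprint matrix of class `maccs_fps`.
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  bits <- vapply(df$bits, function(b) {
    as.integer(strsplit(b, "", fixed = TRUE)[[1]])
  }, integer(166))
  m <- t(bits)
  dimnames(m) <- list(df$id, paste0("key", seq_len(166)))
  class(m) <- c("maccs_fps", class(m))
  m
}
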