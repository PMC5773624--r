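#' @keywords internal
backend_script <- function() {
  path <- system.file("python", "chem_backend.py", package = "ahrscreen")
  if (!nzchar(path) || !file.exists(path)) {
    stop("bundled chemistry helper 'chem_backend.py' not found", call. = FALSE)
  }
  path
}

#' Locate the Python interpreter used for chemistry primitives
#'
#' Structure standardization, 2D descriptors, and MACCS fingerprints are
#' computed by RDKit through a bundled helper script. The interpreter is
#' taken from `options(ahrscreen.python = ...)`, then the `AHRSCREEN_PYTHON`
#' environment variable, then `python` on the `PATH`.
#'
#' @return Path to the Python executable.
#' @export
python_binary <- function() {
  opt <- getOption("ahrscreen.python", "")
  if (nzchar(opt)) return(opt)
  env <- Sys.getenv("AHRSCREEN_PYTHON", "")
  if (nzchar(env)) return(env)
  "python"
}

# Run one backend mode over a two-column (id, smiles) table; returns the
# output read as a data.frame. Extra arguments are passed verbatim.
#' @keywords internal
run_backend <- function(mode, ids = NULL, smiles = NULL, args = character(),
                        infile = NULL) {
  if (is.null(infile)) {
    infile <- tempfile(fileext = ".tsv")
    on.exit(unlink(infile), add = TRUE)
    writeLines(paste(ids, smiles, sep = "\t"), infile)
  }
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(outfile), add = TRUE)
  full <- c(backend_script(), mode, "--in", infile, "--out", outfile, args)
  res <- suppressWarnings(system2(python_binary(), shQuote(full),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0) {
    stop("chemistry backend failed: ", paste(res, collapse = "\n"),
         call. = FALSE)
  }
  utils::read.delim(outfile, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    quote = "", comment.char = "")
}
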