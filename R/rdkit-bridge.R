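# Subprocess bridge to the RDKit Python library.
#
# All chemistry (SMILES parsing, fingerprint generation with bit->atom
# info, SMARTS matching, depiction) is executed by inst/python/
# rdkit_bridge.py in batch: one process launch per call, JSON in/out via
# temp files. Callers are expected to batch many molecules per call.

bridgeScript <- function() {
  p <- system.file("python", "rdkit_bridge.py", package = "ToxConsensus")
  if (!nzchar(p)) stop("rdkit_bridge.py not found in installed package")
  p
}

pythonBinary <- function() {
  p <- Sys.getenv("TOXCONSENSUS_PYTHON", "")
  if (nzchar(p)) return(p)
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' executable on PATH; RDKit is required")
  unname(p)
}

#' Is the RDKit Python bridge available?
#'
#' The package delegates molecule handling to the RDKit Python library
#' through a subprocess. This checks that a `python` with importable
#' `rdkit` is on the PATH (override with the `TOXCONSENSUS_PYTHON`
#' environment variable).
#'
#' @return `TRUE` or `FALSE`.
#' @export
rdkitAvailable <- function() {
  ok <- .bridgeState$available
  if (!is.na(ok)) return(ok)
  py <- tryCatch(pythonBinary(), error = function(e) NULL)
  if (is.null(py)) {
    .bridgeState$available <- FALSE
    return(FALSE)
  }
  st <- suppressWarnings(system2(py, c("-c", shQuote("import rdkit")),
                                 stdout = FALSE, stderr = FALSE))
  .bridgeState$available <- identical(st, 0L)
  .bridgeState$available
}

.bridgeState <- new.env(parent = emptyenv())
.bridgeState$available <- NA

#' @keywords internal
rdkitCall <- function(task, payload) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  st <- suppressWarnings(
    system2(pythonBinary(), c(bridgeScript(), task, fin, fout),
            stdout = TRUE, stderr = TRUE))
  if (!file.exists(fout))
    stop("RDKit bridge failed (task '", task, "'): ",
         paste(st, collapse = "\n"))
  res <- jsonlite::read_json(fout)
  if (!isTRUE(res$ok))
    stop("RDKit bridge error (task '", task, "'): ", res$error)
  res$result
}
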