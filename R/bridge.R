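#' @keywords internal
"_PACKAGE"

# Persistent RDKit worker: lifecycle and low-level call plumbing. The worker
# process is started lazily on first use, lives for the R session, and exits
# on socket EOF. One worker per session; all chemistry calls are batched
# through it.
.bridge <- new.env(parent = emptyenv())

bridge_script <- function() {
  path <- system.file("python", "chem_worker.py", package = "fragopt")
  if (!nzchar(path)) {
    # during devtools::load_all() the inst/ prefix is still present
    path <- system.file("inst", "python", "chem_worker.py", package = "fragopt")
  }
  if (!nzchar(path)) stop("chem_worker.py not found in the installed package")
  path
}

bridge_start <- function(timeout = 30) {
  python <- Sys.which("python")
  if (!nzchar(python)) stop("no 'python' executable on the PATH; RDKit is required")
  port_file <- tempfile("fragopt-port-")
  log_file <- tempfile("fragopt-worker-", fileext = ".log")
  system2(python, c(shQuote(bridge_script()), shQuote(port_file)),
          stdout = log_file, stderr = log_file, wait = FALSE)
  t0 <- Sys.time()
  while (!file.exists(port_file)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > timeout) {
      stop("chemistry worker failed to start; log:\n",
           paste(readLines(log_file, warn = FALSE), collapse = "\n"))
    }
    Sys.sleep(0.05)
  }
  port <- as.integer(readLines(port_file, warn = FALSE)[1])
  con <- socketConnection("127.0.0.1", port = port, blocking = TRUE,
                          open = "r+b", timeout = 600)
  .bridge$con <- con
  .bridge$log <- log_file
  invisible(con)
}

bridge_connection <- function() {
  con <- .bridge$con
  if (is.null(con) || !isOpen(con)) bridge_start() else con
  .bridge$con
}

bridge_stop <- function() {
  con <- .bridge$con
  if (!is.null(con) && isOpen(con)) {
    try(writeLines('{"op": "shutdown"}', con), silent = TRUE)
    try(close(con), silent = TRUE)
  }
  .bridge$con <- NULL
  invisible(NULL)
}

bridge_call <- function(op, payload = list()) {
  con <- bridge_connection()
  payload$op <- op
  line <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA)
  ok <- try({
    writeLines(line, con)
    resp_line <- readLines(con, n = 1L)
  }, silent = TRUE)
  if (inherits(ok, "try-error") || length(resp_line) == 0L) {
    # worker died; restart once and retry
    bridge_stop()
    con <- bridge_connection()
    writeLines(line, con)
    resp_line <- readLines(con, n = 1L)
  }
  resp <- jsonlite::fromJSON(resp_line, simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) {
    stop("chemistry worker error [", op, "]: ", resp$error, call. = FALSE)
  }
  resp$result
}

.onUnload <- function(libpath) {
  bridge_stop()
}

# ------------------------------------------------------------------ wrappers

chem_null_to_na <- function(x) {
  vapply(x, function(v) if (is.null(v)) NA_real_ else as.numeric(v), numeric(1))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit's canonical form. Unparsable inputs map to
#' `NA`. Canonicalization is idempotent: `canonical_smiles(canonical_smiles(s))`
#' equals `canonical_smiles(s)`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  res <- bridge_call("canon", list(smiles = as.list(as.character(smiles))))
  vapply(res, function(v) if (is.null(v)) NA_character_ else v, character(1))
}

chem_descriptors <- function(smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(smiles = character(0)))
  }
  res <- bridge_call("descriptors", list(smiles = as.list(as.character(smiles))))
  cols <- c("mw", "logp", "tpsa", "hba", "hbd", "rotb", "arom_rings", "rings",
            "heavy_atoms", "frac_csp3", "largest_ring", "basic_n", "arom_n",
            "sa_raw")
  out <- as.data.frame(lapply(cols, function(cl) {
    vapply(res, function(r) if (is.null(r)) NA_real_ else as.numeric(r[[cl]]),
           numeric(1))
  }))
  names(out) <- cols
  cbind(data.frame(smiles = as.character(smiles), stringsAsFactors = FALSE), out)
}

chem_substructure <- function(smiles, smarts) {
  if (length(smiles) == 0L) return(logical(0))
  res <- bridge_call("substructure",
                     list(smiles = as.list(as.character(smiles)), smarts = smarts))
  vapply(res, function(v) if (is.null(v)) NA else isTRUE(v), logical(1))
}
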