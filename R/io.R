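# File I/O and run configuration: SMILES/CSV molecule files, YAML run
# configs with defaults materialized, and run artifact writing.

#' Read molecules from a file
#'
#' Supports one-SMILES-per-line text (`.smi`, `#` comments and blank lines
#' ignored; an optional second whitespace-separated token is the id) and CSV
#' with a `smiles` column (optional `id` column). Invalid SMILES are skipped
#' with a warning; molecules are canonicalized and de-duplicated.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"smi"` or `"csv"`.
#' @return a [molecule_library()]; the number of skipped lines is in
#'   `attr(, "n_skipped")`.
#' @export
read_molecules <- function(path, format = c("auto", "smi", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read molecule file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "smi"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"smiles" %in% names(df)) stop("CSV file lacks a 'smiles' column: ", path)
    smiles <- df$smiles
    ids <- if ("id" %in% names(df)) df$id else NULL
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) {
      warning("no molecules in ", path)
      return(molecule_library(character(0), name = basename(path)))
    }
    tokens <- strsplit(lines, "\\s+")
    smiles <- vapply(tokens, `[[`, character(1), 1)
    ids <- vapply(tokens, function(t) if (length(t) > 1) t[2] else NA_character_,
                  character(1))
    if (all(is.na(ids))) ids <- NULL
  }
  molecule_library(smiles, ids = ids, name = basename(path))
}

#' Write molecules to a file
#'
#' @param lib a [molecule_library()] or character vector of SMILES.
#' @param path output file; `.csv` writes all columns, anything else writes
#'   `smiles id` lines.
#' @export
write_molecules <- function(lib, path) {
  if (is.character(lib)) lib <- molecule_library(lib)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(as.data.frame(lib), path, row.names = FALSE)
  } else {
    writeLines(paste(lib$smiles, lib$id), path)
  }
  invisible(path)
}

config_defaults <- function() {
  list(task = "task1", objectives = NULL, success = NULL,
       delta = NULL, eta = NULL,
       M = 20, N = 20, k = 10, Itermax0 = 50, p = 0.05, q = 0.05,
       E = 5, gen_n = 10, seed = 1, generator = "recombine",
       thresholds = NULL, library = NULL, lead = NULL, output = "results")
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are an error; defaults are materialized so the echoed config
#' is complete.
#'
#' @param path YAML file.
#' @return named list with every config key resolved.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- config_defaults()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  for (key in c("library", "lead")) {
    if (is.null(out[[key]])) {
      stop("missing required config key: ", key, call. = FALSE)
    }
  }
  out
}

run_config_to_task <- function(cfg) {
  if (!is.null(cfg$objectives)) {
    task_config(objectives = unlist(cfg$objectives),
                success = unlist(cfg$success),
                delta = if (!is.null(cfg$delta)) unlist(cfg$delta),
                eta = if (!is.null(cfg$eta)) unlist(cfg$eta),
                M = cfg$M, N = cfg$N, k = cfg$k, Itermax0 = cfg$Itermax0,
                p = cfg$p, q = cfg$q, E = cfg$E, gen_n = cfg$gen_n,
                seed = cfg$seed)
  } else {
    td <- task_definition(cfg$task)
    task_config(objectives = names(td$success), success = td$success,
                delta = if (!is.null(cfg$delta)) unlist(cfg$delta),
                eta = if (!is.null(cfg$eta)) unlist(cfg$eta),
                M = cfg$M, N = cfg$N, k = cfg$k, Itermax0 = cfg$Itermax0,
                p = cfg$p, q = cfg$q, E = cfg$E, gen_n = cfg$gen_n,
                seed = cfg$seed)
  }
}

#' Write the artifacts of an optimization run
#'
#' Writes `final_molecules.csv` (SMILES + objective columns), `samples.csv`,
#' `successes.csv`, `history.json` (per-iteration records plus the space
#' histories) and `config.yaml` (the fully resolved configuration, the run's
#' audit trail) into a directory.
#'
#' @param result an `optimization_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$population, file.path(dir, "final_molecules.csv"),
                   row.names = FALSE)
  utils::write.csv(result$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(result$successes, file.path(dir, "successes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(lead = result$lead, success = result$success,
         history = result$history,
         size_history = result$space$size_history,
         property_history = result$space$property_history),
    file.path(dir, "history.json"), auto_unbox = TRUE, digits = NA,
    null = "null", dataframe = "rows")
  cfg <- result$config
  yaml::write_yaml(lapply(unclass(cfg), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  }), file.path(dir, "config.yaml"))
  invisible(dir)
}
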