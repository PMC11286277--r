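# Property scoring. QED, penalized logP and SA are computed by the RDKit
# worker (QED and Crippen logP as RDKit defines them; SA is the Ertl
# synthetic-accessibility score, reported here normalized to higher-is-better
# as (10 - raw)/9 so it lives on [0, 1] like the other bounded objectives).
# Penalized logP is logP - SA_raw - max(0, largest_ring - 6). SIM is the
# Morgan (radius 2, 2048 bit) Tanimoto similarity to the lead.
#
# DRD2 and GSK3B are *synthetic surrogates*: deterministic, smooth functions
# of cheap descriptors squashed to (0, 1). They stand behind the same scorer
# interface a trained activity model would use, so the whole pipeline can be
# exercised and a real predictor dropped in via register_scorer(); their
# values have no pharmacological meaning.

.scorers <- new.env(parent = emptyenv())

BUILTIN_BRIDGE_PROPS <- c("QED", "PLogP", "PLogP_imp", "SA", "SIM", "LogP")

#' Register a property scorer
#'
#' Scorers are keyed by property name and score batches of molecules. All
#' objectives are maximized; `range` is used to clip decaying sample
#' thresholds at the property's domain minimum.
#'
#' @param name property name (the column name in score tables).
#' @param fn function `(smiles, lead)` returning a numeric vector of scores,
#'   one per element of `smiles`.
#' @param range numeric length-2 domain `(min, max)`; may be infinite.
#' @param description one-line description.
#' @param overwrite replace an existing scorer of the same name.
#' @export
register_scorer <- function(name, fn, range = c(-Inf, Inf),
                            description = "", overwrite = FALSE) {
  if (!overwrite && !is.null(.scorers[[name]])) {
    stop("scorer already registered: ", name, call. = FALSE)
  }
  .scorers[[name]] <- list(fn = fn, range = range, description = description)
  invisible(name)
}

#' List registered property scorers
#'
#' @return data frame of scorer names, ranges and descriptions.
#' @export
list_scorers <- function() {
  nms <- sort(ls(.scorers))
  data.frame(
    property = nms,
    min = vapply(nms, function(n) .scorers[[n]]$range[1], numeric(1)),
    max = vapply(nms, function(n) .scorers[[n]]$range[2], numeric(1)),
    description = vapply(nms, function(n) .scorers[[n]]$description, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

scorer_entry <- function(name) {
  e <- .scorers[[name]]
  if (is.null(e)) {
    stop("no scorer registered for property '", name,
         "'; see list_scorers()", call. = FALSE)
  }
  e
}

#' Domain range of a property
#'
#' @param name registered property name.
#' @return numeric length-2 `(min, max)`.
#' @export
property_range <- function(name) scorer_entry(name)$range

surrogate_drd2 <- function(smiles, lead = NULL) {
  d <- chem_descriptors(smiles)
  stats::plogis(0.9 * d$arom_rings + 1.1 * d$basic_n -
                  abs(d$mw - 350) / 120 - 1.8)
}

surrogate_gsk3b <- function(smiles, lead = NULL) {
  d <- chem_descriptors(smiles)
  stats::plogis(0.8 * d$arom_n + 0.45 * d$hbd + 0.4 * d$arom_rings +
                  1.2 * d$frac_csp3 - d$mw / 250 - 0.6)
}

register_builtin_scorers <- function() {
  bridge_scorer <- function(prop) {
    function(smiles, lead = NULL) score_bridge(smiles, lead, prop)[[prop]]
  }
  add <- function(name, fn, range, desc) {
    if (is.null(.scorers[[name]])) register_scorer(name, fn, range, desc)
  }
  add("QED", bridge_scorer("QED"), c(0, 1), "quantitative estimate of drug-likeness")
  add("PLogP", bridge_scorer("PLogP"), c(-Inf, Inf),
      "penalized logP: logP - SA_raw - oversized-ring penalty")
  add("PLogP_imp", bridge_scorer("PLogP_imp"), c(-Inf, Inf),
      "penalized logP improvement over the lead")
  add("SA", bridge_scorer("SA"), c(0, 1),
      "synthetic accessibility, normalized higher-is-better (10 - raw)/9")
  add("SIM", bridge_scorer("SIM"), c(0, 1),
      "Morgan fingerprint Tanimoto similarity to the lead")
  add("LogP", bridge_scorer("LogP"), c(-Inf, Inf), "Crippen logP")
  add("DRD2", surrogate_drd2, c(0, 1),
      "synthetic descriptor-based surrogate for DRD2 activity (not a trained model)")
  add("GSK3B", surrogate_gsk3b, c(0, 1),
      "synthetic descriptor-based surrogate for GSK3B inhibition (not a trained model)")
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_scorers()
}

# One bridge round-trip for any subset of the RDKit-backed properties.
score_bridge <- function(smiles, lead, properties) {
  res <- bridge_call("score", list(smiles = as.list(as.character(smiles)),
                                   lead = lead,
                                   properties = as.list(properties)))
  out <- as.data.frame(lapply(properties, function(p) {
    vapply(res, function(r) if (is.null(r)) NA_real_ else as.numeric(r[[p]]),
           numeric(1))
  }))
  names(out) <- properties
  out
}

#' Score molecules on named properties
#'
#' Looks each property up in the scorer registry; RDKit-backed properties are
#' computed in a single worker round-trip. Scores are deterministic.
#'
#' @param smiles character vector of molecule SMILES.
#' @param lead lead molecule SMILES (required by `SIM` and `PLogP_imp`).
#' @param properties character vector of registered property names.
#' @return data frame with one column per property, rows aligned to `smiles`.
#' @export
score_molecules <- function(smiles, lead = NULL,
                            properties = c("QED", "SIM")) {
  for (p in properties) scorer_entry(p)
  out <- data.frame(row.names = seq_along(smiles))
  builtin <- intersect(properties, BUILTIN_BRIDGE_PROPS)
  if (length(builtin)) {
    out <- cbind(out, score_bridge(smiles, lead, builtin))
  }
  for (p in setdiff(properties, builtin)) {
    out[[p]] <- scorer_entry(p)$fn(smiles, lead)
  }
  out[, properties, drop = FALSE]
}

# ------------------------------------------------------------------ tasks

#' Built-in optimization task definitions
#'
#' Three standard multi-property tasks. Success requires every threshold to
#' be met (inclusive):
#' * Task I: `QED >= 0.85`, `PLogP_imp >= 3`, `SIM >= 0.3`.
#' * Task II: `QED >= 0.8`, `DRD2 >= 0.4`, `SIM >= 0.3`.
#' * Task III: `QED >= 0.7`, `GSK3B >= 0.4`, `SA >= 0.7`, `SIM >= 0.2`.
#'
#' @param name `"task1"`, `"task2"`, `"task3"`, or `"custom"` with explicit
#'   `success` thresholds.
#' @param success named numeric vector of minimum values (for custom tasks).
#' @return object of class `task_definition`: list with `name` and `success`.
#' @export
task_definition <- function(name = c("task1", "task2", "task3", "custom"),
                            success = NULL) {
  name <- match.arg(name)
  success <- switch(name,
    task1 = c(QED = 0.85, PLogP_imp = 3, SIM = 0.3),
    task2 = c(QED = 0.8, DRD2 = 0.4, SIM = 0.3),
    task3 = c(QED = 0.7, GSK3B = 0.4, SA = 0.7, SIM = 0.2),
    custom = {
      if (is.null(success) || is.null(names(success))) {
        stop("a custom task needs a named 'success' threshold vector")
      }
      success
    })
  structure(list(name = name, success = success), class = "task_definition")
}

#' Does an objective vector satisfy a task?
#'
#' @param values named numeric vector (or one-row data frame) of property
#'   values.
#' @param task a [task_definition()].
#' @return `TRUE` iff every threshold is met (inclusive `>=`).
#' @export
is_success <- function(values, task) {
  if (is.data.frame(values)) values <- unlist(values[1, , drop = TRUE])
  needed <- names(task$success)
  missing <- setdiff(needed, names(values))
  if (length(missing)) {
    stop("objective vector lacks propert", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  all(values[needed] >= task$success)
}

#' Success rate over a set of leads
#'
#' The percentage of lead molecules for which at least one output molecule
#' met every task threshold.
#'
#' @param outcomes logical vector (one per lead: did any output succeed?), or
#'   a list of optimization results carrying a logical `success` element.
#' @return percentage in `[0, 100]`.
#' @export
success_rate <- function(outcomes) {
  if (is.list(outcomes) && !is.logical(outcomes)) {
    outcomes <- vapply(outcomes, function(r) isTRUE(r$success), logical(1))
  }
  if (length(outcomes) == 0L) stop("success_rate needs at least one lead")
  100 * mean(outcomes)
}
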