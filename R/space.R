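# The molecule-specific search space: per-lead fragment library organized as
# a similarity tree, built from the reference molecules most similar to the
# lead and grown adaptively as the optimizer discovers new molecules.

#' Construct a molecule library
#'
#' A library is a data frame of unique canonical molecules with optional
#' cached property columns.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers (defaults to `mol1`, `mol2`, ...).
#' @param name library label.
#' @return object of class `molecule_library` (a data frame with columns
#'   `id`, `smiles` plus any cached properties).
#' @export
molecule_library <- function(smiles, ids = NULL, name = "library") {
  canon <- canonical_smiles(smiles)
  bad <- is.na(canon)
  if (any(bad)) {
    warning(sum(bad), " invalid SMILES dropped from library '", name, "'")
  }
  canon <- canon[!bad]
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  ids <- ids[!bad]
  keep <- !duplicated(canon)
  lib <- data.frame(id = ids[keep], smiles = canon[keep],
                    stringsAsFactors = FALSE)
  attr(lib, "name") <- name
  attr(lib, "n_skipped") <- sum(bad)
  class(lib) <- c("molecule_library", class(lib))
  lib
}

#' Cache property values on a library
#'
#' @param lib a [molecule_library()].
#' @param properties registered property names to compute.
#' @param lead lead SMILES, needed by lead-relative properties.
#' @return the library with one cached column per property.
#' @export
add_properties <- function(lib, properties, lead = NULL) {
  vals <- score_molecules(lib$smiles, lead = lead, properties = properties)
  for (p in properties) lib[[p]] <- vals[[p]]
  lib
}

#' Filter a library by property thresholds
#'
#' Keeps molecules whose every listed property meets its minimum value (the
#' intermediate library of candidate donors). Properties not yet cached on
#' the library are computed first.
#'
#' @param lib a [molecule_library()].
#' @param thresholds named numeric vector, property -> minimum value. An
#'   empty vector returns the library unchanged.
#' @param lead lead SMILES for lead-relative properties.
#' @return the filtered `molecule_library`.
#' @export
build_intermediate_library <- function(lib, thresholds = numeric(0),
                                       lead = NULL) {
  if (length(thresholds) == 0L) return(lib)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("thresholds must be a named vector of property minima")
  }
  missing <- setdiff(names(thresholds), names(lib))
  if (length(missing)) lib <- add_properties(lib, missing, lead = lead)
  keep <- rep(TRUE, nrow(lib))
  for (p in names(thresholds)) keep <- keep & (lib[[p]] >= thresholds[[p]])
  out <- lib[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("no molecules survive the thresholds; the intermediate library is empty")
  }
  out
}

#' Select the molecules most similar to a lead
#'
#' Ranks a library by fingerprint Tanimoto similarity to the lead and keeps
#' the top `N` (all of the library if it is smaller). Ties keep library
#' order.
#'
#' @param lead lead molecule SMILES.
#' @param lib a [molecule_library()].
#' @param n number of molecules to keep.
#' @return the selected rows with a `SIM_lead` column, similarity-descending.
#' @export
select_top_n_similar <- function(lead, lib, n = 20) {
  stopifnot(n >= 1L)
  if (nrow(lib) == 0L) {
    stop("the library is empty; relax the intermediate-library thresholds")
  }
  sims <- fingerprint_similarity(lib$smiles, lead)
  ord <- order(-sims)  # stable: ties keep library order
  keep <- ord[seq_len(min(n, nrow(lib)))]
  out <- lib[keep, , drop = FALSE]
  out$SIM_lead <- sims[keep]
  out
}

space_mean_properties <- function(source_props) {
  if (is.null(source_props) || nrow(source_props) == 0L) return(NULL)
  colMeans(source_props[, setdiff(names(source_props), c("id", "smiles")),
                        drop = FALSE], na.rm = TRUE)
}

#' Build the molecule-specific search space
#'
#' Decomposes the `N` library molecules most similar to the lead, pools and
#' de-duplicates their fragments (the lead's own fragments are included so
#' the lead is always embeddable), and builds the similarity tree over the
#' pool.
#'
#' @param lead lead molecule SMILES.
#' @param lib a [molecule_library()] (already filtered, see
#'   [build_intermediate_library()]).
#' @param n how many similar molecules seed the space.
#' @param include_lead include the lead's own fragments (default `TRUE`).
#' @param properties optional property names whose per-source-molecule means
#'   are tracked as the property of the space.
#' @return object of class `molecule_space`: list with `lead`, `fragments`,
#'   `tree`, `source` (donor molecules), `size_history`, `property_history`.
#' @export
build_space <- function(lead, lib, n = 20, include_lead = TRUE,
                        properties = NULL) {
  lead <- canonical_smiles(lead)
  if (is.na(lead)) stop("invalid lead SMILES")
  donors <- select_top_n_similar(lead, lib, n)
  smiles <- donors$smiles
  if (include_lead && !(lead %in% smiles)) smiles <- c(lead, smiles)
  decs <- decompose_molecules(smiles, ids = smiles)
  frags <- dedupe_fragments(do.call(rbind, lapply(decs, `[[`, "fragments")))
  tree <- build_tree(frags)
  source <- data.frame(id = smiles, smiles = smiles, stringsAsFactors = FALSE)
  prop_hist <- NULL
  if (!is.null(properties)) {
    sp <- cbind(source, score_molecules(smiles, lead = lead, properties))
    source <- sp
    prop_hist <- cbind(data.frame(iteration = 0L),
                       as.data.frame(as.list(space_mean_properties(sp))))
  }
  structure(list(lead = lead, fragments = frags, tree = tree,
                 source = source, properties = properties,
                 size_history = data.frame(iteration = 0L,
                                           n_fragments = nrow(frags)),
                 property_history = prop_hist),
            class = "molecule_space")
}

#' Build a search space directly from molecules
#'
#' Lower-level constructor used when the donor set is already chosen (e.g.
#' toy spaces in examples and tests): no similarity ranking is performed.
#'
#' @param lead lead molecule SMILES.
#' @param molecules character vector of donor molecule SMILES.
#' @inheritParams build_space
#' @return a `molecule_space`.
#' @export
space_from_molecules <- function(lead, molecules, include_lead = TRUE,
                                 properties = NULL) {
  lib <- molecule_library(molecules)
  build_space(lead, lib, n = nrow(lib), include_lead = include_lead,
              properties = properties)
}

#' @export
print.molecule_space <- function(x, ...) {
  cat("Molecule-specific search space\n")
  cat("  lead:     ", x$lead, "\n")
  cat("  fragments:", nrow(x$fragments), "\n")
  cat("  tree:     ", x$tree$levels, "node levels, code length",
      x$tree$depth_code, "\n")
  cat("  history:  ", nrow(x$size_history), "snapshot(s), size",
      x$size_history$n_fragments[1], "->",
      utils::tail(x$size_history$n_fragments, 1), "\n")
  invisible(x)
}

#' Expand a search space with new molecules
#'
#' Decomposes the new molecules, unions their fragments into the space
#' (fragments are never removed) and rebuilds the similarity tree on the
#' enlarged set. Invalid molecules are skipped with a warning; an optional
#' filter predicate can reject molecules before expansion.
#'
#' @param space a `molecule_space`.
#' @param new_mols character vector of molecule SMILES.
#' @param iteration iteration index recorded in the histories.
#' @param filter optional predicate `function(smiles) logical` applied to the
#'   valid canonical molecules (default: accept all valid).
#' @return the expanded `molecule_space`.
#' @export
expand_space <- function(space, new_mols, iteration, filter = NULL) {
  canon <- canonical_smiles(new_mols)
  if (anyNA(canon)) {
    warning(sum(is.na(canon)), " invalid molecule(s) skipped during expansion")
    canon <- canon[!is.na(canon)]
  }
  canon <- setdiff(unique(canon), space$source$smiles)
  if (!is.null(filter) && length(canon)) canon <- canon[filter(canon)]
  if (length(canon)) {
    decs <- decompose_molecules(canon, ids = canon)
    frags <- dedupe_fragments(rbind(space$fragments,
                                    do.call(rbind, lapply(decs, `[[`, "fragments"))))
    if (nrow(frags) > nrow(space$fragments)) {
      space$fragments <- frags
      space$tree <- build_tree(frags)
    }
    newsrc <- data.frame(id = canon, smiles = canon, stringsAsFactors = FALSE)
    if (!is.null(space$properties)) {
      newsrc <- cbind(newsrc, score_molecules(canon, lead = space$lead,
                                              space$properties))
    }
    space$source <- rbind(space$source, newsrc)
  }
  space$size_history <- rbind(space$size_history,
                              data.frame(iteration = as.integer(iteration),
                                         n_fragments = nrow(space$fragments)))
  if (!is.null(space$properties)) {
    space$property_history <- rbind(
      space$property_history,
      cbind(data.frame(iteration = as.integer(iteration)),
            as.data.frame(as.list(space_mean_properties(space$source)))))
  }
  space
}

#' Growth of a search space
#'
#' Percentage growth of the fragment count from the first to the latest
#' history snapshot: `100 * (final - initial) / initial`.
#'
#' @param space a `molecule_space`, or a numeric vector of sizes (at least
#'   initial and final).
#' @return growth percentage.
#' @export
space_growth_percent <- function(space) {
  sizes <- if (inherits(space, "molecule_space")) {
    space$size_history$n_fragments
  } else {
    as.numeric(space)
  }
  if (length(sizes) < 2L) stop("need at least two size snapshots")
  if (sizes[1] == 0) stop("initial size is 0; growth is undefined")
  100 * (sizes[length(sizes)] - sizes[1]) / sizes[1]
}

#' Serialize a search space to plain-text files
#'
#' Writes `<stem>_fragments.smi` (fragment SMILES), `<stem>_tree.nwk`
#' (Newick-like tree) and `<stem>_history.json` (size and property
#' histories).
#'
#' @param space a `molecule_space`.
#' @param stem output path stem.
#' @return the three file paths, invisibly.
#' @export
write_space <- function(space, stem) {
  frag_path <- paste0(stem, "_fragments.smi")
  writeLines(space$fragments$smiles, frag_path)
  tree_path <- paste0(stem, "_tree.nwk")
  write_tree_newick(space$tree, tree_path)
  hist_path <- paste0(stem, "_history.json")
  jsonlite::write_json(list(lead = space$lead,
                            size_history = space$size_history,
                            property_history = space$property_history),
                       hist_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(frag_path, tree_path, hist_path))
}
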