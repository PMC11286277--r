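# Fragment chemistry: decomposition of molecules into attachment-marked
# fragments and reassembly. The cutting rule severs every acyclic single bond
# with at least one endpoint in a ring (exocyclic bonds, plus direct
# ring-ring linker bonds such as the biphenyl bond). Each cut leaves one
# attachment marker (a dummy atom) on each side. Markers are isotope-indexed
# [1*], [2*], ... per fragment, numbered by canonical atom rank, so that
# topology records can name attachment slots unambiguously while identical
# fragments from different sources still share one canonical SMILES.

#' Construct a fragment record
#'
#' @param smiles fragment SMILES; attachment points are dummy atoms
#'   (`*`, `[1*]`, `[2*]`, ...).
#' @param n_attachments number of attachment markers; counted from `smiles`
#'   when omitted.
#' @param source optional identifier of the molecule the fragment came from.
#' @return a one-row data frame with columns `smiles`, `n_attachments`,
#'   `source`.
#' @export
fragment <- function(smiles, n_attachments = NULL, source = NA_character_) {
  if (is.null(n_attachments)) n_attachments <- count_attachments(smiles)
  data.frame(smiles = smiles, n_attachments = as.integer(n_attachments),
             source = source, stringsAsFactors = FALSE)
}

#' Count attachment markers in a fragment SMILES
#'
#' @param smiles character vector of fragment SMILES.
#' @return integer vector of marker counts.
#' @export
count_attachments <- function(smiles) {
  # dummy atoms appear as "*" (possibly isotope-labelled "[12*]")
  vapply(gregexpr("\\*", smiles), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
}

#' Decompose molecules into ring-anchored fragments
#'
#' Cuts every acyclic single bond incident to a ring atom; each cut is
#' recorded in a topology table so the molecule can be reassembled exactly.
#' Molecules without ring atoms come back as a single fragment with zero
#' attachment points.
#'
#' @param smiles a single SMILES string.
#' @param id optional molecule identifier carried into fragment provenance.
#' @return an object of class `decomposition`: a list with `smiles` (canonical
#'   input), `fragments` (data frame of `smiles`, `n_attachments`, `source`),
#'   `topology` (data frame with columns `frag_i`, `slot_i`, `frag_j`,
#'   `slot_j`, one row per cut bond), `r` (fragment count) and `t` (total
#'   attachment points).
#' @export
decompose_molecule <- function(smiles, id = NA_character_) {
  decompose_molecules(smiles, ids = id)[[1]]
}

#' Decompose a batch of molecules
#'
#' Vectorized form of [decompose_molecule()]; one worker round-trip for the
#' whole batch.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional identifiers, recycled to `length(smiles)`.
#' @return list of `decomposition` objects.
#' @export
decompose_molecules <- function(smiles, ids = NULL) {
  stopifnot(length(smiles) >= 1L)
  if (is.null(ids)) ids <- rep(NA_character_, length(smiles))
  ids <- rep_len(ids, length(smiles))
  res <- bridge_call("decompose", list(smiles = as.list(as.character(smiles))))
  canon <- canonical_smiles(smiles)
  lapply(seq_along(res), function(i) {
    r <- res[[i]]
    if (!is.null(r$error)) {
      stop("decompose_molecule: ", r$error, call. = FALSE)
    }
    frags <- do.call(rbind, lapply(r$fragments, function(f) {
      fragment(f$smiles, f$n_attachments, source = ids[i])
    }))
    topo <- topology_frame(r$topology)
    structure(list(smiles = canon[i], id = ids[i], fragments = frags,
                   topology = topo, r = nrow(frags),
                   t = sum(frags$n_attachments)),
              class = "decomposition")
  })
}

topology_frame <- function(topo_list) {
  if (length(topo_list) == 0L) {
    return(data.frame(frag_i = integer(0), slot_i = integer(0),
                      frag_j = integer(0), slot_j = integer(0)))
  }
  m <- do.call(rbind, lapply(topo_list, function(row) as.integer(unlist(row))))
  out <- as.data.frame(m)
  names(out) <- c("frag_i", "slot_i", "frag_j", "slot_j")
  out
}

#' @export
print.decomposition <- function(x, ...) {
  cat("Decomposition of", x$smiles, "\n")
  cat("  ", x$r, "fragment(s),", x$t, "attachment point(s)\n")
  for (i in seq_len(nrow(x$fragments))) {
    cat(sprintf("  [%d] %s (%d attachment(s))\n", i, x$fragments$smiles[i],
                x$fragments$n_attachments[i]))
  }
  invisible(x)
}

#' Reassemble fragments into a molecule
#'
#' Joins attachment markers pairwise according to a topology table, resolving
#' each pair into a single bond. Raises an error rather than returning an
#' invalid structure.
#'
#' @param fragments character vector of fragment SMILES, or the `fragments`
#'   data frame of a [decompose_molecule()] result, or a `decomposition`
#'   (whose own topology is then the default plan).
#' @param topology data frame (or 4-column matrix) of
#'   `frag_i, slot_i, frag_j, slot_j` rows; fragment indices are positions in
#'   `fragments`, slots are the marker indices within each fragment.
#' @return canonical SMILES of the assembled molecule.
#' @export
assemble_fragments <- function(fragments, topology = NULL) {
  if (inherits(fragments, "decomposition")) {
    if (is.null(topology)) topology <- fragments$topology
    fragments <- fragments$fragments$smiles
  } else if (is.data.frame(fragments)) {
    fragments <- fragments$smiles
  }
  res <- assemble_batch(list(list(fragments = fragments, topology = topology)))
  if (is.na(res$smiles[1])) {
    stop("assemble_fragments: ", res$error[1], call. = FALSE)
  }
  res$smiles[1]
}

# Batch assembly with failures returned as values (NA + message), for the
# optimizer's decode path where invalid products are expected occasionally.
assemble_batch <- function(jobs) {
  jobs <- lapply(jobs, function(j) {
    topo <- j$topology
    if (is.null(topo) || NROW(topo) == 0L) {
      topo_list <- list()
    } else {
      topo <- as.matrix(as.data.frame(topo))
      topo_list <- lapply(seq_len(nrow(topo)), function(k) as.integer(topo[k, ]))
    }
    list(fragments = as.list(as.character(j$fragments)), topology = topo_list)
  })
  res <- bridge_call("assemble", list(jobs = jobs))
  data.frame(
    smiles = vapply(res, function(r) {
      if (is.null(r$smiles)) NA_character_ else r$smiles
    }, character(1)),
    error = vapply(res, function(r) {
      if (is.null(r$error)) NA_character_ else r$error
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

# De-duplicate fragment rows by canonical marker-containing SMILES, keeping
# first occurrence (stable order).
dedupe_fragments <- function(frags) {
  frags[!duplicated(frags$smiles), , drop = FALSE]
}
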