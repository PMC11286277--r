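# Fragment and molecule similarity. Fragment similarity is the maximum of a
# structural term (maximum-common-substructure Tanimoto over heavy atoms) and
# a string term (normalized Levenshtein similarity of canonical fragment
# SMILES). The string Levenshtein *distance* is normalized to a similarity,
# 1 - d/max(len), so both terms live on [0, 1] and their max is meaningful.

#' Maximum-common-substructure Tanimoto similarity
#'
#' `|MCS| / (|f1| + |f2| - |MCS|)` counted over heavy atoms. Attachment
#' markers are stripped before matching; atoms must match by element, bonds by
#' order, and ring bonds only match ring bonds.
#'
#' @param f1,f2 fragment SMILES (markers allowed) or plain molecule SMILES.
#' @param timeout MCS search budget in seconds per pair; on timeout the
#'   best-so-far bound is returned with a warning.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto_mcs <- function(f1, f2, timeout = 1) {
  tanimoto_mcs_pairs(cbind(f1, f2), timeout = timeout)
}

# Vectorized over a 2-column matrix/data.frame of SMILES pairs.
tanimoto_mcs_pairs <- function(pairs, timeout = 1) {
  pairs <- unname(as.matrix(pairs))
  res <- bridge_call("mcs_tanimoto", list(
    pairs = lapply(seq_len(nrow(pairs)), function(i) as.list(unname(pairs[i, ]))),
    timeout = timeout))
  out <- chem_null_to_na(res)
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("tanimoto_mcs: unparsable SMILES in pair (",
         pairs[bad, 1], ", ", pairs[bad, 2], ")", call. = FALSE)
  }
  out
}

#' Normalized Levenshtein similarity of two strings
#'
#' `1 - edit_distance(s1, s2) / max(nchar(s1), nchar(s2))`; defined as 1 when
#' both strings are empty. Fragments are compared by their canonical
#' marker-containing SMILES.
#'
#' @param s1,s2 character vectors (recycled).
#' @return similarity in `[0, 1]`.
#' @export
levenshtein_similarity <- function(s1, s2) {
  n <- max(length(s1), length(s2))
  s1 <- rep_len(as.character(s1), n)
  s2 <- rep_len(as.character(s2), n)
  d <- vapply(seq_len(n), function(i) {
    utils::adist(s1[i], s2[i])[1, 1]
  }, numeric(1))
  len <- pmax(nchar(s1), nchar(s2))
  ifelse(len == 0, 1, 1 - d / len)
}

#' Pairwise fragment similarity
#'
#' The maximum of [tanimoto_mcs()] and [levenshtein_similarity()] for a pair
#' of fragments.
#'
#' @inheritParams tanimoto_mcs
#' @return similarity in `[0, 1]`.
#' @export
pair_similarity <- function(f1, f2, timeout = 1) {
  pmax(tanimoto_mcs(f1, f2, timeout = timeout), levenshtein_similarity(f1, f2))
}

#' Build the fragment similarity matrix
#'
#' Symmetric matrix of [pair_similarity()] values over a fragment set, with
#' unit diagonal. Deterministic for a fixed input order.
#'
#' @param frags character vector of fragment SMILES, or a fragment data frame
#'   with a `smiles` column.
#' @param timeout per-pair MCS budget in seconds.
#' @return a `similarity_matrix`: a numeric matrix with `labels` dimnames.
#' @export
build_similarity_matrix <- function(frags, timeout = 1) {
  if (is.data.frame(frags)) frags <- frags$smiles
  n <- length(frags)
  stopifnot(n >= 1L)
  m <- diag(1, n)
  if (n > 1L) {
    idx <- which(upper.tri(m), arr.ind = TRUE)
    pairs <- cbind(frags[idx[, 1]], frags[idx[, 2]])
    tan <- tanimoto_mcs_pairs(pairs, timeout = timeout)
    lev <- levenshtein_similarity(pairs[, 1], pairs[, 2])
    vals <- pmax(tan, lev)
    m[idx] <- vals
    m[cbind(idx[, 2], idx[, 1])] <- vals
  }
  dimnames(m) <- list(frags, frags)
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Fragment similarity matrix (", nrow(x), " x ", ncol(x), ")\n", sep = "")
  print(round(unclass(x), 3), ...)
  invisible(x)
}

#' Fingerprint Tanimoto similarity between molecules
#'
#' Tanimoto similarity on circular (radius-2, 2048-bit) fingerprints; the SIM
#' metric used to keep optimized molecules close to the lead.
#'
#' @param m1,m2 molecule SMILES. `m1` may be a vector; `m2` is a single
#'   reference unless it has the same length as `m1`.
#' @return similarity values in `[0, 1]`.
#' @export
fingerprint_similarity <- function(m1, m2) {
  if (length(m2) == 1L && length(m1) >= 1L) {
    res <- bridge_call("fp_tanimoto",
                       list(smiles = as.list(as.character(m1)), ref = m2))
  } else {
    n <- max(length(m1), length(m2))
    m1 <- rep_len(m1, n); m2 <- rep_len(m2, n)
    res <- bridge_call("fp_tanimoto", list(
      pairs = lapply(seq_len(n), function(i) list(m1[i], m2[i]))))
  }
  out <- chem_null_to_na(res)
  if (anyNA(out)) stop("fingerprint_similarity: unparsable SMILES", call. = FALSE)
  out
}

#' Export a similarity matrix to CSV
#'
#' @param m a `similarity_matrix`.
#' @param path output file path.
#' @export
write_similarity_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
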