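# The fragment similarity tree: a binary tree over a fragment set built by
# greedy most-similar pairing. Step 1 pairs fragments two at a time into
# single-level trees (odd leftover: a tree with only a left leaf); Step 2
# repeatedly pairs the two most similar trees within a round, tree similarity
# being the maximum cross-tree fragment similarity, until one tree remains.
# Every internal node is virtual; fragments sit only at leaves. Root-to-leaf
# paths (left = 0, right = 1) give each fragment a binary path code of length
# at most d = ceiling(log2 n); shorter codes are right-padded with 0.
#
# Tie-breaking (the procedure is otherwise underdetermined): among equal
# similarities the pair with the smallest (row, column) index wins; within a
# pair the lower-index item goes left; when two subtrees merge, the one
# holding the lower-index fragment of the best cross pair goes left.

tree_leaf <- function(i) list(leaf = TRUE, frag = i)
tree_node <- function(left, right = NULL) list(leaf = FALSE, left = left, right = right)

node_frags <- function(node) {
  if (is.null(node)) return(integer(0))
  if (isTRUE(node$leaf)) return(node$frag)
  c(node_frags(node$left), node_frags(node$right))
}

# Greedy argmax pairing over a similarity matrix restricted to `avail`
# indices. Returns list(pairs = 2-col matrix in extraction order,
# leftover = index or NA).
greedy_pairing <- function(sim, avail = seq_len(nrow(sim))) {
  pairs <- matrix(integer(0), ncol = 2)
  while (length(avail) >= 2L) {
    sub <- sim[avail, avail, drop = FALSE]
    diag(sub) <- -Inf
    best <- max(sub)
    hits <- which(sub == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- avail[hits[1, 1]]; j <- avail[hits[1, 2]]
    pairs <- rbind(pairs, c(i, j))
    avail <- setdiff(avail, c(i, j))
  }
  list(pairs = pairs, leftover = if (length(avail)) avail else NA_integer_)
}

#' Build a fragment similarity tree
#'
#' Constructs the binary similarity tree by greedy most-similar pairing: first
#' among fragments, then among the resulting subtrees (tree-to-tree similarity
#' is the maximum fragment similarity across the two leaf sets), one pairing
#' round at a time until a single tree remains.
#'
#' @param frags character vector of fragment SMILES or a fragment data frame.
#' @param sim similarity matrix from [build_similarity_matrix()]; computed on
#'   the fly when `NULL`.
#' @return an object of class `fragment_tree` with elements `root` (nested
#'   node list), `fragments`, `n_fragments`, `depth_code` (path-code length
#'   `d = ceiling(log2 n)`, 1 when `n = 1`), `levels` (node levels counting
#'   the root as level 1), `leaves` (data frame of `smiles`, `code`,
#'   `n_attachments`), `step1_pairs`, and the similarity matrix `sim`.
#' @export
build_tree <- function(frags, sim = NULL) {
  if (!is.data.frame(frags)) {
    frags <- do.call(rbind, lapply(frags, fragment))
  }
  n <- nrow(frags)
  stopifnot(n >= 1L)
  if (is.null(sim)) sim <- build_similarity_matrix(frags)
  sim <- unclass(sim)
  if (!is.matrix(sim) || nrow(sim) != n || ncol(sim) != n) {
    stop("similarity matrix must be ", n, "x", n, " to match the fragments")
  }

  if (n == 1L) {
    root <- tree_leaf(1L)
    step1 <- matrix(integer(0), ncol = 2)
  } else {
    # Step 1: pair fragments greedily into single-level trees
    g <- greedy_pairing(sim)
    step1 <- g$pairs
    forest <- lapply(seq_len(nrow(step1)), function(k) {
      tree_node(tree_leaf(step1[k, 1]), tree_leaf(step1[k, 2]))
    })
    if (!is.na(g$leftover)) {
      forest <- c(forest, list(tree_node(tree_leaf(g$leftover), NULL)))
    }
    # Step 2: round-based greedy pairing of trees; ceiling-halves the forest
    while (length(forest) > 1L) {
      k <- length(forest)
      tsim <- matrix(-Inf, k, k)
      fsets <- lapply(forest, node_frags)
      for (a in seq_len(k - 1L)) {
        for (b in seq((a + 1L), k)) {
          tsim[a, b] <- tsim[b, a] <- max(sim[fsets[[a]], fsets[[b]], drop = FALSE])
        }
      }
      g <- greedy_pairing(tsim)
      nxt <- lapply(seq_len(nrow(g$pairs)), function(m) {
        a <- g$pairs[m, 1]; b <- g$pairs[m, 2]
        cross <- sim[fsets[[a]], fsets[[b]], drop = FALSE]
        hit <- which(cross == max(cross), arr.ind = TRUE)
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
        fa <- fsets[[a]][hit[1, 1]]; fb <- fsets[[b]][hit[1, 2]]
        # subtree holding the lower-index fragment of the best cross pair
        # goes left
        if (fa <= fb) tree_node(forest[[a]], forest[[b]])
        else tree_node(forest[[b]], forest[[a]])
      })
      if (!is.na(g$leftover)) nxt <- c(nxt, forest[g$leftover])
      forest <- nxt
    }
    root <- forest[[1]]
  }

  d <- if (n == 1L) 1L else as.integer(ceiling(log2(n)))
  paths <- leaf_paths(root)
  codes <- character(n)
  codes[vapply(paths, `[[`, integer(1), "frag")] <-
    vapply(paths, `[[`, character(1), "code")
  padded <- vapply(codes, function(cd) {
    paste0(cd, strrep("0", d - nchar(cd)))
  }, character(1), USE.NAMES = FALSE)
  leaves <- data.frame(smiles = frags$smiles, code = padded,
                       depth = nchar(codes),
                       n_attachments = frags$n_attachments,
                       stringsAsFactors = FALSE)
  structure(list(root = root, fragments = frags, n_fragments = n,
                 depth_code = d, levels = node_levels(root),
                 leaves = leaves, step1_pairs = step1, sim = sim),
            class = "fragment_tree")
}

leaf_paths <- function(node, prefix = "") {
  if (is.null(node)) return(list())
  if (isTRUE(node$leaf)) {
    return(list(list(frag = node$frag, code = prefix)))
  }
  c(leaf_paths(node$left, paste0(prefix, "0")),
    leaf_paths(node$right, paste0(prefix, "1")))
}

node_levels <- function(node) {
  if (is.null(node)) return(0L)
  if (isTRUE(node$leaf)) return(1L)
  1L + max(node_levels(node$left), node_levels(node$right))
}

#' @export
print.fragment_tree <- function(x, ...) {
  cat("Fragment similarity tree:", x$n_fragments, "fragment(s), code length",
      x$depth_code, ",", x$levels, "node level(s)\n")
  print(x$leaves[, c("smiles", "code", "n_attachments")], ...)
  invisible(x)
}

code_to_bits <- function(code) {
  as.integer(strsplit(code, "")[[1]])
}

bits_to_code <- function(bits) paste(bits, collapse = "")

#' Path code of a fragment
#'
#' The left-0/right-1 bit sequence from the root to the fragment's leaf,
#' right-padded with 0 to the tree's code length `d`.
#'
#' @param tree a `fragment_tree`.
#' @param frag fragment SMILES (canonical, marker-containing) or leaf index.
#' @return integer vector of 0/1 bits, length `tree$depth_code`.
#' @export
encode_fragment <- function(tree, frag) {
  if (is.character(frag)) {
    idx <- match(frag, tree$leaves$smiles)
    if (is.na(idx)) stop("fragment not in tree: ", frag, call. = FALSE)
  } else {
    idx <- as.integer(frag)
    if (idx < 1L || idx > tree$n_fragments) {
      stop("leaf index out of range: ", idx, call. = FALSE)
    }
  }
  code_to_bits(tree$leaves$code[idx])
}

# Does the subtree under `node` contain a leaf with the given attachment
# count (or any leaf when `n_attach` is NULL)?
subtree_compatible <- function(node, tree, n_attach) {
  fr <- node_frags(node)
  if (length(fr) == 0L) return(FALSE)
  if (is.null(n_attach)) return(TRUE)
  any(tree$fragments$n_attachments[fr] == n_attach)
}

#' Decode a path code to a fragment
#'
#' Walks from the root consuming bits (0 = left, 1 = right). Missing children
#' divert the walk to the existing child; reaching a leaf early stops the
#' walk. When `n_attachments` is given, the walk is restricted to subtrees
#' containing at least one leaf with that attachment count, so the returned
#' fragment is always slot-compatible; `NA` is returned only when no such leaf
#' exists anywhere in the tree.
#'
#' @param tree a `fragment_tree`.
#' @param code integer bit vector or "0101" string, length `tree$depth_code`
#'   (shorter codes are treated as 0-padded).
#' @param n_attachments optional required attachment-point count.
#' @return leaf index into `tree$leaves` (`NA_integer_` if an attachment
#'   constraint cannot be met).
#' @export
decode_code <- function(tree, code, n_attachments = NULL) {
  if (is.character(code)) code <- code_to_bits(code)
  if (!is.null(n_attachments) &&
      !subtree_compatible(tree$root, tree, n_attachments)) {
    return(NA_integer_)
  }
  node <- tree$root
  t <- 1L
  while (!isTRUE(node$leaf)) {
    bit <- if (t <= length(code)) code[t] else 0L
    first <- if (bit == 0L) node$left else node$right
    second <- if (bit == 0L) node$right else node$left
    node <- if (subtree_compatible(first, tree, n_attachments)) first else second
    t <- t + 1L
  }
  node$frag
}

#' Fragment for a path code
#'
#' Convenience wrapper around [decode_code()] returning the fragment row.
#'
#' @inheritParams decode_code
#' @return one-row fragment data frame, or `NULL` when no compatible leaf
#'   exists.
#' @export
decode_fragment <- function(tree, code, n_attachments = NULL) {
  idx <- decode_code(tree, code, n_attachments)
  if (is.na(idx)) return(NULL)
  tree$fragments[idx, , drop = FALSE]
}

#' Check that sibling leaves were mutual best matches
#'
#' Structural diagnostic: for each leaf, reports whether its Step-1 partner
#' (the leaf sharing its longest code prefix) was its most similar available
#' fragment at the moment the pair was formed. Under greedy argmax pairing
#' this holds by construction; the report exists to make that property
#' testable.
#'
#' @param tree a `fragment_tree` built with its similarity matrix retained.
#' @return data frame with one row per leaf: `smiles`, `code`, `partner`
#'   (SMILES or `NA` for an odd leftover), `most_similar_at_pairing`.
#' @export
code_prefix_similarity_check <- function(tree) {
  n <- tree$n_fragments
  partner <- rep(NA_integer_, n)
  best <- rep(NA, n)
  avail <- seq_len(n)
  pairs <- tree$step1_pairs
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    partner[i] <- j; partner[j] <- i
    others_i <- setdiff(avail, i); others_j <- setdiff(avail, j)
    best[i] <- tree$sim[i, j] >= max(tree$sim[i, others_i])
    best[j] <- tree$sim[i, j] >= max(tree$sim[j, others_j])
    avail <- setdiff(avail, c(i, j))
  }
  data.frame(smiles = tree$leaves$smiles, code = tree$leaves$code,
             partner = ifelse(is.na(partner), NA_character_,
                              tree$leaves$smiles[partner]),
             most_similar_at_pairing = best, stringsAsFactors = FALSE)
}

# ------------------------------------------------------- serialization

format_newick_node <- function(node, tree) {
  if (isTRUE(node$leaf)) {
    return(paste0("'", tree$fragments$smiles[node$frag], "'"))
  }
  inner <- format_newick_node(node$left, tree)
  if (!is.null(node$right)) {
    inner <- paste0(inner, ",", format_newick_node(node$right, tree))
  }
  paste0("(", inner, ")")
}

#' Serialize a fragment tree to Newick-like text
#'
#' Leaf labels are single-quoted fragment SMILES; internal nodes are
#' unlabelled. A left-only node is written as a one-child clade.
#'
#' @param tree a `fragment_tree`.
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_tree_newick <- function(tree, path = NULL) {
  txt <- paste0(format_newick_node(tree$root, tree), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick-like fragment tree
#'
#' Inverse of [write_tree_newick()]. Path codes and leaf order are recomputed
#' from the parsed topology; the similarity matrix is not stored in the text
#' form, so `sim` and `step1_pairs` are absent from the result.
#'
#' @param text Newick string, or `NULL` to read from `path`.
#' @param path file to read.
#' @return a `fragment_tree` (without `sim`).
#' @export
read_tree_newick <- function(text = NULL, path = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  text <- sub(";\\s*$", "", trimws(text))
  labels <- character(0)
  pos <- 1L
  parse_node <- function() {
    ch <- substr(text, pos, pos)
    if (ch == "(") {
      pos <<- pos + 1L
      left <- parse_node()
      right <- NULL
      if (substr(text, pos, pos) == ",") {
        pos <<- pos + 1L
        right <- parse_node()
      }
      if (substr(text, pos, pos) != ")") stop("malformed tree text at ", pos)
      pos <<- pos + 1L
      if (is.null(right) && isTRUE(left$leaf)) return(tree_node(left, NULL))
      if (is.null(right)) return(tree_node(left, NULL))
      tree_node(left, right)
    } else if (ch == "'") {
      end <- regexpr("'", substr(text, pos + 1L, nchar(text)), fixed = TRUE)
      if (end == -1L) stop("unterminated leaf label")
      lab <- substr(text, pos + 1L, pos + end - 1L)
      pos <<- pos + end + 1L
      labels[length(labels) + 1L] <<- lab
      tree_leaf(length(labels))
    } else {
      stop("malformed tree text at position ", pos)
    }
  }
  root <- parse_node()
  frags <- do.call(rbind, lapply(labels, fragment))
  n <- nrow(frags)
  d <- if (n == 1L) 1L else as.integer(ceiling(log2(n)))
  paths <- leaf_paths(root)
  codes <- character(n)
  codes[vapply(paths, `[[`, integer(1), "frag")] <-
    vapply(paths, `[[`, character(1), "code")
  leaves <- data.frame(smiles = frags$smiles,
                       code = vapply(codes, function(cd) {
                         paste0(cd, strrep("0", max(0L, d - nchar(cd))))
                       }, character(1), USE.NAMES = FALSE),
                       depth = nchar(codes),
                       n_attachments = frags$n_attachments,
                       stringsAsFactors = FALSE)
  structure(list(root = root, fragments = frags, n_fragments = n,
                 depth_code = d, levels = node_levels(root), leaves = leaves,
                 step1_pairs = matrix(integer(0), ncol = 2), sim = NULL),
            class = "fragment_tree")
}
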