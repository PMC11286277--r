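# Independent oracles used to pin expected values: deliberately naive
# implementations, kept separate from the package's code paths.

# Dynamic-programming Levenshtein distance.
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1, D[i + 1, j] + 1,
                             D[i, j] + (a[i] != b[j]))
    }
  }
  D[n + 1, m + 1]
}

# Pareto fronts by repeatedly peeling the non-dominated set, using an
# explicit O(n^2) dominance matrix (maximization).
oracle_pareto_fronts <- function(obj) {
  obj <- as.matrix(obj)
  remaining <- seq_len(nrow(obj))
  fronts <- list()
  while (length(remaining)) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ])
      }, logical(1)))
    }, logical(1))
    fronts[[length(fronts) + 1L]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

# Crowding distance, straight transcription of the textbook formula.
oracle_crowding <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(front))) {
    ord <- order(front[, k])
    rng <- diff(range(front[, k]))
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (t in 2:(n - 1)) {
        d[ord[t]] <- d[ord[t]] + (front[ord[t + 1], k] - front[ord[t - 1], k]) / rng
      }
    }
  }
  d
}

# Environmental selection re-derived from the two oracles above.
oracle_selection <- function(obj, m) {
  fronts <- oracle_pareto_fronts(obj)
  chosen <- integer(0)
  for (fr in fronts) {
    if (length(chosen) + length(fr) <= m) {
      chosen <- c(chosen, fr)
    } else {
      cd <- oracle_crowding(obj[fr, , drop = FALSE])
      ord <- order(-cd, seq_along(fr))
      chosen <- c(chosen, fr[ord[seq_len(m - length(chosen))]])
      break
    }
  }
  chosen
}

# Greedy most-similar pairing by literal repeated argmax scan.
oracle_greedy_pairs <- function(sim) {
  avail <- seq_len(nrow(sim))
  pairs <- NULL
  while (length(avail) >= 2) {
    best <- -Inf; bi <- NA; bj <- NA
    for (i in avail) {
      for (j in avail) {
        if (i < j && (sim[i, j] > best)) {
          best <- sim[i, j]; bi <- i; bj <- j
        }
      }
    }
    pairs <- rbind(pairs, c(bi, bj))
    avail <- setdiff(avail, c(bi, bj))
  }
  pairs
}

# --- tiny labelled-graph maximum common connected subgraph ----------------
# Graphs: list(elem = character vector, adj = bond-order matrix, 0 = none).
# Counts atoms of the largest connected subgraph of g1 embeddable into g2
# with matching elements and bond orders.

graph_benzene <- function() {
  adj <- matrix(0, 6, 6)
  for (i in 1:6) {
    j <- i %% 6 + 1
    adj[i, j] <- adj[j, i] <- 1.5  # aromatic
  }
  list(elem = rep("C", 6), adj = adj)
}

graph_toluene <- function() {
  g <- graph_benzene()
  elem <- c(g$elem, "C")
  adj <- matrix(0, 7, 7)
  adj[1:6, 1:6] <- g$adj
  adj[1, 7] <- adj[7, 1] <- 1  # exocyclic single bond
  list(elem = elem, adj = adj)
}

subset_connected <- function(adj, verts) {
  if (length(verts) <= 1) return(TRUE)
  seen <- verts[1]
  frontier <- verts[1]
  while (length(frontier)) {
    nxt <- setdiff(verts[colSums(adj[frontier, verts, drop = FALSE] > 0) > 0], seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(verts)
}

embeds_into <- function(g1, verts, g2) {
  # backtracking injective mapping of g1[verts] into g2
  k <- length(verts)
  recur <- function(map) {
    t <- length(map) + 1L
    if (t > k) return(TRUE)
    v <- verts[t]
    for (cand in seq_along(g2$elem)) {
      if (cand %in% map) next
      if (g2$elem[cand] != g1$elem[v]) next
      ok <- TRUE
      for (s in seq_len(t - 1L)) {
        if (g1$adj[v, verts[s]] != g2$adj[cand, map[s]]) { ok <- FALSE; break }
      }
      if (ok && recur(c(map, cand))) return(TRUE)
    }
    FALSE
  }
  recur(integer(0))
}

oracle_mcs_atoms <- function(g1, g2) {
  n <- length(g1$elem)
  for (size in n:1) {
    for (verts in utils::combn(n, size, simplify = FALSE)) {
      if (subset_connected(g1$adj, verts) && embeds_into(g1, verts, g2)) {
        return(size)
      }
    }
  }
  0L
}
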