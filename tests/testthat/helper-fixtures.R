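# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; no data files.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_library <- function() memo("lib", make_fixture_library(6, 8, seed = 0))

fx_smiles50 <- function() memo("smi50", {
  lib <- make_fixture_library(8, 10, seed = 0, n_disubstituted = 40)
  head(lib$smiles, 50)
})

fx_frags8 <- function() memo("frags8", fixture_fragments(8))

fx_sim8 <- function() memo("sim8", build_similarity_matrix(fx_frags8()))

fx_tree8 <- function() memo("tree8", build_tree(fx_frags8(), fx_sim8()))

# A distinct-valued similarity matrix for deterministic tree traces.
synthetic_sim <- function(n, seed = 1) {
  set.seed(seed)
  vals <- sample(seq(0.01, 0.99, length.out = n * (n - 1) / 2))
  m <- diag(1, n)
  m[upper.tri(m)] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(paste0("f", 1:n), paste0("f", 1:n))
  m
}

# Placeholder fragment set for trees driven by a synthetic matrix (the
# SMILES are real fragments so encode/decode and printing stay meaningful).
synthetic_frags <- function(n) {
  pool <- c("[1*]C", "[1*]CC", "[1*]CCC", "[1*]O", "[1*]OC", "[1*]N",
            "[1*]NC", "[1*]F", "[1*]Cl", "[1*]C(N)=O", "[1*]C#N", "[1*]CO",
            "[1*]CN", "[1*]C(C)C", "[1*]CCO", "[1*]CCN")
  stopifnot(n <= length(pool))
  do.call(rbind, lapply(pool[seq_len(n)], fragment))
}
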