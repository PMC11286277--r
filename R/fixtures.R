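# Deterministic synthetic molecule libraries for tests, examples and demos.
# Molecules are ring scaffolds decorated with small substituents, assembled
# through the same fragment machinery the optimizer uses, so every fixture
# molecule is valid and decomposes into at least two fragments. These
# libraries emulate small drug-like reference sets; they do not reproduce the
# size or chemical diversity of screening databases.

FIXTURE_SCAFFOLDS_1 <- c(
  benzene      = "[1*]c1ccccc1",
  pyridine     = "[1*]c1ccncc1",
  cyclohexane  = "[1*]C1CCCCC1",
  thiophene    = "[1*]c1cccs1",
  furan        = "[1*]c1ccco1",
  piperidine   = "[1*]C1CCNCC1",
  pyrimidine   = "[1*]c1ccncn1",
  cyclopentane = "[1*]C1CCCC1"
)

FIXTURE_SCAFFOLDS_2 <- c(
  benzene      = "[1*]c1ccc([2*])cc1",
  pyridine     = "[1*]c1ccc([2*])nc1",
  cyclohexane  = "[1*]C1CCC([2*])CC1",
  thiophene    = "[1*]c1ccc([2*])s1",
  furan        = "[1*]c1ccc([2*])o1",
  piperidine   = "[1*]C1CCN([2*])CC1",
  pyrimidine   = "[1*]c1ncc([2*])cn1",
  cyclopentane = "[1*]C1CCC([2*])C1"
)

FIXTURE_SUBSTITUENTS <- c(
  methyl   = "[1*]C",
  hydroxyl = "[1*]O",
  amino    = "[1*]N",
  fluoro   = "[1*]F",
  chloro   = "[1*]Cl",
  amide    = "[1*]C(N)=O",
  methoxy  = "[1*]OC",
  ethyl    = "[1*]CC",
  nitrile  = "[1*]C#N",
  acetyl   = "[1*]C(C)=O"
)

#' Generate a deterministic fixture molecule library
#'
#' Enumerates ring scaffolds decorated with one substituent (all
#' combinations) and with two substituents (a seeded random subset),
#' assembled via [assemble_fragments()]. The result is reproducible for a
#' fixed `(n_scaffolds, n_substituents, seed)` triple.
#'
#' @param n_scaffolds number of ring scaffolds used (1-8).
#' @param n_substituents number of substituents used (1-10).
#' @param seed RNG seed for the disubstituted subset.
#' @param n_disubstituted how many disubstituted products to add.
#' @return a [molecule_library()].
#' @export
make_fixture_library <- function(n_scaffolds = 4, n_substituents = 5,
                                 seed = 0, n_disubstituted = 30) {
  stopifnot(n_scaffolds >= 1, n_substituents >= 1)
  n_scaffolds <- min(n_scaffolds, length(FIXTURE_SCAFFOLDS_1))
  n_substituents <- min(n_substituents, length(FIXTURE_SUBSTITUENTS))
  scaf1 <- FIXTURE_SCAFFOLDS_1[seq_len(n_scaffolds)]
  scaf2 <- FIXTURE_SCAFFOLDS_2[seq_len(n_scaffolds)]
  subs <- FIXTURE_SUBSTITUENTS[seq_len(n_substituents)]

  mono <- expand.grid(s = seq_along(scaf1), r = seq_along(subs))
  jobs <- lapply(seq_len(nrow(mono)), function(i) {
    list(fragments = c(scaf1[mono$s[i]], subs[mono$r[i]]),
         topology = data.frame(frag_i = 1L, slot_i = 1L,
                               frag_j = 2L, slot_j = 1L))
  })

  di <- expand.grid(s = seq_along(scaf2), r1 = seq_along(subs),
                    r2 = seq_along(subs))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  set.seed(seed)
  pick <- sample.int(nrow(di), min(n_disubstituted, nrow(di)))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  topo2 <- data.frame(frag_i = c(1L, 1L), slot_i = c(1L, 2L),
                      frag_j = c(2L, 3L), slot_j = c(1L, 1L))
  jobs <- c(jobs, lapply(pick, function(i) {
    list(fragments = c(scaf2[di$s[i]], subs[di$r1[i]], subs[di$r2[i]]),
         topology = topo2)
  }))

  res <- assemble_batch(jobs)
  smiles <- res$smiles[!is.na(res$smiles)]
  molecule_library(smiles, name = sprintf("fixture_%ds_%dr_seed%d",
                                          n_scaffolds, n_substituents, seed))
}

#' Assemble a fixture fragment set of a given size
#'
#' Selects fixture molecules until their de-duplicated decomposition
#' fragments reach exactly `n` entries, mirroring small worked examples
#' (e.g. an eight-fragment tree).
#'
#' @param n desired fragment count.
#' @param lib optional [molecule_library()] to draw from (default: the
#'   standard fixture library).
#' @return fragment data frame with `n` rows.
#' @export
fixture_fragments <- function(n = 8, lib = NULL) {
  if (is.null(lib)) lib <- make_fixture_library(8, 10, seed = 0)
  frags <- NULL
  for (s in lib$smiles) {
    dec <- decompose_molecule(s)
    cand <- dedupe_fragments(rbind(frags, dec$fragments))
    n_have <- if (is.null(frags)) 0L else nrow(frags)
    if (nrow(cand) > n) {
      # take individual fragments to land exactly on n
      extra <- cand[(n_have + 1L):nrow(cand), , drop = FALSE]
      frags <- rbind(frags, extra[seq_len(n - n_have), , drop = FALSE])
      break
    }
    frags <- cand
    if (nrow(frags) == n) break
  }
  if (is.null(frags) || nrow(frags) < n) {
    stop("fixture library exhausted before reaching ", n, " fragments")
  }
  rownames(frags) <- NULL
  frags
}
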