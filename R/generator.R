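# Pluggable molecule generators for adaptive search-space expansion. The
# default "recombine" generator swaps attachment-compatible fragments between
# the lead's decomposition template and fragments harvested from the sample
# molecules. A neural encoder-fusion-decoder generator can be plugged in
# through the same interface (see register_generator()): it receives the lead
# and the k most recent sample molecules and must return novel SMILES.

.generators <- new.env(parent = emptyenv())

#' Build a generator request
#'
#' @param lead lead molecule SMILES.
#' @param samples character vector of sample molecule SMILES (at least one).
#' @param n_out number of molecules requested.
#' @param rng_seed optional seed; when `NULL` the generator draws from the
#'   caller's RNG stream (the optimizer relies on this for one-seed
#'   reproducibility).
#' @return object of class `generator_request`.
#' @export
generator_request <- function(lead, samples, n_out = 10, rng_seed = NULL) {
  stopifnot(length(samples) >= 1L, n_out >= 1L)
  structure(list(lead = lead, samples = samples, n_out = as.integer(n_out),
                 rng_seed = rng_seed),
            class = "generator_request")
}

#' Register a molecule generator
#'
#' @param name generator name used in configs (`generator: <name>`).
#' @param fn function taking a [generator_request()] and returning a
#'   character vector of at most `n_out` valid canonical SMILES.
#' @param overwrite replace an existing generator.
#' @export
register_generator <- function(name, fn, overwrite = FALSE) {
  if (!overwrite && !is.null(.generators[[name]])) {
    stop("generator already registered: ", name, call. = FALSE)
  }
  .generators[[name]] <- fn
  invisible(name)
}

#' List registered generators
#' @return character vector of generator names.
#' @export
list_generators <- function() sort(ls(.generators))

resolve_generator <- function(generator) {
  if (is.null(generator)) return(NULL)
  if (is.function(generator)) return(generator)
  if (identical(generator, "recombine")) return(generate_recombine)
  fn <- .generators[[generator]]
  if (is.null(fn)) stop("unknown generator: ", generator, call. = FALSE)
  fn
}

#' Fragment-recombination generator
#'
#' Decomposes the lead and the sample molecules, then assembles candidates on
#' the lead's topology by substituting a random subset of slots with
#' attachment-compatible fragments drawn from the pooled decompositions.
#' Outputs are valid, canonical, and differ from the lead and the inputs;
#' infeasible draws simply yield fewer molecules.
#'
#' @param req a [generator_request()].
#' @return character vector of at most `req$n_out` SMILES.
#' @export
generate_recombine <- function(req) {
  run <- function() {
    inputs <- unique(c(req$lead, req$samples))
    decs <- decompose_molecules(inputs, ids = inputs)
    template <- decs[[1]]
    pool <- dedupe_fragments(do.call(rbind, lapply(decs, `[[`, "fragments")))
    m <- template$r
    out <- character(0)
    jobs <- list()
    for (tries in seq_len(4L * req$n_out)) {
      if (length(jobs) >= 2L * req$n_out) break
      n_swap <- sample.int(m, 1L)
      slots <- template$fragments$smiles
      for (s in sample.int(m, n_swap)) {
        compat <- pool$smiles[pool$n_attachments ==
                                template$fragments$n_attachments[s]]
        if (length(compat)) slots[s] <- compat[sample.int(length(compat), 1L)]
      }
      if (identical(slots, template$fragments$smiles)) next
      jobs[[length(jobs) + 1L]] <- list(fragments = slots,
                                        topology = template$topology)
    }
    if (!length(jobs)) return(character(0))
    res <- assemble_batch(jobs)
    ok <- !is.na(res$smiles) & !(res$smiles %in% inputs)
    out <- unique(res$smiles[ok])
    if (length(out)) {
      # provenance closure: keep only products whose own decomposition stays
      # within the pooled fragments (a ring-free product, say, would
      # re-decompose as one whole-molecule fragment not in the pool)
      closed <- vapply(decompose_molecules(out), function(dec) {
        all(dec$fragments$smiles %in% pool$smiles)
      }, logical(1))
      out <- out[closed]
    }
    utils::head(out, req$n_out)
  }
  if (!is.null(req$rng_seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(req$rng_seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  }
  run()
}

# Adapter stub documenting the call signature a pretrained
# encoder-fusion-decoder generator must satisfy to be dropped in:
#   register_generator("external", function(req) {
#     # req$lead: SMILES; req$samples: character vector; req$n_out: integer
#     # must return <= req$n_out valid SMILES strings
#   })
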