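# Evolutionary optimization of molecule embeddings. A molecule is represented
# by the concatenated path codes of its fragments (length m*d bits, m
# fragments, d = code length of the space's tree). Two mutation operators are
# scheduled against each other over the run: a uniform operator flipping
# every bit with the same probability, and a positional operator whose
# per-position flip probability p + q*i (i = 1..d within each fragment code)
# rises toward the rear of a code, where flips move between nearby (similar)
# leaves. Early iterations favor the uniform operator (large jumps); late
# iterations favor positional refinement. Selection is elitist
# non-dominated sorting with crowding distance; all objectives are maximized.

#' Optimizer and task configuration
#'
#' Bundles the objectives, success thresholds, sample-collection schedule and
#' evolutionary hyperparameters of one optimization task.
#'
#' @param objectives property names to maximize. `SIM` (similarity to the
#'   lead) is always appended if absent: staying near the lead is part of
#'   every task.
#' @param success named minimum values defining a successful molecule
#'   (defaults to the thresholds of [task_definition()] `"task1"` when the
#'   objectives match, otherwise must be given).
#' @param delta named starting sample-collection thresholds (default: the
#'   success thresholds).
#' @param eta named per-iteration decay of the sample thresholds (default
#'   0.001 for every objective). The collection threshold at iteration
#'   `Iter` is `delta - Iter * eta`, clipped at the property's domain
#'   minimum.
#' @param M population size.
#' @param N donor molecules used to seed the search space.
#' @param k minimum number of sample molecules the run must collect; the
#'   iteration budget grows (by `ext_step`, up to `4 * Itermax0`) while fewer
#'   have been found.
#' @param Itermax0 initial maximum iteration count.
#' @param p,q positional-mutation parameters; position `i` of a fragment code
#'   flips with probability `p + q * i`, which must stay within `[0, 1]` at
#'   `i = d`.
#' @param E search-space expansion period (iterations between generator
#'   calls).
#' @param gen_n molecules requested from the generator per expansion.
#' @param ext_step iteration-budget extension step (default `Itermax0 / 2`).
#' @param init_flip_frac largest fraction of bits flipped when building the
#'   initial population.
#' @param seed RNG seed governing every stochastic draw of the run.
#' @return object of class `task_config`.
#' @export
task_config <- function(objectives = c("QED", "PLogP_imp", "SIM"),
                        success = NULL, delta = NULL, eta = NULL,
                        M = 20, N = 20, k = 10, Itermax0 = 50,
                        p = 0.05, q = 0.05, E = 5, gen_n = 10,
                        ext_step = NULL, init_flip_frac = 0.25, seed = 1) {
  if (!"SIM" %in% objectives) objectives <- c(objectives, "SIM")
  if (is.null(success)) {
    for (nm in c("task1", "task2", "task3")) {
      td <- task_definition(nm)
      if (setequal(names(td$success), objectives)) {
        success <- td$success
        break
      }
    }
    if (is.null(success)) {
      stop("no built-in task matches these objectives; supply 'success'")
    }
  }
  if (is.null(delta)) delta <- success[intersect(names(success), objectives)]
  if (is.null(eta)) eta <- stats::setNames(rep(0.001, length(delta)), names(delta))
  if (is.null(ext_step)) ext_step <- max(1L, floor(Itermax0 / 2))
  stopifnot(p >= 0, q >= 0, M >= 2, k >= 1, Itermax0 >= 1, E >= 1)
  structure(list(objectives = objectives, success = success, delta = delta,
                 eta = eta, M = as.integer(M), N = as.integer(N),
                 k = as.integer(k), Itermax0 = as.integer(Itermax0),
                 p = p, q = q, E = as.integer(E), gen_n = as.integer(gen_n),
                 ext_step = as.integer(ext_step),
                 init_flip_frac = init_flip_frac, seed = as.integer(seed)),
            class = "task_config")
}

#' Embed a molecule against a search space
#'
#' The embedding is the concatenation of the path codes of the molecule's
#' fragments, in decomposition order: `m * d` bits.
#'
#' @param smiles molecule SMILES.
#' @param space a `molecule_space` whose tree contains every fragment of the
#'   molecule's decomposition.
#' @return object of class `molecule_embedding`: list with `bits` (0/1
#'   integer vector), `m`, `d`, `slot_frags` (fragment SMILES per slot) and
#'   the `template` decomposition.
#' @export
embed_molecule <- function(smiles, space) {
  dec <- decompose_molecule(smiles)
  codes <- lapply(dec$fragments$smiles, function(f) {
    if (!f %in% space$tree$leaves$smiles) {
      stop("fragment not present in the search space tree: ", f, call. = FALSE)
    }
    encode_fragment(space$tree, f)
  })
  structure(list(bits = unlist(codes), m = dec$r, d = space$tree$depth_code,
                 slot_frags = dec$fragments$smiles, template = dec),
            class = "molecule_embedding")
}

#' @export
print.molecule_embedding <- function(x, ...) {
  cat("Molecule embedding: m =", x$m, ", d =", x$d, "\n")
  cat("  bits:", bits_to_code(x$bits), "\n")
  invisible(x)
}

# Decode one bit vector against (space, template): returns slot fragment
# SMILES (with attachment-compatible fallback to the template's own
# fragment).
decode_slots <- function(bits, space, template) {
  d <- space$tree$depth_code
  m <- template$r
  vapply(seq_len(m), function(s) {
    code <- bits[((s - 1) * d + 1):(s * d)]
    idx <- decode_code(space$tree, code,
                       n_attachments = template$fragments$n_attachments[s])
    if (is.na(idx)) template$fragments$smiles[s]
    else space$tree$leaves$smiles[idx]
  }, character(1))
}

#' Decode embeddings into molecules
#'
#' Each slot's code is decoded to a fragment with the same attachment-point
#' count as the template slot (the decode walk only enters subtrees holding a
#' compatible leaf; a slot keeps its original fragment when no compatible
#' leaf exists). The fragments are then reassembled along the template
#' topology. Chemically invalid assemblies are reported as failures, not
#' errors.
#'
#' @param embeddings a `molecule_embedding`, a bit vector, or a list of
#'   either.
#' @param space a `molecule_space`.
#' @param template the lead's `decomposition` (taken from the embedding when
#'   available).
#' @return data frame with columns `smiles` (NA on failure), `error`, and a
#'   list-column `slots` of the fragment SMILES used.
#' @export
decode_embedding <- function(embeddings, space, template = NULL) {
  if (inherits(embeddings, "molecule_embedding") || !is.list(embeddings)) {
    embeddings <- list(embeddings)
  }
  bits_list <- lapply(embeddings, function(e) {
    if (inherits(e, "molecule_embedding")) e$bits else as.integer(e)
  })
  if (is.null(template)) {
    first <- embeddings[[1]]
    if (!inherits(first, "molecule_embedding")) {
      stop("a template decomposition is required when passing raw bits")
    }
    template <- first$template
  }
  slots <- lapply(bits_list, decode_slots, space = space, template = template)
  jobs <- lapply(slots, function(sl) list(fragments = sl,
                                          topology = template$topology))
  res <- assemble_batch(jobs)
  res$slots <- slots
  res
}

# ------------------------------------------------------------- mutation

#' Uniform bit-flip mutation
#'
#' Flips every bit independently with the same probability.
#'
#' @param bits 0/1 integer vector.
#' @param prob flip probability in `[0, 1]`.
#' @return mutated bit vector.
#' @export
mutate_uniform <- function(bits, prob) {
  stopifnot(prob >= 0, prob <= 1)
  flip <- stats::runif(length(bits)) < prob
  ifelse(flip, 1L - bits, bits)
}

#' Position-weighted bit-flip mutation
#'
#' Within each fragment code, bit `i` (1-based, `i = 1..d`) flips with
#' probability `p + q * i`: flips concentrate on rear positions, which move
#' between nearby leaves of the similarity tree and therefore make small
#' structural changes.
#'
#' @param bits 0/1 integer vector of length `m * d`.
#' @param p base flip probability.
#' @param q per-position increment.
#' @param d fragment-code length.
#' @return mutated bit vector.
#' @export
mutate_positional <- function(bits, p, q, d) {
  if (length(bits) %% d != 0) stop("bit length is not a multiple of d")
  probs <- rep(p + q * seq_len(d), times = length(bits) / d)
  if (any(probs < 0 | probs > 1)) {
    stop("positional mutation probability p + q*i outside [0, 1]; ",
         "reduce p or q", call. = FALSE)
  }
  flip <- stats::runif(length(bits)) < probs
  ifelse(flip, 1L - bits, bits)
}

#' Mutation-operator weights
#'
#' The positional operator is drawn with probability
#' `w1 = 1 - cos(pi/2 * Iter/Itermax)` and the uniform operator with
#' `w2 = cos(pi/2 * Iter/Itermax)`; the weights always sum to 1, starting at
#' (0, 1) and ending at (1, 0).
#'
#' @param iter current iteration (0..`itermax`).
#' @param itermax maximum iteration, >= 1.
#' @return named numeric vector `c(positional = w1, uniform = w2)`.
#' @export
operator_weights <- function(iter, itermax) {
  stopifnot(itermax >= 1, iter >= 0, iter <= itermax)
  w2 <- cos(pi / 2 * iter / itermax)
  c(positional = 1 - w2, uniform = w2)
}

# ------------------------------------------------------------- selection

dominates <- function(a, b) all(a >= b) && any(a > b)

#' Non-dominated sorting
#'
#' Partitions objective vectors (all maximized) into Pareto fronts: front 1
#' is dominated by nothing; front `f` is dominated only by members of
#' earlier fronts.
#'
#' @param objectives numeric matrix, one row per solution, one column per
#'   objective.
#' @return list of integer index vectors, one per front.
#' @export
pareto_fronts <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0L) return(list())
  dom_count <- integer(n)
  dominated_by <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && dominates(objectives[j, ], objectives[i, ])) {
        dom_count[i] <- dom_count[i] + 1L
        dominated_by[[j]] <- c(dominated_by[[j]], i)
      }
    }
  }
  fronts <- list()
  current <- which(dom_count == 0L)
  while (length(current)) {
    fronts[[length(fronts) + 1L]] <- current
    nxt <- integer(0)
    for (j in current) {
      for (i in dominated_by[[j]]) {
        dom_count[i] <- dom_count[i] - 1L
        if (dom_count[i] == 0L) nxt <- c(nxt, i)
      }
    }
    current <- sort(unique(nxt))
  }
  fronts
}

#' Crowding distance within a front
#'
#' For each objective the front is sorted; boundary solutions get infinite
#' distance and interior ones accumulate the normalized gap between their
#' neighbors. Objectives with zero range contribute nothing.
#'
#' @param front numeric matrix of objective vectors (rows = solutions).
#' @return numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  front <- as.matrix(front)
  n <- nrow(front)
  if (n == 0L) return(numeric(0))
  if (n <= 2L) return(rep(Inf, n))
  dist <- numeric(n)
  for (obj in seq_len(ncol(front))) {
    ord <- order(front[, obj])  # stable for ties
    rng <- front[ord[n], obj] - front[ord[1], obj]
    dist[ord[1]] <- Inf
    dist[ord[n]] <- Inf
    if (rng > 0) {
      for (t in 2:(n - 1L)) {
        dist[ord[t]] <- dist[ord[t]] +
          (front[ord[t + 1L], obj] - front[ord[t - 1L], obj]) / rng
      }
    }
  }
  dist
}

#' Elitist environmental selection
#'
#' Fills the next population front by front; the last, partially fitting
#' front is split by descending crowding distance (ties keep index order).
#'
#' @param objectives numeric matrix of the pooled parent+offspring objective
#'   vectors.
#' @param m number of survivors.
#' @return integer indices of the survivors, in selection order.
#' @export
select_next_population <- function(objectives, m) {
  objectives <- as.matrix(objectives)
  stopifnot(nrow(objectives) >= m)
  fronts <- pareto_fronts(objectives)
  chosen <- integer(0)
  for (front in fronts) {
    if (length(chosen) + length(front) <= m) {
      chosen <- c(chosen, front)
    } else {
      cd <- crowding_distance(objectives[front, , drop = FALSE])
      ord <- order(-cd, seq_along(front))
      chosen <- c(chosen, front[ord[seq_len(m - length(chosen))]])
    }
    if (length(chosen) == m) break
  }
  chosen
}

# Rank helper for tournaments: front index and crowding distance per row.
rank_population <- function(objectives) {
  fronts <- pareto_fronts(objectives)
  n <- nrow(objectives)
  front_of <- integer(n)
  crowd <- numeric(n)
  for (f in seq_along(fronts)) {
    idx <- fronts[[f]]
    front_of[idx] <- f
    crowd[idx] <- crowding_distance(objectives[idx, , drop = FALSE])
  }
  list(front = front_of, crowd = crowd)
}

binary_tournament <- function(ranks) {
  n <- length(ranks$front)
  cand <- sample.int(n, 2L, replace = TRUE)
  a <- cand[1]; b <- cand[2]
  if (ranks$front[a] < ranks$front[b]) return(a)
  if (ranks$front[b] < ranks$front[a]) return(b)
  if (ranks$crowd[a] >= ranks$crowd[b]) a else b
}

#' Sample-collection threshold at an iteration
#'
#' The decaying acceptance threshold `delta_p - Iter * eta_p` for property
#' `p`, clipped below at the property's domain minimum.
#'
#' @param property property name configured in `config$delta`.
#' @param iter iteration index.
#' @param config a [task_config()].
#' @return threshold value.
#' @export
sample_threshold <- function(property, iter, config) {
  if (!property %in% names(config$delta)) {
    stop("no sample threshold configured for property '", property, "'",
         call. = FALSE)
  }
  eta <- if (property %in% names(config$eta)) config$eta[[property]] else 0
  max(config$delta[[property]] - iter * eta, property_range(property)[1])
}

# ------------------------------------------------------------- main loop

new_member <- function(bits, slots, smiles, obj) {
  list(bits = bits, slots = slots, smiles = smiles, obj = obj)
}

member_objectives <- function(members, objectives) {
  do.call(rbind, lapply(members, function(m) m$obj[objectives]))
}

scalarize <- function(obj_row, objectives) {
  vals <- vapply(objectives, function(p) {
    rng <- property_range(p)
    v <- obj_row[[p]]
    if (is.finite(rng[1]) && is.finite(rng[2]) && rng[2] > rng[1]) {
      (v - rng[1]) / (rng[2] - rng[1])
    } else {
      v
    }
  }, numeric(1))
  sum(vals)
}

#' Initialize the optimizer population
#'
#' Generates `2M` distinct embeddings, each differing from the lead's by at
#' least one flipped bit (flip count uniform on `[1, init_flip_frac * m * d]`),
#' decodes and scores them, and keeps the best `M` by non-dominated sorting
#' and crowding distance.
#'
#' @param lead_emb the lead's [embed_molecule()] result.
#' @param space a `molecule_space`.
#' @param config a [task_config()].
#' @return list of population members (bits, slot fragments, SMILES,
#'   objective vector).
#' @export
init_population <- function(lead_emb, space, config) {
  bits0 <- lead_emb$bits
  L <- length(bits0)
  if (2^L - 1 < 2 * config$M) {
    stop("the search space is degenerate: ", L, " embedding bits cannot ",
         "yield ", 2 * config$M, " distinct perturbed embeddings", call. = FALSE)
  }
  max_flips <- max(1L, floor(config$init_flip_frac * L))
  # widen the flip window until enough distinct perturbations exist
  while (max_flips < L && sum(choose(L, seq_len(max_flips))) < 2 * config$M) {
    max_flips <- max_flips + 1L
  }
  seen <- character(0)
  cand <- list()
  guard <- 0L
  while (length(cand) < 2 * config$M) {
    guard <- guard + 1L
    if (guard > 10000L) stop("failed to sample distinct initial embeddings")
    nf <- sample.int(max_flips, 1L)
    pos <- sample.int(L, nf)
    bits <- bits0
    bits[pos] <- 1L - bits[pos]
    key <- bits_to_code(bits)
    if (key %in% seen || identical(bits, bits0)) next
    seen <- c(seen, key)
    cand[[length(cand) + 1L]] <- bits
  }
  decoded <- decode_embedding(cand, space, lead_emb$template)
  smiles_vec <- decoded$smiles
  slots_list <- decoded$slots
  valid <- which(!is.na(smiles_vec))
  if (length(valid) < config$M) {
    # top up with the lead itself so selection always has M rows
    need <- config$M - length(valid)
    cand <- c(cand, rep(list(bits0), need))
    smiles_vec <- c(smiles_vec, rep(space$lead, need))
    slots_list <- c(slots_list, rep(list(lead_emb$slot_frags), need))
    valid <- which(!is.na(smiles_vec))
  }
  scores <- score_molecules(smiles_vec[valid], lead = space$lead,
                            properties = config$objectives)
  members <- lapply(seq_along(valid), function(t) {
    i <- valid[t]
    new_member(cand[[i]], slots_list[[i]], smiles_vec[i],
               stats::setNames(as.numeric(scores[t, ]), config$objectives))
  })
  obj <- member_objectives(members, config$objectives)
  members[select_next_population(obj, config$M)]
}

#' Run the full optimization loop
#'
#' Builds (or accepts) the molecule-specific search space, evolves embeddings
#' with the scheduled two-operator mutation and elitist Pareto selection,
#' collects sample molecules passing the decaying thresholds, and
#' periodically expands the space with generator output. The iteration
#' budget grows (up to `4 * Itermax0`) while fewer than `k` samples have been
#' collected.
#'
#' @param lead lead molecule SMILES.
#' @param lib a [molecule_library()] of reference molecules (ignored when
#'   `space` is supplied).
#' @param config a [task_config()].
#' @param generator generator name (see [list_generators()]), a generator
#'   function, or `NULL` to disable search-space expansion.
#' @param space optional pre-built `molecule_space`.
#' @return object of class `optimization_result`: list with `population`
#'   (data frame of the final M molecules and their objectives), `samples`,
#'   `successes`, `success` (logical: did any molecule meet every success
#'   threshold), `history` (per-iteration records), `space`, `config`.
#' @export
run_optimization <- function(lead, lib = NULL, config = task_config(),
                             generator = "recombine", space = NULL) {
  set.seed(config$seed)
  lead <- canonical_smiles(lead)
  if (is.na(lead)) stop("invalid lead SMILES")
  if (is.null(space)) {
    if (is.null(lib)) stop("either a molecule library or a space is required")
    space <- build_space(lead, lib, n = config$N,
                         properties = config$objectives)
  }
  gen_fn <- resolve_generator(generator)
  lead_emb <- embed_molecule(lead, space)
  d <- space$tree$depth_code
  if (config$p + config$q * d > 1) {
    stop("p + q*d = ", config$p + config$q * d,
         " exceeds 1; positional mutation is not a probability", call. = FALSE)
  }

  population <- init_population(lead_emb, space, config)
  template <- lead_emb$template
  samples <- data.frame(smiles = character(0), iteration = integer(0),
                        stringsAsFactors = FALSE)
  successes <- data.frame(smiles = character(0), iteration = integer(0),
                          stringsAsFactors = FALSE)
  task <- structure(list(name = "configured", success = config$success),
                    class = "task_definition")
  history <- NULL
  best_scalar <- -Inf
  Itermax <- config$Itermax0
  iter <- 0L

  while (iter < Itermax) {
    iter <- iter + 1L
    w <- operator_weights(iter, Itermax)
    ranks <- rank_population(member_objectives(population, config$objectives))
    offspring_bits <- vector("list", config$M)
    for (j in seq_len(config$M)) {
      parent <- population[[binary_tournament(ranks)]]
      use_positional <- stats::runif(1) < w[["positional"]]
      offspring_bits[[j]] <- if (use_positional) {
        mutate_positional(parent$bits, config$p, config$q, space$tree$depth_code)
      } else {
        mutate_uniform(parent$bits, config$p)
      }
    }
    decoded <- decode_embedding(offspring_bits, space, template)
    valid <- which(!is.na(decoded$smiles))
    offspring <- list()
    if (length(valid)) {
      scores <- score_molecules(decoded$smiles[valid], lead = lead,
                                properties = config$objectives)
      offspring <- lapply(seq_along(valid), function(t) {
        i <- valid[t]
        new_member(offspring_bits[[i]], decoded$slots[[i]], decoded$smiles[i],
                   stats::setNames(as.numeric(scores[t, ]), config$objectives))
      })
      # sample collection against the decaying thresholds
      thr <- vapply(names(config$delta), sample_threshold, numeric(1),
                    iter = iter, config = config)
      for (m in offspring) {
        if (all(m$obj[names(thr)] >= thr) && !(m$smiles %in% samples$smiles)) {
          samples <- rbind(samples, data.frame(smiles = m$smiles,
                                               iteration = iter))
        }
        if (is_success(m$obj, task) && !(m$smiles %in% successes$smiles)) {
          successes <- rbind(successes, data.frame(smiles = m$smiles,
                                                   iteration = iter))
        }
        sc <- scalarize(as.list(m$obj), config$objectives)
        if (sc > best_scalar) best_scalar <- sc
      }
    }
    pool <- c(population, offspring)
    obj <- member_objectives(pool, config$objectives)
    population <- pool[select_next_population(obj, config$M)]

    # adaptive search-space expansion
    if (!is.null(gen_fn) && iter %% config$E == 0L && nrow(samples) > 0L) {
      recent <- utils::tail(samples$smiles, config$k)
      req <- generator_request(lead, recent, n_out = config$gen_n,
                               rng_seed = NULL)
      new_mols <- gen_fn(req)
      if (length(new_mols)) {
        old_n <- nrow(space$fragments)
        space <- expand_space(space, new_mols, iter)
        if (nrow(space$fragments) > old_n) {
          population <- lapply(population, function(m) {
            m$bits <- unlist(lapply(m$slots, encode_fragment, tree = space$tree))
            m
          })
          lead_emb <- embed_molecule(lead, space)
        }
      } else {
        space$size_history <- rbind(space$size_history,
                                    data.frame(iteration = iter,
                                               n_fragments = nrow(space$fragments)))
      }
    }

    pop_obj <- member_objectives(population, config$objectives)
    rec <- data.frame(iteration = iter, Itermax = Itermax,
                      w_positional = w[["positional"]],
                      w_uniform = w[["uniform"]],
                      n_samples = nrow(samples),
                      n_successes = nrow(successes),
                      n_fragments = nrow(space$fragments),
                      best_scalar = best_scalar)
    for (pn in config$objectives) {
      rec[[paste0("best_", pn)]] <- max(pop_obj[, pn])
      rec[[paste0("mean_", pn)]] <- mean(pop_obj[, pn])
    }
    history <- rbind(history, rec)

    if (iter == Itermax && nrow(samples) < config$k &&
        Itermax < 4L * config$Itermax0) {
      Itermax <- min(Itermax + config$ext_step, 4L * config$Itermax0)
    }
  }

  pop_obj <- member_objectives(population, config$objectives)
  pop_df <- data.frame(smiles = vapply(population, `[[`, character(1), "smiles"),
                       stringsAsFactors = FALSE)
  pop_df <- cbind(pop_df, as.data.frame(pop_obj))
  pop_df$embedding <- vapply(population, function(m) bits_to_code(m$bits),
                             character(1))
  if (nrow(samples)) {
    samples <- cbind(samples, score_molecules(samples$smiles, lead = lead,
                                              properties = config$objectives))
  }
  if (nrow(successes)) {
    successes <- cbind(successes,
                       score_molecules(successes$smiles, lead = lead,
                                       properties = config$objectives))
  }
  structure(list(lead = lead, population = pop_df, samples = samples,
                 successes = successes, success = nrow(successes) > 0L,
                 history = history, space = space, config = config),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("Optimization of", x$lead, "\n")
  cat("  iterations:", max(x$history$iteration), " population:",
      nrow(x$population), "\n")
  cat("  samples:", nrow(x$samples), " successes:", nrow(x$successes), "\n")
  cat("  search space:", x$space$size_history$n_fragments[1], "->",
      utils::tail(x$space$size_history$n_fragments, 1), "fragments\n")
  best <- x$population[which.max(apply(
    x$population[, x$config$objectives, drop = FALSE], 1, sum)), ]
  cat("  best (by objective sum):", best$smiles, "\n")
  invisible(x)
}
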