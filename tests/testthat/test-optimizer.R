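# A tiny but fully functional optimization setting shared by several tests:
# a toluene-like lead in a space of one-attachment rings and substituents.
toy_setting <- function() {
  memo("toy_setting", {
    lead <- "Cc1ccccc1"
    donors <- c("Cc1ccccc1", "Oc1ccccc1", "CCc1ccncc1", "NC1CCCCC1",
                "Clc1cccs1", "N#Cc1ccco1")
    space <- space_from_molecules(lead, donors)
    list(lead = lead, space = space,
         emb = embed_molecule(lead, space))
  })
}

test_that("molecule embeddings concatenate per-fragment path codes", {
  st <- toy_setting()
  emb <- st$emb
  expect_equal(length(emb$bits), emb$m * emb$d)
  expect_equal(emb$m, 2L)
  codes <- lapply(emb$slot_frags, function(f) encode_fragment(st$space$tree, f))
  expect_equal(emb$bits, unlist(codes))
  # single-fragment molecule: embedding of length d
  space1 <- space_from_molecules("CCO", "CCO")
  emb1 <- embed_molecule("CCO", space1)
  expect_equal(length(emb1$bits), space1$tree$depth_code)
})

test_that("fragments at the tree extremes embed as all-0 / all-1 codes", {
  frags <- fx_frags8()
  tree <- fx_tree8()
  leftmost <- tree$leaves$smiles[tree$leaves$code == "000"]
  rightmost <- tree$leaves$smiles[tree$leaves$code == "111"]
  # build a molecule from those two fragments (all carry one attachment)
  smi <- assemble_fragments(c(leftmost, rightmost),
                            data.frame(frag_i = 1, slot_i = 1,
                                       frag_j = 2, slot_j = 1))
  space <- list(tree = tree)
  emb <- embed_molecule(smi, space)
  expect_setequal(vapply(seq_len(emb$m), function(s) {
    fragopt:::bits_to_code(emb$bits[((s - 1) * emb$d + 1):(s * emb$d)])
  }, character(1)), c("000", "111"))
})

test_that("embedding a molecule with foreign fragments names the culprit", {
  st <- toy_setting()
  expect_error(embed_molecule("FCCCF", st$space), "not present")
})

test_that("decoding the lead embedding reproduces the lead", {
  st <- toy_setting()
  dec <- decode_embedding(st$emb, st$space)
  expect_equal(dec$smiles[1], st$lead)
})

test_that("decoded slots always satisfy the attachment constraint", {
  st <- toy_setting()
  d <- st$space$tree$depth_code
  n_att <- st$emb$template$fragments$n_attachments
  set.seed(1)
  for (rep in 1:20) {
    bits <- sample(0:1, st$emb$m * d, replace = TRUE)
    slots <- fragopt:::decode_slots(bits, st$space, st$emb$template)
    expect_equal(count_attachments(slots), n_att)
  }
})

test_that("slots with a single compatible leaf always decode to it", {
  # space with exactly one two-attachment fragment: any code for a
  # two-attachment slot must fall back to it
  lead <- "Cc1ccc(O)cc1"   # ring carries two attachments
  space <- space_from_molecules(lead, c(lead, "CCO", "NC"))
  two_att <- space$fragments$smiles[space$fragments$n_attachments == 2]
  expect_length(two_att, 1L)
  d <- space$tree$depth_code
  for (k in 0:(2^d - 1)) {
    bits <- as.integer(intToBits(k))[d:1]
    idx <- decode_code(space$tree, bits, n_attachments = 2L)
    expect_equal(space$tree$leaves$smiles[idx], two_att)
  }
})

test_that("uniform mutation hits its closed-form flip rate", {
  bits <- rep(0L, 60)
  expect_equal(mutate_uniform(bits, 0), bits)
  expect_equal(mutate_uniform(bits, 1), rep(1L, 60))
  set.seed(11)
  n_trials <- 10000
  flips <- replicate(n_trials, sum(mutate_uniform(bits, 0.1)))
  exp_mean <- 60 * 0.1
  sd_mean <- sqrt(60 * 0.1 * 0.9) / sqrt(n_trials)
  expect_lt(abs(mean(flips) - exp_mean), 3 * sd_mean)
})

test_that("positional mutation follows p + q*i per position", {
  bits <- rep(0L, 9)   # m = 3 fragments, d = 3
  expect_equal(mutate_positional(bits, 0, 0, d = 3), bits)
  set.seed(12)
  # q = 0 reduces to the uniform operator's statistics
  flips_q0 <- replicate(2000, sum(mutate_positional(bits, 0.2, 0, d = 3)))
  expect_lt(abs(mean(flips_q0) - 9 * 0.2), 3 * sqrt(9 * 0.2 * 0.8 / 2000))
  # per-position rates approximate (0.10, 0.15, 0.20) for p=q=0.05, d=3
  n_trials <- 10000
  hits <- matrix(0, nrow = n_trials, ncol = 3)
  one <- rep(0L, 3)
  for (t in seq_len(n_trials)) hits[t, ] <- mutate_positional(one, 0.05, 0.05, d = 3)
  rates <- colMeans(hits)
  expected <- 0.05 + 0.05 * (1:3)
  for (i in 1:3) {
    se <- sqrt(expected[i] * (1 - expected[i]) / n_trials)
    expect_lt(abs(rates[i] - expected[i]), 3 * se)
  }
  expect_true(all(diff(rates) > 0))   # rear positions mutate more
  expect_error(mutate_positional(bits, 0.5, 0.2, d = 3), "outside")
})

test_that("operator weights follow the cosine schedule", {
  expect_equal(unname(operator_weights(0, 50)), c(0, 1))
  expect_equal(unname(operator_weights(50, 50)), c(1, 0))
  expect_equal(unname(operator_weights(25, 50)),
               c(1 - sqrt(2) / 2, sqrt(2) / 2))
  w <- t(vapply(0:50, operator_weights, numeric(2), itermax = 50))
  expect_equal(rowSums(w), rep(1, 51))
  expect_true(all(diff(w[, 1]) > 0))
  expect_true(all(diff(w[, 2]) < 0))
})

test_that("non-dominated sorting matches the O(n^2) oracle", {
  expect_equal(pareto_fronts(rbind(c(1, 1), c(0, 0))), list(1L, 2L))
  expect_equal(pareto_fronts(matrix(1, 4, 2)), list(1:4))
  set.seed(21)
  for (rep in 1:20) {
    obj <- matrix(runif(3 * 20), ncol = 3)
    got <- pareto_fronts(obj)
    want <- oracle_pareto_fronts(obj)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("crowding distance matches hand computation", {
  expect_equal(crowding_distance(rbind(c(1, 2))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(3, 4))), c(Inf, Inf))
  # three collinear equally spaced points in two objectives
  front <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(front), c(Inf, 2, Inf))
  # permutation invariance
  set.seed(5)
  f <- matrix(runif(12), ncol = 2)
  perm <- sample(6)
  expect_equal(crowding_distance(f)[perm], crowding_distance(f[perm, ]))
})

test_that("environmental selection matches the oracle re-implementation", {
  set.seed(31)
  for (rep in 1:20) {
    obj <- matrix(runif(2 * 15), ncol = 2)
    m <- sample(3:12, 1)
    expect_equal(sort(select_next_population(obj, m)),
                 sort(oracle_selection(obj, m)))
  }
  # pool of exactly M survives whole
  obj <- matrix(runif(10), ncol = 2)
  expect_setequal(select_next_population(obj, 5), 1:5)
  # M non-dominated points survive any number of dominated ones
  nd <- cbind(5:1, 1:5)
  dom <- matrix(0, 4, 2)
  expect_setequal(select_next_population(rbind(nd, dom), 5), 1:5)
})

test_that("sample thresholds decay linearly and clip at the domain floor", {
  cfg <- task_config(objectives = c("QED", "SIM"),
                     success = c(QED = 0.85, SIM = 0.3),
                     delta = c(QED = 0.85, SIM = 0.3),
                     eta = c(QED = 0.001, SIM = 0.001))
  expect_equal(sample_threshold("QED", 0, cfg), 0.85)
  expect_equal(sample_threshold("QED", 30, cfg), 0.82)
  thr <- vapply(0:2000, sample_threshold, numeric(1),
                property = "QED", config = cfg)
  expect_true(all(diff(thr) <= 0))
  expect_equal(min(thr), 0)    # clipped at QED's domain minimum
  expect_error(sample_threshold("NOPE", 1, cfg), "NOPE")
})

test_that("initial population has M members, all perturbed, reproducibly", {
  st <- toy_setting()
  cfg <- task_config(objectives = c("QED", "SIM"),
                     success = c(QED = 0.6, SIM = 0.3),
                     M = 8, seed = 5)
  set.seed(5)
  pop1 <- init_population(st$emb, st$space, cfg)
  expect_length(pop1, 8L)
  set.seed(5)
  pop2 <- init_population(st$emb, st$space, cfg)
  expect_identical(lapply(pop1, `[[`, "bits"), lapply(pop2, `[[`, "bits"))
  expect_identical(vapply(pop1, `[[`, character(1), "smiles"),
                   vapply(pop2, `[[`, character(1), "smiles"))
})

test_that("degenerate spaces are refused at initialization", {
  space1 <- space_from_molecules("CCO", "CCO")   # single fragment, d = 1
  emb1 <- embed_molecule("CCO", space1)
  cfg <- task_config(objectives = c("QED", "SIM"),
                     success = c(QED = 0.6, SIM = 0.3), M = 20)
  expect_error(init_population(emb1, space1, cfg), "degenerate")
})

test_that("a fixed seed reproduces a full run exactly", {
  st <- toy_setting()
  cfg <- task_config(objectives = c("QED", "SIM"),
                     success = c(QED = 0.62, SIM = 0.35),
                     delta = c(QED = 0.5, SIM = 0.2),
                     M = 8, k = 2, Itermax0 = 6, E = 3, seed = 99)
  r1 <- run_optimization(st$lead, config = cfg, space = st$space)
  r2 <- run_optimization(st$lead, config = cfg, space = st$space)
  expect_identical(r1$population$smiles, r2$population$smiles)
  expect_identical(r1$history, r2$history)
  expect_equal(nrow(r1$population), 8L)
})

test_that("the best scalarized objective never regresses", {
  st <- toy_setting()
  cfg <- task_config(objectives = c("QED", "SIM"),
                     success = c(QED = 0.62, SIM = 0.35),
                     delta = c(QED = 0.5, SIM = 0.2),
                     M = 8, k = 2, Itermax0 = 8, E = 4, seed = 7)
  res <- run_optimization(st$lead, config = cfg, space = st$space)
  expect_true(all(diff(res$history$best_scalar) >= 0))
})

test_that("collected samples satisfied their collection-time thresholds", {
  st <- toy_setting()
  cfg <- task_config(objectives = c("QED", "SIM"),
                     success = c(QED = 0.62, SIM = 0.35),
                     delta = c(QED = 0.45, SIM = 0.15),
                     eta = c(QED = 0.002, SIM = 0.002),
                     M = 8, k = 2, Itermax0 = 8, E = 4, seed = 13)
  res <- run_optimization(st$lead, config = cfg, space = st$space)
  if (nrow(res$samples) > 0) {
    vals <- score_molecules(res$samples$smiles, lead = st$lead,
                            properties = c("QED", "SIM"))
    for (i in seq_len(nrow(res$samples))) {
      it <- res$samples$iteration[i]
      expect_gte(vals$QED[i], sample_threshold("QED", it, cfg) - 1e-9)
      expect_gte(vals$SIM[i], sample_threshold("SIM", it, cfg) - 1e-9)
    }
  }
})
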