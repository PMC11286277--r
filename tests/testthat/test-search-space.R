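test_that("intermediate-library filtering matches a linear scan", {
  lib <- head(fx_library(), 10)
  class(lib) <- class(fx_library())
  expect_identical(build_intermediate_library(lib, numeric(0)), lib)

  lib <- add_properties(lib, "QED")
  out <- build_intermediate_library(lib, c(QED = 0.5))
  expect_setequal(out$smiles, lib$smiles[lib$QED >= 0.5])
  expect_true(nrow(out) >= 1)

  expect_warning(
    empty <- build_intermediate_library(lib, c(QED = 1.1)),
    "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("unknown property names in thresholds are a config error", {
  expect_error(build_intermediate_library(fx_library(), c(NOPE = 1)),
               "NOPE")
})

test_that("top-N selection matches the brute-force ranking", {
  lib <- head(fx_library(), 10)
  class(lib) <- class(fx_library())
  lead <- lib$smiles[3]
  sims <- fingerprint_similarity(lib$smiles, lead)

  all_ranked <- select_top_n_similar(lead, lib, n = 50)
  expect_equal(nrow(all_ranked), 10L)
  expect_equal(all_ranked$smiles, lib$smiles[order(-sims)])
  expect_equal(all_ranked$smiles[1], lead)
  expect_equal(all_ranked$SIM_lead[1], 1.0)

  top3 <- select_top_n_similar(lead, lib, n = 3)
  expect_equal(top3$smiles, lib$smiles[order(-sims)][1:3])

  empty <- fx_library()[0, ]
  class(empty) <- class(fx_library())
  expect_error(select_top_n_similar(lead, empty), "relax")
})

test_that("build_space pools de-duplicated fragments of the top molecules", {
  lead <- "CCc1ccc(O)cc1"   # 3 unique fragments: ring, ethyl, hydroxyl
  space <- space_from_molecules(lead, lead)
  expect_equal(nrow(space$fragments), 3L)
  expect_equal(space$tree$n_fragments, 3L)
  expect_equal(space$size_history,
               data.frame(iteration = 0L, n_fragments = 3L))

  # duplicates across molecules appear once: both share the benzene ring
  space2 <- space_from_molecules("Cc1ccccc1", c("Cc1ccccc1", "Oc1ccccc1"))
  expect_equal(sum(space2$fragments$smiles == "[1*]c1ccccc1"), 1L)

  # deterministic rebuild
  space3 <- space_from_molecules("Cc1ccccc1", c("Cc1ccccc1", "Oc1ccccc1"))
  expect_identical(space2$fragments, space3$fragments)
  expect_identical(space2$tree$leaves, space3$tree$leaves)
})

test_that("expansion only grows the space and tracks history", {
  space <- space_from_molecules("Cc1ccccc1", c("Cc1ccccc1", "Oc1ccccc1"))
  n0 <- nrow(space$fragments)

  # already-known fragments leave the size unchanged
  s1 <- expand_space(space, "Cc1ccccc1", iteration = 1)
  expect_equal(nrow(s1$fragments), n0)

  s2 <- expand_space(s1, c("NCc1ccccc1", "CCc1ccccc1"), iteration = 2)
  expect_gt(nrow(s2$fragments), n0)
  expect_equal(s2$tree$n_fragments, nrow(s2$fragments))
  expect_true(all(diff(s2$size_history$n_fragments) >= 0))

  # invalid molecules are skipped with a warning, not an error
  expect_warning(s3 <- expand_space(s2, "xxxx", iteration = 3), "invalid")
  expect_equal(nrow(s3$fragments), nrow(s2$fragments))

  # caller-supplied filter can reject candidates
  s4 <- expand_space(s2, "Clc1ccccc1", iteration = 3,
                     filter = function(smi) rep(FALSE, length(smi)))
  expect_equal(nrow(s4$fragments), nrow(s2$fragments))
})

test_that("space property history equals brute-force recomputation", {
  lead <- "Cc1ccccc1"
  space <- space_from_molecules(lead, c("Cc1ccccc1", "Oc1ccccc1"),
                                properties = c("QED", "SIM"))
  space <- expand_space(space, "NCc1ccccc1", iteration = 1)
  recomputed <- colMeans(score_molecules(space$source$smiles, lead = lead,
                                         properties = c("QED", "SIM")))
  last <- utils::tail(space$property_history, 1)
  expect_equal(last$QED, unname(recomputed["QED"]), tolerance = 1e-12)
  expect_equal(last$SIM, unname(recomputed["SIM"]), tolerance = 1e-12)
})

test_that("growth percentage follows the definition", {
  expect_equal(round(space_growth_percent(c(64, 115)), 1), 79.7)
  expect_equal(space_growth_percent(c(30, 30)), 0)
  expect_equal(space_growth_percent(c(10, 20)), 100)
  expect_error(space_growth_percent(c(42)), "two")
  expect_error(space_growth_percent(c(0, 10)), "undefined|0")
})

test_that("space serialization writes fragments, tree and history", {
  space <- space_from_molecules("Cc1ccccc1", c("Cc1ccccc1", "Oc1ccccc1"))
  stem <- file.path(withr::local_tempdir(), "space")
  paths <- write_space(space, stem)
  expect_true(all(file.exists(paths)))
  frags <- readLines(paths[1])
  expect_setequal(frags, space$fragments$smiles)
  back <- read_tree_newick(path = paths[2])
  expect_equal(back$n_fragments, space$tree$n_fragments)
})
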