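test_that("an 8-fragment tree has 4 node levels and 3-bit codes", {
  tree <- fx_tree8()
  expect_equal(tree$n_fragments, 8L)
  expect_equal(tree$levels, 4L)
  expect_equal(tree$depth_code, 3L)
  expect_setequal(tree$leaves$code,
                  c("000", "001", "010", "011", "100", "101", "110", "111"))
  leftmost <- tree$leaves$smiles[tree$leaves$code == "000"]
  rightmost <- tree$leaves$smiles[tree$leaves$code == "111"]
  expect_equal(encode_fragment(tree, leftmost), c(0L, 0L, 0L))
  expect_equal(encode_fragment(tree, rightmost), c(1L, 1L, 1L))
})

test_that("a single-fragment tree is its own root with code length 1", {
  tree <- build_tree(fragment("[1*]C"), matrix(1, 1, 1))
  expect_equal(tree$n_fragments, 1L)
  expect_equal(tree$depth_code, 1L)
  expect_equal(decode_code(tree, c(0L)), 1L)
  expect_equal(decode_code(tree, c(1L)), 1L)
})

test_that("a 5-fragment build follows the traced grouping procedure", {
  # engineered distinct similarities: argmax order is (2,3), then (1,4),
  # leaving 5 as the odd left-only leaf
  sim <- diag(1, 5)
  vals <- c("12" = 0.30, "13" = 0.20, "14" = 0.80, "15" = 0.10,
            "23" = 0.90, "24" = 0.25, "25" = 0.15,
            "34" = 0.22, "35" = 0.12, "45" = 0.05)
  for (key in names(vals)) {
    i <- as.integer(substr(key, 1, 1)); j <- as.integer(substr(key, 2, 2))
    sim[i, j] <- sim[j, i] <- vals[[key]]
  }
  frags <- synthetic_frags(5)
  tree <- build_tree(frags, sim)
  expect_equal(nrow(tree$step1_pairs), 2L)           # 3 groups incl. leftover
  expect_equal(tree$step1_pairs[1, ], c(2L, 3L))
  expect_equal(tree$step1_pairs[2, ], c(1L, 4L))
  expect_equal(tree$n_fragments, 5L)
  expect_equal(nrow(tree$leaves), 5L)
  expect_equal(tree$depth_code, 3L)
  expect_true(all(nchar(tree$leaves$code) == 3L))
  expect_true(any(tree$leaves$depth < 3L))           # padded shallow leaf
})

test_that("greedy pairing equals the repeated-argmax oracle", {
  for (seed in 1:5) {
    sim <- synthetic_sim(8, seed)
    got <- fragopt:::greedy_pairing(sim)$pairs
    expect_equal(unname(got), unname(oracle_greedy_pairs(sim)))
  }
})

test_that("leaf set is preserved and codes are unique", {
  for (n in c(2, 3, 5, 6, 8, 9)) {
    sim <- synthetic_sim(n, seed = n)
    frags <- synthetic_frags(n)
    tree <- build_tree(frags, sim)
    expect_equal(sort(tree$leaves$smiles), sort(frags$smiles))
    expect_equal(tree$depth_code, max(1L, ceiling(log2(n))))
    expect_true(all(nchar(tree$leaves$code) == tree$depth_code))
    expect_equal(anyDuplicated(tree$leaves$code), 0L)
  }
})

test_that("encode/decode roundtrip holds on every leaf", {
  for (n in c(2, 5, 8, 11)) {
    tree <- build_tree(synthetic_frags(n), synthetic_sim(n, seed = n + 50))
    for (i in seq_len(n)) {
      code <- encode_fragment(tree, i)
      expect_equal(decode_code(tree, code), i)
    }
  }
})

test_that("decoding is total: every code reaches some leaf", {
  tree <- build_tree(synthetic_frags(5), synthetic_sim(5, seed = 3))
  d <- tree$depth_code
  for (k in 0:(2^d - 1)) {
    bits <- as.integer(intToBits(k))[d:1]
    idx <- decode_code(tree, bits)
    expect_true(idx %in% seq_len(5))
  }
})

test_that("a globally dominant pair become prefix-sharing siblings", {
  sim <- synthetic_sim(8, seed = 11)
  sim[1, 2] <- sim[2, 1] <- 0.999
  frags <- synthetic_frags(8)
  tree <- build_tree(frags, sim)
  codes <- tree$leaves$code[match(frags$smiles[1:2], tree$leaves$smiles)]
  d <- tree$depth_code
  expect_equal(substr(codes[1], 1, d - 1), substr(codes[2], 1, d - 1))
  report <- code_prefix_similarity_check(tree)
  expect_true(all(report$most_similar_at_pairing, na.rm = TRUE))
  expect_equal(report$partner[match(frags$smiles[1], report$smiles)],
               frags$smiles[2])
})

test_that("all-equal similarities pair by index order", {
  n <- 6
  sim <- matrix(0.5, n, n); diag(sim) <- 1
  tree <- build_tree(synthetic_frags(n), sim)
  expect_equal(unname(tree$step1_pairs),
               matrix(c(1L, 2L, 3L, 4L, 5L, 6L), ncol = 2, byrow = TRUE))
})

test_that("tree count after step 1 is ceiling(n/2)", {
  for (n in c(4, 5, 7, 9)) {
    tree <- build_tree(synthetic_frags(n), synthetic_sim(n, seed = n))
    n_groups <- nrow(tree$step1_pairs) + (n %% 2L)
    expect_equal(n_groups, ceiling(n / 2))
  }
})

test_that("newick serialization roundtrips structure and codes", {
  tree <- fx_tree8()
  txt <- write_tree_newick(tree)
  back <- read_tree_newick(txt)
  expect_equal(back$n_fragments, tree$n_fragments)
  expect_equal(back$depth_code, tree$depth_code)
  ord <- match(tree$leaves$smiles, back$leaves$smiles)
  expect_equal(back$leaves$code[ord], tree$leaves$code)

  # odd tree with a left-only node survives the roundtrip too
  tree5 <- build_tree(synthetic_frags(5), synthetic_sim(5, seed = 9))
  back5 <- read_tree_newick(write_tree_newick(tree5))
  ord5 <- match(tree5$leaves$smiles, back5$leaves$smiles)
  expect_equal(back5$leaves$code[ord5], tree5$leaves$code)
})

test_that("size mismatch between fragments and matrix errors", {
  expect_error(build_tree(synthetic_frags(4), synthetic_sim(5)), "match")
})
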