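test_that("lead-relative scores are exact at the lead itself", {
  lead <- "Cc1ccccc1"
  s <- score_molecules(lead, lead = lead,
                       properties = c("QED", "PLogP", "PLogP_imp", "SA", "SIM"))
  expect_equal(s$SIM, 1.0)
  expect_equal(s$PLogP_imp, 0.0)
  expect_true(s$QED > 0 && s$QED < 1)
  expect_true(s$SA > 0 && s$SA <= 1)
})

test_that("scores are deterministic across calls", {
  smiles <- head(fx_library()$smiles, 5)
  a <- score_molecules(smiles, lead = smiles[1],
                       properties = c("QED", "SA", "SIM", "DRD2", "GSK3B"))
  b <- score_molecules(smiles, lead = smiles[1],
                       properties = c("QED", "SA", "SIM", "DRD2", "GSK3B"))
  expect_identical(a, b)
})

test_that("bounded properties stay in [0, 1] on the fixture library", {
  smiles <- head(fx_library()$smiles, 20)
  s <- score_molecules(smiles, lead = smiles[1],
                       properties = c("QED", "SA", "SIM", "DRD2", "GSK3B"))
  for (p in names(s)) {
    expect_true(all(s[[p]] >= 0 & s[[p]] <= 1), info = p)
  }
})

test_that("penalized logP decomposes into its three terms", {
  desc <- fragopt:::chem_descriptors("Cc1ccccc1")
  s <- score_molecules("Cc1ccccc1", properties = c("PLogP", "LogP"))
  # no ring larger than 6: penalty 0, so PLogP = logP - SA_raw
  expect_equal(s$PLogP, s$LogP - desc$sa_raw, tolerance = 1e-9)
})

test_that("unregistered properties are a config error; custom ones register", {
  expect_error(score_molecules("CC", properties = "UNKNOWN"), "UNKNOWN")
  register_scorer("HEAVY", function(smiles, lead = NULL) {
    fragopt:::chem_descriptors(smiles)$heavy_atoms
  }, range = c(0, Inf), description = "heavy atom count", overwrite = TRUE)
  s <- score_molecules(c("CC", "CCC"), properties = "HEAVY")
  expect_equal(s$HEAVY, c(2, 3))
  expect_error(register_scorer("HEAVY", identity), "already")
})

test_that("task success predicates apply inclusive thresholds", {
  t1 <- task_definition("task1")
  expect_true(is_success(c(QED = 0.86, PLogP_imp = 3.2, SIM = 0.35), t1))
  expect_true(is_success(c(QED = 0.85, PLogP_imp = 3.0, SIM = 0.30), t1))
  expect_false(is_success(c(QED = 0.86, PLogP_imp = 3.2, SIM = 0.29), t1))
  expect_error(is_success(c(QED = 0.9), t1), "PLogP_imp|SIM")

  t2 <- task_definition("task2")
  expect_equal(t2$success, c(QED = 0.8, DRD2 = 0.4, SIM = 0.3))
  t3 <- task_definition("task3")
  expect_equal(t3$success, c(QED = 0.7, GSK3B = 0.4, SA = 0.7, SIM = 0.2))
})

test_that("success is monotone in every property", {
  t1 <- task_definition("task1")
  set.seed(41)
  for (rep in 1:50) {
    v <- c(QED = runif(1), PLogP_imp = runif(1, -2, 5), SIM = runif(1))
    better <- v + abs(rnorm(3, sd = 0.2))
    names(better) <- names(v)
    if (is_success(v, t1)) expect_true(is_success(better, t1))
  }
})

test_that("success rate is the percentage of optimizable leads", {
  expect_equal(success_rate(c(TRUE, TRUE)), 100)
  expect_equal(success_rate(c(FALSE, FALSE, FALSE)), 0)
  expect_equal(success_rate(c(TRUE, TRUE, TRUE, FALSE)), 75)
  expect_equal(success_rate(list(list(success = TRUE), list(success = FALSE))), 50)
  expect_error(success_rate(logical(0)), "at least one")
  # invariant to ordering
  set.seed(2)
  x <- runif(10) > 0.5
  expect_equal(success_rate(x), success_rate(rev(x)))
})
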