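test_that("sampleDataset is reproducible and matches its moments", {
  d1 <- sampleDataset(KineticParams(5, 3), nCells = 10000, seed = 11)
  d2 <- sampleDataset(KineticParams(5, 3), nCells = 10000, seed = 11)
  expect_identical(counts(d1), counts(d2))
  # E[Y] = 7.5, Var[Y] = 18.75 at lambda = 0.5
  se_mean <- sqrt(18.75 / 10000)
  expect_lt(abs(mean(counts(d1)) - 7.5), 4 * se_mean)
  expect_s4_class(d1, "SyntheticDataset")
  expect_equal(d1@lambda, 0.5)
  expect_equal(d1@seed, 11)
})

test_that("empirical pmf matches the model pmf", {
  th <- KineticParams(4, 8, k = 5, h = -4)
  d <- sampleDataset(th, nCells = 20000, seed = 12)
  p <- observedPmf(th, 0.5)
  bins <- burstfeedback:::.gof_bins(p, 20000)
  obs <- burstfeedback:::.gof_observed(counts(d), bins$cut)
  chi2 <- chiSquareStat(obs, bins$expected)
  # generous chi-square bound at ~bins$cut degrees of freedom
  expect_lt(chi2, qchisq(0.9999, df = bins$cut))
})

test_that("dropout thins counts as documented", {
  d <- sampleDataset(KineticParams(5, 3), nCells = 5000, seed = 13)
  expect_identical(counts(applyDropout(d, 0)), counts(d))
  thinned <- applyDropout(d, 0.5, seed = 14)
  expect_equal(thinned@lambda, 0.25)
  expect_true(all(counts(thinned) <= counts(d)))
  se <- sqrt(var(counts(d)) / 5000)
  expect_lt(abs(mean(counts(thinned)) - 0.5 * mean(counts(d))), 4 * se)
  expect_error(applyDropout(d, 1))
  # plain integer vectors work too
  expect_identical(applyDropout(c(3L, 0L), 0), c(3L, 0L))
})

test_that("recovery error is the squared log10 distance", {
  expect_equal(recoveryError(c(2, 3), c(2, 3)), 0)
  expect_equal(recoveryError(c(2, 3), c(4, 3)), log10(2)^2)
  expect_equal(recoveryError(c(2, 3), c(4, 6)), 2 * log10(2)^2)
  expect_equal(recoveryError(c(2, 3), c(4, 6)), recoveryError(c(4, 6), c(2, 3)))
  expect_equal(recoveryError(KineticParams(2, 3), KineticParams(4, 3)),
               log10(2)^2)
  expect_error(recoveryError(c(0, 3), c(2, 3)), "positive")
})

test_that("simulateExperiment assembles truth-annotated counts", {
  thetas <- list(gA = KineticParams(2, 4),
                 gB = KineticParams(6, 6, k = 10, h = 3))
  se1 <- simulateExperiment(thetas, nCells = 50, seed = 15)
  se2 <- simulateExperiment(thetas, nCells = 50, seed = 15)
  expect_identical(SummarizedExperiment::assay(se1, "counts"),
                   SummarizedExperiment::assay(se2, "counts"))
  expect_equal(dim(se1), c(2L, 50L))
  rd <- SummarizedExperiment::rowData(se1)
  expect_equal(unname(rd$true_form), c("none", "negative"))
  expect_equal(unname(rd$true_a), c(2, 6))
  expect_equal(S4Vectors::metadata(se1)$lambda, 0.5)
})

test_that("robustnessSuite emits one tidy row per replicate", {
  tab <- robustnessSuite(list(t1 = KineticParams(3, 3)), cellSizes = 100,
                         reps = 1, restarts = 1, forms = "matched",
                         seed = 16)
  expect_equal(nrow(tab), 1)
  expect_named(tab, c("theta_id", "n_cells", "dropout", "rep", "true_form",
                      "selected_form", "a_hat", "b_hat", "error",
                      "correct", "failed"))
  expect_false(tab$failed)
  expect_true(is.finite(tab$error))
  # matched mode never classifies
  expect_true(is.na(tab$selected_form))
})

test_that("derived seeds differ across tasks", {
  s <- vapply(1:50, function(i) burstfeedback:::.derive_seed(1, i),
              numeric(1))
  expect_equal(anyDuplicated(s), 0)
})
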