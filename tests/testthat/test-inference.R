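test_that("moment-based starts invert the thinned-model moments", {
  # mean 2, variance 4: a0 = 4 / 2 = 2, b0 = (2 - 1) / 0.5 = 2
  cnt <- c(0L, 2L, 4L)
  withr::with_seed(1, {
    th <- initialValues(cnt, lambda = 0.5, form = "none")
    expect_equal(burstFrequency(th), 2)
    expect_equal(burstSize(th), 2)
    expect_false(attr(th, "fallback"))
  })
})

test_that("degenerate counts fall back to midpoint starts", {
  withr::with_seed(1, {
    th <- initialValues(c(1L, 1L, 1L), form = "none")
    expect_true(attr(th, "fallback"))
    b <- fitBounds()
    expect_equal(burstFrequency(th), mean(b$a))
    expect_equal(burstSize(th), mean(b$b))
  })
})

test_that("feedback starts draw h and k inside the bounds", {
  withr::with_seed(2, {
    for (i in 1:20) {
      th <- initialValues(c(0L, 2L, 4L, 9L), form = "positive")
      expect_true(hillCoefficient(th) %in% -5:-1)
      expect_true(bindingConstant(th) >= 1 &&
                    bindingConstant(th) <= 100)
      tn <- initialValues(c(0L, 2L, 4L, 9L), form = "negative")
      expect_true(hillCoefficient(tn) %in% 1:5)
    }
  })
})

test_that("negative log-likelihood matches direct summation", {
  expect_equal(negLogLikelihood(KineticParams(1, 2), counts = 0L), log(2))
  cnt <- c(0L, 1L, 1L, 3L, 7L, 2L)
  th <- KineticParams(2.2, 3.3)
  expect_equal(negLogLikelihood(th, cnt),
               -sum(dnbinom(cnt, size = 2.2,
                            prob = 1 / (1 + 3.3 * 0.5), log = TRUE)))
  thf <- KineticParams(3, 6, k = 4, h = -3)
  p <- observedPmf(thf, 0.5, ymax = max(cnt))
  expect_equal(negLogLikelihood(thf, cnt),
               -sum(log(p[as.character(cnt)])), tolerance = 1e-9)
})

test_that("fitGene returns the documented shape and is seeded", {
  cnt <- counts(sampleDataset(KineticParams(3, 3), nCells = 150, seed = 4))
  f1 <- fitGene(cnt, restarts = 2, order = 60, seed = 9)
  f2 <- fitGene(cnt, restarts = 2, order = 60, seed = 9)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 3 * 2)
  expect_named(f1, c("form", "restart", "a", "b", "k", "h", "nll",
                     "converged", "on_boundary", "init_fallback",
                     "degenerate", "aicc"))
  expect_equal(attr(f1, "n_cells"), 150)
  # AICc column obeys the small-sample formula
  kpar <- ifelse(f1$form == "none", 2, 4)
  expect_equal(f1$aicc,
               2 * f1$nll + 2 * kpar + 2 * kpar * (kpar + 1) /
                 (150 - kpar - 1))
})

test_that("fitGene recovers NB parameters on a large sample", {
  cnt <- counts(sampleDataset(KineticParams(5, 3), nCells = 2000, seed = 1))
  f <- fitGene(cnt, forms = "none", restarts = 3, seed = 2)
  best <- f[which.min(f$nll), ]
  expect_lt(recoveryError(KineticParams(5, 3), c(best$a, best$b)), 0.05)
})

test_that("selectModel picks the smallest AICc and breaks ties simply", {
  fits <- data.frame(
    form = c("none", "negative", "positive"),
    restart = 1L, a = c(2, 2, 2), b = c(3, 3, 3),
    k = c(NA, 5, 5), h = c(0, 2, -2), nll = c(100, 96, 95.9),
    converged = TRUE, on_boundary = FALSE,
    init_fallback = FALSE, degenerate = FALSE,
    aicc = c(204.1, 200.2, 200.0))
  sel <- selectModel(fits, n = 500, gene = "g")
  expect_equal(selectedForm(sel), "positive")
  expect_equal(hillCoefficient(selectedParams(sel)), -2)
  # exact tie goes to the simpler (earlier-ordered) form
  fits$aicc <- c(200, 200, 200)
  expect_equal(selectedForm(selectModel(fits, n = 500)), "none")
  fits$aicc <- c(204, 200, 200)
  expect_equal(selectedForm(selectModel(fits, n = 500)), "negative")
})

test_that("selectModel filters boundary and failed fits", {
  fits <- data.frame(
    form = c("none", "negative"), restart = 1L,
    a = c(2, 2), b = c(3, 3), k = c(NA, 5), h = c(0, 2),
    nll = c(100, 90), converged = c(TRUE, TRUE),
    on_boundary = c(FALSE, TRUE), init_fallback = FALSE,
    degenerate = FALSE, aicc = c(204.1, 188))
  expect_equal(selectedForm(selectModel(fits, n = 500)), "none")
  fits$on_boundary <- TRUE
  sel <- selectModel(fits, n = 500)
  expect_true(sel@unclassifiable)
  expect_error(selectModel(fits, n = 5), "sample size")
})

test_that("fitBurstKinetics fits every row of an experiment", {
  se <- simulateExperiment(list(gA = KineticParams(2, 4),
                                gB = KineticParams(6, 2)),
                           nCells = 200, seed = 7)
  res <- fitBurstKinetics(se, restarts = 2, seed = 3)
  expect_equal(res$gene, c("gA", "gB"))
  expect_equal(res$n_cells, c(200, 200))
  expect_false(any(res$unclassifiable))
  expect_true(all(res$form %in% c("none", "negative", "positive")))
})

test_that("fitBurstKinetics honors the keep mask", {
  m <- matrix(c(rep(1L, 9), 50L), nrow = 1,
              dimnames = list("g1", paste0("c", 1:10)))
  keep <- matrix(TRUE, 1, 10, dimnames = dimnames(m))
  keep[1, 10] <- FALSE
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m, keep = keep))
  res <- fitBurstKinetics(se, restarts = 1, seed = 5)
  expect_equal(res$n_cells, 9)
})
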