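test_that("cv2AndRcv2 matches the closed non-feedback moments", {
  s <- cv2AndRcv2(KineticParams(2, 3))
  expect_equal(s[["mean"]], 3)
  expect_equal(s[["cv2"]], 7.5 / 9)
  expect_equal(s[["rcv2"]], 7.5 / 9 - 1 / log2(3))
})

test_that("rcv2 is undefined at mean <= 1", {
  s <- cv2AndRcv2(KineticParams(1, 2))  # mean = 0.5 * 1 * 2 = 1
  expect_true(is.na(s[["rcv2"]]))
  expect_equal(s[["mean"]], 1)
})

test_that("feedback statistics come from the model pmf", {
  th <- KineticParams(6, 6, k = 10, h = 3)
  s <- cv2AndRcv2(th)
  p <- observedPmf(th, 0.5)
  y <- seq_along(p) - 1
  mu <- sum(p * y)
  v <- sum(p * y^2) - mu^2
  expect_equal(s[["mean"]], mu, tolerance = 1e-8)
  expect_equal(s[["cv2"]], v / mu^2, tolerance = 1e-8)
})

test_that("burstStatsTable joins fits, stats and annotations", {
  fit <- data.frame(gene = c("g1", "g2", "g3"),
                    n_cells = 500,
                    form = c("none", "negative", "none"),
                    a = c(2, 6, 4), b = c(3, 6, 5),
                    k = c(NA, 10, NA), h = c(0, 3, 0),
                    nll = 1, aicc_none = 1, aicc_negative = 1,
                    aicc_positive = 1,
                    unclassifiable = c(FALSE, FALSE, TRUE))
  ann <- data.frame(gene_id = c("g1", "g2"), TATA = c(1L, 0L),
                    promoter_width_bp = c(10, 40))
  tab <- burstStatsTable(fit, annotations = ann)
  expect_equal(tab$gene, c("g1", "g2"))   # unclassifiable g3 dropped
  expect_equal(levels(tab$feedback), c("none", "negative", "positive"))
  expect_equal(tab$bf, c(2, 6))
  expect_equal(tab$cv2[1], 7.5 / 9)
  expect_equal(tab$tss_class, c("sharp", "broad"))
})

test_that("gofOnly filters on the gof_pass column", {
  fit <- data.frame(gene = c("g1", "g2"), n_cells = 500,
                    form = "none", a = c(2, 3), b = c(3, 3),
                    k = NA, h = 0, nll = 1, aicc_none = 1,
                    aicc_negative = NA, aicc_positive = NA,
                    unclassifiable = FALSE,
                    gof_pass = c(TRUE, FALSE))
  expect_equal(burstStatsTable(fit, gofOnly = TRUE)$gene, "g1")
  fit$gof_pass <- NULL
  expect_error(burstStatsTable(fit, gofOnly = TRUE), "gof_pass")
})

test_that("regressionTvalues recovers a planted motif effect", {
  set.seed(31)
  n <- 400
  d <- data.frame(TATA = rbinom(n, 1, 0.5), Inr = rbinom(n, 1, 0.5),
                  CCAAT = rbinom(n, 1, 0.5), GC = rbinom(n, 1, 0.5),
                  feedback = factor("none",
                                    levels = c("none", "negative",
                                               "positive")),
                  bf = 1, bs = 1)
  d$rcv2 <- 2 * d$TATA - 1 * d$GC + rnorm(n, sd = 0.5)
  out <- regressionTvalues(d, "rcv2")
  expect_gt(out$t_value[out$term == "TATA"], 10)
  expect_lt(out$t_value[out$term == "GC"], -5)
  expect_false(any(out$aliased))
})

test_that("regression crosses motifs with feedback and flags aliasing", {
  set.seed(32)
  n <- 300
  d <- data.frame(TATA = rbinom(n, 1, 0.5), Inr = rbinom(n, 1, 0.5),
                  CCAAT = rbinom(n, 1, 0.5), GC = 0L,
                  feedback = factor(sample(c("none", "negative"), n,
                                           replace = TRUE),
                                    levels = c("none", "negative",
                                               "positive")),
                  bf = exp(rnorm(n)), bs = 1)
  d$rcv2 <- rnorm(n)
  out <- regressionTvalues(d, "rcv2")
  expect_true(any(grepl(":feedback", out$term)))
  # GC is constant, so its terms must be flagged, not dropped silently
  expect_true(all(out$aliased[grepl("GC", out$term)]))
  out_bf <- regressionTvalues(d, "log10_bf")
  expect_equal(nrow(out_bf), nrow(out))
  expect_error(regressionTvalues(d[, -1], "rcv2"), "missing columns")
})
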