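test_that("KineticParams validity is enforced", {
  expect_s4_class(KineticParams(2, 3), "KineticParams")
  expect_error(KineticParams(-1, 3))
  expect_error(KineticParams(2, 0))
  expect_error(KineticParams(2, 3, h = 2))          # k required
  expect_error(KineticParams(2, 3, epsilon = 0, k = 5, h = -2))
  expect_error(KineticParams(2, 3, epsilon = 1, k = 5, h = 2))
})

test_that("accessors return the slots", {
  th <- KineticParams(2, 3, epsilon = 0.05, k = 5, h = -2)
  expect_equal(burstFrequency(th), 2)
  expect_equal(burstSize(th), 3)
  expect_equal(leakiness(th), 0.05)
  expect_equal(bindingConstant(th), 5)
  expect_equal(hillCoefficient(th), -2)
  expect_equal(feedbackForm(th), "positive")
  expect_equal(feedbackForm(KineticParams(2, 3)), "none")
  expect_equal(feedbackForm(KineticParams(2, 3, k = 5, h = 3)), "negative")
})

test_that("non-feedback kernel is the Gamma density", {
  th <- KineticParams(2.5, 3)
  x <- c(0.1, 1, 5, 20)
  expect_equal(kernelDensity(th, x), dgamma(x, shape = 2.5, scale = 3))
  expect_equal(kernelDensity(KineticParams(1, 1), 1), exp(-1))
})

test_that("feedback kernels are normalized densities", {
  for (th in list(KineticParams(3, 4, k = 5, h = 3),
                  KineticParams(2, 6, k = 4, h = -3))) {
    f <- function(x) kernelDensity(th, x)
    total <- integrate(f, 0, th@k, rel.tol = 1e-10)$value +
      integrate(f, th@k, Inf, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("closed-form non-feedback pmf has the known values", {
  expect_equal(observedPmfNonfeedback(1, 2, 0.5, 0), 0.5)
  expect_equal(observedPmfNonfeedback(1, 2, 0.5, 3), 1 / 16)
  y <- 0:40
  expect_equal(observedPmfNonfeedback(3.2, 4.1, 0.5, y),
               dnbinom(y, size = 3.2, prob = 1 / (1 + 4.1 * 0.5)),
               tolerance = 1e-14)
})

test_that("quadrature path agrees with the closed form at h = 0", {
  th <- KineticParams(4, 3)
  p_closed <- observedPmf(th, 0.5, ymax = 40, method = "closed")
  p_quad <- observedPmf(th, 0.5, ymax = 40, method = "quadrature")
  expect_lt(max(abs(p_closed - p_quad)), 1e-10)
})

test_that("observed pmf sums to one under automatic truncation", {
  for (th in list(KineticParams(5, 3),
                  KineticParams(4, 10, k = 8, h = 4),
                  KineticParams(4, 8, k = 5, h = -4))) {
    p <- observedPmf(th, 0.5)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-7)
  }
})

test_that("quadrature pmf matches the adaptive-integration oracle", {
  for (th in list(KineticParams(6, 6, k = 10, h = 2),
                  KineticParams(3, 6, k = 4, h = -3))) {
    p <- observedPmf(th, 0.5, ymax = 30)
    p_or <- oracle_observed_pmf(th, 0.5, ymax = 30)
    expect_lt(max(abs(p - p_or)), 1e-9)
  }
})

test_that("order self-check flags nothing for a well-behaved case", {
  p <- observedPmf(KineticParams(4, 10, k = 8, h = 4), 0.5, ymax = 30,
                   check = TRUE)
  expect_false(attr(p, "orderWarning"))
})

test_that("gene pmf is the lambda = 1 observed pmf", {
  expect_equal(genePmf(KineticParams(1, 1), nmax = 3)[["0"]], 0.5)
  th <- KineticParams(6, 6, k = 10, h = 3)
  expect_equal(unname(genePmf(th, nmax = 25)),
               unname(observedPmf(th, lambda = 1, ymax = 25)))
})

test_that("closed moments match pmf moments for the NB model", {
  mm <- modelMoments(2, 3, 0.5)
  expect_equal(unname(mm), c(3, 7.5))
  p <- observedPmf(KineticParams(2, 3), 0.5)
  num <- burstfeedback:::.pmf_moments(p)
  expect_equal(unname(num), c(3, 7.5), tolerance = 1e-6)
})

test_that("invalid pmf requests error", {
  expect_error(observedPmf(KineticParams(2, 3, k = 5, h = 2),
                           method = "closed"),
               "closed form")
  expect_error(observedPmf(KineticParams(2, 3), lambda = 0))
  expect_error(observedPmf(KineticParams(2, 3), order = 5))
})
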