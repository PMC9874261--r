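# Shared oracles and fixtures for the test suite.  Everything here is
# independent of the package's quadrature path: the pmf oracle uses
# stats::integrate() on the raw integrand.

# numerically stable log(1 + exp(u))
.log1pexp <- function(u) ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u)))

# log of the unnormalized stationary kernel x^{a(1+eps)-1} e^{-x/b} H(x)
.oracle_log_kernel <- function(x, a, b, eps, k, h) {
  lH <- if (h == 0) 0 else -(a / h) * .log1pexp(h * (log(x) - log(k)))
  (a * (1 + eps) - 1) * log(x) - x / b + lH
}

# adaptive integral of exp(logf(x)) over (0, Inf), split at `split` for
# kinked integrands, with a probe-grid shift for overflow safety
.oracle_integral <- function(logf, split = NULL) {
  probe <- exp(seq(log(1e-8), log(1e4), length.out = 400))
  shift <- max(logf(probe), na.rm = TRUE)
  g <- function(x) exp(logf(x) - shift)
  tol <- 1e-11
  val <- if (is.null(split)) {
    integrate(g, 0, Inf, rel.tol = tol, abs.tol = 0)$value
  } else {
    integrate(g, 0, split, rel.tol = tol, abs.tol = 0)$value +
      integrate(g, split, Inf, rel.tol = tol, abs.tol = 0)$value
  }
  list(value = val, shift = shift)
}

# oracle for the observed-count pmf: Binomial(lambda) thinning of a
# Poisson mixture is Poisson(lambda * x), so
#   P(y) = \int Pois(y | lambda x) kernel(x) dx / \int kernel(x) dx
oracle_observed_pmf <- function(theta, lambda = 0.5, ymax) {
  a <- theta@a; b <- theta@b; eps <- theta@epsilon
  k <- if (theta@h == 0) 1 else theta@k; h <- theta@h
  split <- if (h == 0) NULL else k
  norm <- .oracle_integral(function(x)
    .oracle_log_kernel(x, a, b, eps, k, h), split)
  p <- vapply(0:ymax, function(y) {
    num <- .oracle_integral(function(x)
      dpois(y, lambda * x, log = TRUE) +
        .oracle_log_kernel(x, a, b, eps, k, h), split)
    num$value / norm$value * exp(num$shift - norm$shift)
  }, numeric(1))
  names(p) <- 0:ymax
  p
}

# negative-binomial form of the non-feedback observed pmf
oracle_nb_pmf <- function(a, b, lambda, ymax) {
  dnbinom(0:ymax, size = a, prob = 1 / (1 + b * lambda))
}

# -- frozen acceptance study conditions ------------------------------------

# six-point recovery grid: two non-feedback, two negative, two positive
acceptance_theta_grid <- function() {
  list(none_lo    = KineticParams(2, 4),
       none_hi    = KineticParams(8, 2),
       neg_strong = KineticParams(4, 10, k = 8,  h = 4),
       neg_mild   = KineticParams(6, 6,  k = 10, h = 3),
       pos_strong = KineticParams(4, 8,  k = 5,  h = -4),
       pos_mild   = KineticParams(3, 6,  k = 4,  h = -3))
}

# well-separated planted-feedback parameter sets for model selection
acceptance_planted_thetas <- function() {
  list(negative = KineticParams(4, 10, k = 8, h = 4),
       positive = KineticParams(4, 8,  k = 5, h = -4))
}

# -- toy QC fixtures with hand-computable survivor sets --------------------

# A tiny pair of allelic matrices designed so the QC outcome can be worked
# out by hand with relaxed thresholds (minCells = 2, minGenes = 2,
# minMean = 1).  Layout (genes x cells):
#   g1: high counts everywhere            -> survives both alleles
#   g2: expressed in both alleles, mean high enough on both
#   g3: expressed in only 1 cell on cast  -> fails minCells on cast
#   g4: mean below minMean on c57         -> fails minMean on c57
# cell4 on cast expresses only 1 gene     -> fails minGenes on cast
toy_allele_matrices <- function() {
  cast <- matrix(c(
    5, 6, 7, 9,    # g1
    3, 4, 2, 0,    # g2
    0, 8, 0, 0,    # g3
    2, 2, 3, 0),   # g4
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("g", 1:4), paste0("cell", 1:4)))
  c57 <- matrix(c(
    4, 5, 8, 6,    # g1
    2, 3, 3, 4,    # g2
    3, 2, 4, 2,    # g3
    1, 0, 1, 0),   # g4
    nrow = 4, byrow = TRUE,
    dimnames = list(paste0("g", 1:4), paste0("cell", 1:4)))
  list(cast = cast, c57 = c57)
}

write_toy_umi_csv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  data.table::fwrite(df, path)
  path
}
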