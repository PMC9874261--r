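#' Chi-square statistic over count categories
#'
#' \eqn{\chi^2 = \sum_k (O_k - E_k)^2 / E_k} over per-count categories.
#' The caller supplies already-pooled categories; [gofTest()] pools the
#' upper tail (model mass below \code{1e-6 * n} per count value merged
#' into the final category) before calling this.
#'
#' @param observed observed counts per category.
#' @param expected expected counts per category (all > 0, same total as
#'   \code{observed} within 1e-6).
#' @return The chi-square statistic.
#' @examples
#' chiSquareStat(c(5, 5), c(4, 6))  # 1/4 + 1/6
#' @export
chiSquareStat <- function(observed, expected) {
  if (length(observed) == 0 || length(expected) == 0)
    stop("observed and expected must be nonempty")
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (any(expected <= 0))
    stop("all expected counts must be positive (pool sparse categories)")
  if (abs(sum(observed) - sum(expected)) >
      1e-6 * max(1, abs(sum(expected))))
    stop("observed and expected totals differ")
  sum((observed - expected)^2 / expected)
}

# internal: category edges for the GOF test.  Categories are single count
# values 0, 1, ..., cut - 1 plus one pooled upper tail holding every count
# >= cut, where cut is the first value from which all per-count model
# masses fall below 1e-6 (so expected counts below 1e-6 * n are merged).
.gof_bins <- function(probs, n) {
  p <- as.numeric(probs)
  small <- p < 1e-6
  cut <- length(p)  # default: pool only the truncation remainder
  run <- rev(cumsum(rev(!small)))  # nonzero until the all-small suffix
  suffix <- which(run == 0)
  if (length(suffix)) cut <- suffix[1L] - 1L
  cut <- max(cut, 1L)
  # the pooled tail must keep positive expected mass
  repeat {
    rem <- 1 - sum(p[seq_len(cut)])
    if (rem > 1e-12 || cut == 1L) break
    cut <- cut - 1L
  }
  expected <- c(p[seq_len(cut)], max(rem, 1e-12)) * n
  list(cut = cut, expected = expected)
}

# internal: observed counts per category for the edges above
.gof_observed <- function(counts, cut) {
  capped <- pmin(counts, cut)  # counts >= cut fall into the tail category
  tabulate(capped + 1L, nbins = cut + 1L)
}

#' Monte-Carlo chi-square goodness-of-fit test
#'
#' Tests whether observed counts are consistent with the observed-count
#' model at a fitted parameter set.  The expected category counts come
#' from the model pmf (upper tail pooled where per-count model mass falls
#' below \code{1e-6 * n}).  Because cell numbers are often too small for
#' the asymptotic chi-square law, the null distribution is simulated:
#' \code{reps} datasets of the same size are drawn from the model, the
#' statistic recomputed for each, and the empirical p-value is the
#' add-one-smoothed exceedance fraction
#' \eqn{(1 + \#\{\chi^2_{sim} \ge \chi^2_{obs}\})/(reps + 1)}.  A fit
#' passes when the empirical p-value is at least 0.05, i.e. when the
#' observed statistic is exceeded by at least 5\% of the simulated ones.
#'
#' @param counts nonnegative integer vector of per-cell counts.
#' @param theta the fitted [KineticParams-class].
#' @param lambda capture probability.
#' @param reps number of Monte-Carlo null replicates (default 1000).
#' @param order quadrature order.
#' @param seed optional integer seed for the null simulation.
#' @return A [GOFResult-class] object.
#' @examples
#' th <- KineticParams(2, 3)
#' y <- sampleDataset(th, nCells = 300, seed = 1)
#' gofTest(slot(y, "counts"), th, reps = 200, seed = 2)
#' @export
gofTest <- function(counts, theta, lambda = 0.5, reps = 1000, order = 200,
                    seed = NULL) {
  stopifnot(is(theta, "KineticParams"), length(counts) > 0,
            all(counts >= 0), all(counts == round(counts)))
  if (reps < 1) stop("reps must be >= 1")
  if (!is.null(seed))
    return(withr::with_seed(seed,
      gofTest(counts, theta, lambda, reps, order)))
  n <- length(counts)
  # support must cover the observed counts and the model's own tail
  ymax <- max(.choose_ymax_auto(theta, lambda, order), max(counts))
  probs <- observedPmf(theta, lambda, ymax = ymax, order = order)
  bins <- .gof_bins(probs, n)
  obs <- .gof_observed(counts, bins$cut)
  chi2_obs <- chiSquareStat(obs, bins$expected)
  support <- seq_along(probs) - 1L
  chi2_null <- vapply(seq_len(reps), function(r) {
    sim <- sample(support, n, replace = TRUE, prob = probs)
    chiSquareStat(.gof_observed(sim, bins$cut), bins$expected)
  }, numeric(1))
  p <- (1 + sum(chi2_null >= chi2_obs)) / (reps + 1)
  new("GOFResult", chi2Obs = chi2_obs, chi2Null = chi2_null,
      empiricalP = p, pass = p >= 0.05)
}

# internal: truncation point dispatching on form
.choose_ymax_auto <- function(theta, lambda, order) {
  if (theta@h == 0) .choose_ymax_nb(theta@a, theta@b, lambda)
  else .choose_ymax(theta, lambda, order)
}

#' @describeIn gofTest empirical p-value of a result.
#' @param object a \code{GOFResult}.
#' @export
setMethod("empiricalP", "GOFResult", function(object) object@empiricalP)

#' @describeIn gofTest pass flag (\code{empiricalP >= 0.05}).
#' @export
setMethod("gofPass", "GOFResult", function(object) object@pass)

setMethod("show", "GOFResult", function(object) {
  cat(sprintf(
    "GOFResult: chi2 = %.3f, empirical p = %.4f (%d null reps) -> %s\n",
    object@chi2Obs, object@empiricalP, length(object@chi2Null),
    if (object@pass) "pass" else "fail"))
})
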