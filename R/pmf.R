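#' Generalized Gauss-Laguerre quadrature rule
#'
#' Nodes and log-weights for the weight function \eqn{t^\alpha e^{-t}} on
#' \eqn{(0, \infty)}, computed by the Golub-Welsch method (eigenvalues of
#' the Jacobi matrix of the monic generalized Laguerre recurrence, with
#' weights from the first eigenvector components).
#'
#' @param order number of nodes, >= 1.
#' @param alpha weight exponent, > -1.
#' @return A list with \code{nodes} (ascending) and \code{logw}
#'   (log weights).
#' @examples
#' r <- gaussLaguerreRule(20, 0)
#' sum(exp(r$logw))          # integrates 1 exactly: gamma(1)
#' sum(exp(r$logw) * r$nodes) # gamma(2)
#' @export
gaussLaguerreRule <- function(order, alpha) {
  stopifnot(order >= 1, alpha > -1)
  .gl_rule_cpp(as.integer(order), as.numeric(alpha))
}

#' Feedback kernel density
#'
#' Normalized density of the mixing kernel
#' \deqn{f(x) = N x^{a(1+\epsilon)-1} e^{-x/b} (1 + (x/k)^h)^{-a/h},}
#' the steady-state distribution of gene product under bursty expression
#' with Hill-type auto-regulation.  For \code{h = 0} the kernel is the
#' Gamma density with shape \code{a} and scale \code{b}.  The normalizing
#' constant is computed by the package's generalized Gauss-Laguerre rule
#' and all evaluation is carried out in log space.
#'
#' @param theta a [KineticParams-class] object.
#' @param x positive abundance value(s).
#' @param order quadrature order used for the normalizing constant.
#' @param log logical; return the log density?
#' @return Numeric vector of (log) density values.
#' @examples
#' kernelDensity(KineticParams(1, 1), 1)   # exp(-1)
#' @export
kernelDensity <- function(theta, x, order = 200, log = FALSE) {
  stopifnot(is(theta, "KineticParams"), all(x > 0))
  validObject(theta)
  if (theta@h == 0) return(dgamma(x, shape = theta@a, scale = theta@b,
                                  log = log))
  a <- theta@a; b <- theta@b; eps <- theta@epsilon; k <- theta@k; h <- theta@h
  logN <- .kernel_log_norm_cpp(a, b, eps, k, h, as.integer(order))
  u <- h * (log(x) - log(k))
  logH <- -(a / h) * ifelse(u > 0, u + log1p(exp(-u)), log1p(exp(u)))
  out <- logN + (a * (1 + eps) - 1) * log(x) - x / b + logH
  if (any(!is.finite(out)))
    stop("non-finite kernel density; parameters: a=", a, " b=", b,
         " epsilon=", eps, " k=", k, " h=", h)
  if (log) out else exp(out)
}

# internal: log pmf of observed counts for y = 0..ymax by quadrature
.observed_logpmf <- function(theta, lambda, ymax, order) {
  .observed_logpmf_cpp(as.integer(ymax), theta@a, theta@b, theta@epsilon,
                       .k_or_one(theta), theta@h, lambda, as.integer(order))
}

# internal: pick the truncation point: smallest ymax whose cumulative model
# mass reaches 1 - tail, capped at `cap` (error if the cap is hit).
.choose_ymax <- function(theta, lambda, order, tail = 1e-8, cap = 5000L) {
  mu <- lambda * theta@a * theta@b   # exact for h = 0, scale guess otherwise
  ymax <- max(20L, ceiling(4 * mu))
  repeat {
    lp <- .observed_logpmf(theta, lambda, ymax, order)
    cum <- cumsum(exp(lp))
    hit <- which(cum >= 1 - tail)
    if (length(hit)) return(hit[1L] - 1L)
    if (ymax >= cap)
      stop("could not capture 1 - ", tail, " of the model mass within ",
           cap, " counts")
    ymax <- min(cap, ymax * 2L)
  }
}

#' Observed-count probability mass function
#'
#' Distribution of the observed UMI count: the gene-level model thinned by
#' the Binomial measurement process with per-molecule capture probability
#' \code{lambda}.  Feedback forms (\code{h != 0}) are evaluated by
#' generalized Gauss-Laguerre quadrature after the change of variable
#' \eqn{t = x(\lambda + 1/b)}, with one node set per parameter vector
#' serving every count value and all node contributions accumulated with
#' log-sum-exp.  The non-feedback case has the closed form implemented in
#' [observedPmfNonfeedback()], to which \code{method = "auto"} routes it.
#'
#' @param theta a [KineticParams-class] object.
#' @param lambda capture probability in (0, 1].
#' @param ymax largest count evaluated; if \code{NULL}, the smallest value
#'   whose cumulative model mass reaches \code{1 - 1e-8}.
#' @param order quadrature order (>= 20; default 200).
#' @param method \code{"auto"} (closed form when \code{h = 0}, quadrature
#'   otherwise), or force one path.
#' @param check logical; re-evaluate at doubled order and attach an
#'   \code{orderWarning} attribute (with a warning) if any entry moves by
#'   more than 1e-7.
#' @return Named numeric vector of probabilities for counts
#'   \code{0:ymax}.
#' @examples
#' p <- observedPmf(KineticParams(1, 2), lambda = 0.5, ymax = 5)
#' p[["0"]]  # 0.5: geometric with b * lambda = 1
#' @export
observedPmf <- function(theta, lambda = 0.5, ymax = NULL, order = 200,
                        method = c("auto", "quadrature", "closed"),
                        check = FALSE) {
  stopifnot(is(theta, "KineticParams"), lambda > 0, lambda <= 1, order >= 20)
  validObject(theta)
  method <- match.arg(method)
  if (method == "closed" && theta@h != 0)
    stop("the closed form applies only to the non-feedback case h = 0")
  closed <- (method == "closed" || (method == "auto" && theta@h == 0))
  if (is.null(ymax))
    ymax <- if (closed) .choose_ymax_nb(theta@a, theta@b, lambda)
            else .choose_ymax(theta, lambda, order)
  y <- 0:ymax
  p <- if (closed) observedPmfNonfeedback(theta@a, theta@b, lambda, y)
       else exp(.observed_logpmf(theta, lambda, ymax, order))
  if (any(!is.finite(p)))
    stop("non-finite pmf values; parameters: ",
         paste(names(as.numeric(theta)), signif(as.numeric(theta), 4),
               sep = "=", collapse = " "))
  names(p) <- y
  if (check && !closed) {
    p2 <- exp(.observed_logpmf(theta, lambda, ymax, 2L * order))
    drift <- max(abs(p - p2))
    attr(p, "orderWarning") <- drift > 1e-7
    if (drift > 1e-7)
      warning("quadrature order ", order, " not self-consistent: ",
              "doubling the order moved an entry by ", signif(drift, 3))
  }
  p
}

# internal: truncation point for the closed-form NB path
.choose_ymax_nb <- function(a, b, lambda, tail = 1e-8, cap = 5000L) {
  q <- stats::qnbinom(tail, size = a, prob = 1 / (1 + b * lambda),
                      lower.tail = FALSE)
  ymax <- min(cap, q + 10L)
  # qnbinom is already exact; the small pad keeps the summed tail below
  # `tail` after cumulative rounding
  ymax
}

#' Closed-form non-feedback observed pmf
#'
#' For \code{h = 0} the kernel is Gamma(\code{a}, \code{b}) and the
#' observed count is negative binomial; the probability of count \code{y}
#' is
#' \deqn{P(y) = \frac{(b\lambda)^y}{(a+y)\,B(a, y+1)\,(b\lambda+1)^{y+a}},}
#' evaluated via log-gamma.
#'
#' @param a burst frequency, > 0.
#' @param b burst size, > 0.
#' @param lambda capture probability in (0, 1].
#' @param y nonnegative integer count(s).
#' @return Probability (vectorized over \code{y}).
#' @examples
#' observedPmfNonfeedback(1, 2, 0.5, 0)  # 0.5
#' observedPmfNonfeedback(1, 2, 0.5, 3)  # 1/16
#' @export
observedPmfNonfeedback <- function(a, b, lambda = 0.5, y) {
  stopifnot(a > 0, b > 0, lambda > 0, lambda <= 1, all(y >= 0),
            all(y == round(y)))
  exp(y * log(b * lambda) - log(a + y) - lbeta(a, y + 1) -
        (y + a) * log1p(b * lambda))
}

#' Latent gene-level pmf
#'
#' Distribution of the true (unobserved) molecule number: the observed-count
#' model with capture probability 1.
#'
#' @inheritParams observedPmf
#' @param nmax largest molecule number evaluated; \code{NULL} for automatic
#'   truncation at tail mass 1e-8.
#' @return Named numeric vector of probabilities for \code{0:nmax}.
#' @examples
#' genePmf(KineticParams(1, 1), nmax = 3)[["0"]]  # (1+b)^-a = 0.5
#' @export
genePmf <- function(theta, nmax = NULL, order = 200,
                    method = c("auto", "quadrature", "closed")) {
  observedPmf(theta, lambda = 1, ymax = nmax, order = order,
              method = method)
}

#' Moments of the observed-count model (non-feedback)
#'
#' Closed-form mean and variance of the observed count under the
#' Gamma-Poisson (non-feedback) model thinned at capture probability
#' \code{lambda}: \eqn{E[Y] = \lambda a b} and
#' \eqn{Var[Y] = \lambda a b + \lambda^2 a b^2}.
#'
#' @inheritParams observedPmfNonfeedback
#' @return Named numeric vector with \code{mean} and \code{variance}.
#' @examples
#' modelMoments(2, 3, 0.5)  # mean 3, variance 7.5
#' @export
modelMoments <- function(a, b, lambda = 0.5) {
  stopifnot(a > 0, b > 0, lambda > 0, lambda <= 1)
  c(mean = lambda * a * b, variance = lambda * a * b + lambda^2 * a * b^2)
}

# internal: mean/variance of a pmf vector over support 0..(length-1)
.pmf_moments <- function(p) {
  y <- seq_along(p) - 1
  m <- sum(p * y)
  v <- sum(p * y^2) - m^2
  c(mean = m, variance = v)
}
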