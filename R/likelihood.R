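#' Optimization bounds for the kinetic parameters
#'
#' Box constraints used by the bounded quasi-Newton fits: burst frequency
#' \code{a} in (0.1, 30), burst size \code{b} in (1, 20), binding constant
#' \code{k} in (1, 1000), Hill coefficient \code{h} in (-10, -1) for
#' positive feedback or (1, 10) for negative feedback; leakiness
#' \code{epsilon} is fixed at 0.05 and never optimized.  The non-feedback
#' model frees only \code{a} and \code{b}.
#'
#' @return A list with components \code{a}, \code{b}, \code{k},
#'   \code{h_positive}, \code{h_negative} (each \code{c(lower, upper)}) and
#'   \code{epsilon}.
#' @export
fitBounds <- function() {
  list(a = c(0.1, 30), b = c(1, 20), k = c(1, 1000),
       h_positive = c(-10, -1), h_negative = c(1, 10), epsilon = 0.05)
}

.FORMS <- c("none", "negative", "positive")

.clip <- function(x, range) min(max(x, range[1]), range[2])

#' Moment-based initial values for one restart
#'
#' Burst frequency and size start at the method-of-moments inversion of the
#' thinned-model mean and variance,
#' \eqn{a_0 = E[Y]^2/(Var[Y] - E[Y])} and
#' \eqn{b_0 = (Var[Y]/E[Y] - 1)/\lambda}, clipped into [fitBounds()].  For
#' feedback forms the Hill coefficient starts at an integer drawn uniformly
#' from \{-5..-1\} (positive feedback) or \{1..5\} (negative), and the
#' binding constant at \eqn{10^u} with \eqn{u \sim U(0, 2)}.  Underdispersed
#' or degenerate counts (variance <= mean) fall back to midpoint-of-bounds
#' starts, flagged via the \code{"fallback"} attribute.
#'
#' Draws come from the caller's RNG stream, so results are deterministic
#' under a fixed seed.
#'
#' @param counts nonnegative integer vector of per-cell counts.
#' @param lambda capture probability.
#' @param form \code{"none"}, \code{"negative"} or \code{"positive"}.
#' @param bounds bounds list, see [fitBounds()].
#' @return A [KineticParams-class] start point with attribute
#'   \code{fallback} (logical).
#' @export
initialValues <- function(counts, lambda = 0.5,
                          form = c("none", "negative", "positive"),
                          bounds = fitBounds()) {
  form <- match.arg(form)
  stopifnot(length(counts) > 0, all(counts >= 0))
  m <- mean(counts)
  v <- var(counts)
  if (length(counts) == 1L) v <- 0
  fallback <- !is.finite(m) || !is.finite(v) || m <= 0 || v <= m
  if (fallback) {
    a0 <- mean(bounds$a)
    b0 <- mean(bounds$b)
  } else {
    a0 <- .clip(m^2 / (v - m), bounds$a)
    b0 <- .clip((v / m - 1) / lambda, bounds$b)
  }
  if (form == "none") {
    theta <- KineticParams(a0, b0, epsilon = bounds$epsilon)
  } else {
    h0 <- if (form == "positive") sample(-5:-1, 1) else sample(1:5, 1)
    k0 <- 10^runif(1, 0, 2)
    theta <- KineticParams(a0, b0, epsilon = bounds$epsilon, k = k0, h = h0)
  }
  attr(theta, "fallback") <- fallback
  theta
}

#' Negative log-likelihood of observed counts
#'
#' \eqn{-\sum_i \log P(Y = y_i; \theta)} under the observed-count model,
#' evaluated by the quadrature path for feedback forms and the closed form
#' for \code{h = 0}.  Counts whose model probability underflows contribute
#' a large finite penalty (log-probability floored at \code{log(1e-300)})
#' so that optimizers can recover from pathological parameter values.
#'
#' @param theta a [KineticParams-class] object.
#' @param counts nonnegative integer vector.
#' @param lambda capture probability.
#' @param order quadrature order.
#' @return The negative log-likelihood (finite for valid inputs).
#' @examples
#' negLogLikelihood(KineticParams(1, 2), counts = c(0L), lambda = 0.5) # log 2
#' @export
negLogLikelihood <- function(theta, counts, lambda = 0.5, order = 200) {
  stopifnot(is(theta, "KineticParams"), length(counts) > 0,
            all(counts >= 0), all(counts == round(counts)))
  tab <- table(counts)
  yv <- as.integer(names(tab))
  nc <- as.numeric(tab)
  .nll_tabulated(theta, yv, nc, lambda, order)
}

# internal: nll over tabulated counts (yv unique values, nc multiplicities)
.nll_tabulated <- function(theta, yv, nc, lambda, order) {
  if (theta@h == 0) {
    lp <- log(observedPmfNonfeedback(theta@a, theta@b, lambda, yv))
    lp <- pmax(lp, log(1e-300))
    lp[!is.finite(lp)] <- log(1e-300)
    -sum(nc * lp)
  } else {
    .nll_quadrature_cpp(yv, nc, theta@a, theta@b, theta@epsilon, theta@k,
                        theta@h, lambda, as.integer(order))
  }
}

# internal: small-sample corrected AIC
.aicc <- function(nll, kpar, n) {
  2 * nll + 2 * kpar + 2 * kpar * (kpar + 1) / (n - kpar - 1)
}

# internal: one bounded quasi-Newton fit from a given start.
# k is optimized on the log10 scale for conditioning; h, a, b on the raw
# scale.  Returns a one-row data.frame.
.fit_one <- function(yv, nc, n, start, form, lambda, order, bounds,
                     boundaryTol) {
  feedback <- form != "none"
  eps <- bounds$epsilon
  if (feedback) {
    hb <- if (form == "positive") bounds$h_positive else bounds$h_negative
    lower <- c(bounds$a[1], bounds$b[1], log10(bounds$k[1]), hb[1])
    upper <- c(bounds$a[2], bounds$b[2], log10(bounds$k[2]), hb[2])
    par0 <- c(start@a, start@b, log10(start@k), start@h)
    fn <- function(p) {
      .nll_quadrature_cpp(yv, nc, p[1], p[2], eps, 10^p[3], p[4], lambda,
                          as.integer(order))
    }
    # Central-difference gradient evaluated with the quadrature rule of the
    # base point's weight exponent frozen: perturbing the burst frequency
    # then no longer forces a rule rebuild, which dominates the fit cost.
    alpha_of <- if (form == "positive") function(a) a * eps - 1
                else function(a) a * (1 + eps) - 1
    steps <- 1e-4 * (upper - lower)
    gr <- function(p) {
      ar <- alpha_of(p[1])
      g <- numeric(4L)
      for (j in 1:4) {
        pp <- p; pm <- p
        pp[j] <- p[j] + steps[j]
        pm[j] <- p[j] - steps[j]
        g[j] <- (.nll_quadrature_cpp(yv, nc, pp[1], pp[2], eps, 10^pp[3],
                                     pp[4], lambda, as.integer(order), ar) -
                   .nll_quadrature_cpp(yv, nc, pm[1], pm[2], eps, 10^pm[3],
                                       pm[4], lambda, as.integer(order),
                                       ar)) / (2 * steps[j])
      }
      g
    }
  } else {
    lower <- c(bounds$a[1], bounds$b[1])
    upper <- c(bounds$a[2], bounds$b[2])
    par0 <- c(start@a, start@b)
    fn <- function(p) {
      lp <- log(observedPmfNonfeedback(p[1], p[2], lambda, yv))
      lp[!is.finite(lp) | lp < log(1e-300)] <- log(1e-300)
      -sum(nc * lp)
    }
    gr <- NULL
  }
  par0 <- pmin(pmax(par0, lower), upper)
  res <- tryCatch(
    optim(par0, fn, gr = gr, method = "L-BFGS-B", lower = lower,
          upper = upper, control = list(maxit = 200, factr = 1e8)),
    error = function(e) NULL)
  if (is.null(res)) {
    return(data.frame(form = form, a = NA_real_, b = NA_real_,
                      k = NA_real_, h = if (feedback) NA_real_ else 0,
                      nll = NA_real_, converged = FALSE, on_boundary = TRUE,
                      aicc = NA_real_))
  }
  rel <- (res$par - lower) / (upper - lower)
  on_boundary <- any(rel < boundaryTol | rel > 1 - boundaryTol)
  kpar <- if (feedback) 4L else 2L
  data.frame(form = form,
             a = res$par[1], b = res$par[2],
             k = if (feedback) 10^res$par[3] else NA_real_,
             h = if (feedback) res$par[4] else 0,
             nll = res$value,
             converged = res$convergence == 0,
             on_boundary = on_boundary,
             aicc = .aicc(res$value, kpar, n))
}

#' Multi-restart maximum-likelihood fits for one gene
#'
#' For each requested feedback form, repeatedly solves the bounded
#' likelihood optimization from randomized moment-based starts (default 30
#' restarts per form, giving 90 fits over the three forms).  The first
#' restart of each form uses the moment start unchanged; later restarts
#' jitter the burst frequency and size by a factor uniform in [0.8, 1.2]
#' and redraw the Hill coefficient and binding constant.  Optimizer
#' failures are recorded as non-converged rows, never raised.
#'
#' @param counts nonnegative integer vector of per-cell counts.
#' @param lambda capture probability.
#' @param forms feedback forms to fit (default all three).
#' @param restarts restarts per form.
#' @param order quadrature order for the feedback likelihoods.
#' @param bounds bounds list, see [fitBounds()].
#' @param boundaryTol a fit is flagged \code{on_boundary} when any free
#'   parameter ends within this relative distance of a bound in
#'   normalized [0, 1] coordinates.
#' @param seed optional integer; when given, the whole set of restarts is
#'   reproducible (the caller's RNG state is restored afterwards).
#' @return A data.frame with one row per restart and columns \code{form},
#'   \code{restart}, \code{a}, \code{b}, \code{k}, \code{h}, \code{nll},
#'   \code{converged}, \code{on_boundary}, \code{init_fallback},
#'   \code{degenerate}, \code{aicc}; the number of cells is attached as
#'   attribute \code{n_cells}.
#' @seealso [selectModel()] to pick the best form by AICc.
#' @export
fitGene <- function(counts, lambda = 0.5, forms = .FORMS, restarts = 30,
                    order = 200, bounds = fitBounds(), boundaryTol = 1e-3,
                    seed = NULL) {
  stopifnot(length(counts) > 0, all(counts >= 0),
            all(counts == round(counts)), restarts >= 1)
  forms <- match.arg(forms, .FORMS, several.ok = TRUE)
  if (!is.null(seed))
    return(withr::with_seed(seed,
      fitGene(counts, lambda, forms, restarts, order, bounds, boundaryTol)))
  tab <- table(counts)
  yv <- as.integer(names(tab))
  nc <- as.numeric(tab)
  n <- length(counts)
  degenerate <- length(yv) == 1L
  rows <- vector("list", length(forms) * restarts)
  i <- 0L
  for (form in forms) {
    for (r in seq_len(restarts)) {
      start <- initialValues(counts, lambda, form, bounds)
      if (r > 1L) {
        a0 <- .clip(start@a * runif(1, 0.8, 1.2), bounds$a)
        b0 <- .clip(start@b * runif(1, 0.8, 1.2), bounds$b)
        start <- KineticParams(a0, b0, epsilon = bounds$epsilon,
                               k = start@k, h = start@h)
      }
      fit <- .fit_one(yv, nc, n, start, form, lambda, order, bounds,
                      boundaryTol)
      fit$restart <- r
      fit$init_fallback <- isTRUE(attr(start, "fallback"))
      i <- i + 1L
      rows[[i]] <- fit
    }
  }
  out <- do.call(rbind, rows)
  out$degenerate <- degenerate
  out <- out[, c("form", "restart", "a", "b", "k", "h", "nll", "converged",
                 "on_boundary", "init_fallback", "degenerate", "aicc")]
  attr(out, "n_cells") <- n
  attr(out, "lambda") <- lambda
  out
}

#' AICc model selection across feedback forms
#'
#' Removes boundary-flagged and non-converged fits, keeps the minimum-AICc
#' survivor of each form, and selects the form with the globally smallest
#' AICc, where \eqn{AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)} with \code{k}
#' free parameters (2 for the non-feedback model, 4 for feedback forms;
#' the fixed leakiness is never counted).  Exact AICc ties break toward
#' the model with fewer parameters (\code{none}, then \code{negative},
#' then \code{positive}).
#'
#' @param fits a data.frame from [fitGene()].
#' @param n number of cells; defaults to the \code{n_cells} attribute of
#'   \code{fits}.
#' @param gene optional gene identifier carried into the result.
#' @return A [GeneInference-class] object; when every fit of every form is
#'   filtered out the gene is marked unclassifiable.
#' @export
selectModel <- function(fits, n = attr(fits, "n_cells"), gene = NA_character_) {
  stopifnot(is.data.frame(fits), !is.null(n))
  kpar <- ifelse(fits$form == "none", 2L, 4L)
  if (any(n <= kpar + 1))
    stop("sample size n must exceed the parameter count + 1 for AICc")
  keep <- fits[fits$converged & !fits$on_boundary & is.finite(fits$aicc), ,
               drop = FALSE]
  if (nrow(keep) == 0) {
    return(new("GeneInference", gene = as.character(gene),
               selectedForm = NA_character_, theta = new("KineticParams"),
               bestFits = fits[0, ], aicc = numeric(), nll = NA_real_,
               nCells = as.integer(n), unclassifiable = TRUE))
  }
  best <- do.call(rbind, lapply(split(keep, keep$form), function(d) {
    d[which.min(d$aicc), , drop = FALSE]
  }))
  # simplicity-ordered tie-break: none < negative < positive
  best <- best[order(match(best$form, .FORMS)), , drop = FALSE]
  sel <- best[which.min(best$aicc), , drop = FALSE]
  eps <- if (!is.null(attr(fits, "epsilon"))) attr(fits, "epsilon") else 0.05
  theta <- KineticParams(sel$a, sel$b, epsilon = eps,
                         k = if (sel$form == "none") NA_real_ else sel$k,
                         h = sel$h)
  aicc <- setNames(best$aicc, best$form)
  new("GeneInference", gene = as.character(gene),
      selectedForm = sel$form, theta = theta, bestFits = best,
      aicc = aicc, nll = sel$nll, nCells = as.integer(n),
      unclassifiable = FALSE)
}

#' @describeIn selectModel selected feedback form.
#' @param object a \code{GeneInference} object.
#' @export
setMethod("selectedForm", "GeneInference", function(object) object@selectedForm)

#' @describeIn selectModel selected parameter set.
#' @export
setMethod("selectedParams", "GeneInference", function(object) object@theta)

setMethod("show", "GeneInference", function(object) {
  cat("GeneInference for", object@gene, "\n")
  if (object@unclassifiable) {
    cat("  unclassifiable: no converged non-boundary fit survived\n")
    return(invisible(NULL))
  }
  cat("  selected form:", object@selectedForm, "\n")
  cat("  AICc:", paste(sprintf("%s=%.2f", names(object@aicc), object@aicc),
                       collapse = ", "), "\n")
  show(object@theta)
})
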