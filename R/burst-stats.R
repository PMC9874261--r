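#' Model-based expression variability statistics
#'
#' Mean, squared coefficient of variation
#' \eqn{CV^2 = Var[Y;\theta] / E[Y;\theta]^2} and residual variability
#' \eqn{rCV^2 = CV^2 - 1/\log_2(\mu)} of the observed-count model at a
#' fitted parameter set.  The non-feedback moments are closed form
#' (\eqn{E[Y] = \lambda ab}, \eqn{Var[Y] = \lambda ab + \lambda^2 ab^2});
#' feedback forms use numerical moments of the quadrature pmf.  The
#' residual term subtracts the inverse log2 mean to decouple variability
#' from expression level; it is undefined (NA) when the mean is at or
#' below 1.
#'
#' @param theta a [KineticParams-class] object.
#' @param lambda capture probability.
#' @param order quadrature order.
#' @return Named numeric vector \code{c(mean, cv2, rcv2)}.
#' @examples
#' cv2AndRcv2(KineticParams(2, 3))  # mean 3, cv2 = 7.5/9
#' @export
cv2AndRcv2 <- function(theta, lambda = 0.5, order = 200) {
  stopifnot(is(theta, "KineticParams"))
  if (theta@h == 0) {
    mm <- modelMoments(theta@a, theta@b, lambda)
  } else {
    p <- observedPmf(theta, lambda, order = order)
    mm <- .pmf_moments(p)
  }
  mu <- mm[["mean"]]
  cv2 <- mm[["variance"]] / mu^2
  rcv2 <- if (mu > 1) cv2 - 1 / log2(mu) else NA_real_
  c(mean = mu, cv2 = cv2, rcv2 = rcv2)
}

#' Per-gene burst statistics table
#'
#' Joins the genome-wide fit results with model-based variability
#' statistics and optional promoter-architecture annotations into the
#' tidy per-gene table used by the downstream regressions.  Burst
#' frequency is the fitted \code{a} and burst size the fitted \code{b}.
#'
#' @param fitTable data.frame from [fitBurstKinetics()].
#' @param annotations optional data.frame with a \code{gene_id} column and
#'   covariates (e.g. 0/1 motif flags \code{TATA}, \code{Inr},
#'   \code{CCAAT}, \code{GC}, \code{promoter_width_bp},
#'   \code{ep_intensity}); left-joined on gene.  A \code{tss_class}
#'   column (\code{"sharp"} when the promoter width is below
#'   \code{sharpWidth}) is added when \code{promoter_width_bp} exists.
#' @param lambda capture probability used in the fits.
#' @param order quadrature order.
#' @param gofOnly keep only genes whose goodness-of-fit test passed
#'   (requires \code{gof_pass} in \code{fitTable}).
#' @param sharpWidth TSS-width threshold (bp) separating sharp from broad
#'   promoters.
#' @return A data.frame with one row per classified gene: \code{gene},
#'   \code{feedback}, \code{bf}, \code{bs}, \code{mean}, \code{cv2},
#'   \code{rcv2} and any annotation columns.
#' @export
burstStatsTable <- function(fitTable, annotations = NULL, lambda = 0.5,
                            order = 200, gofOnly = FALSE, sharpWidth = 15) {
  stopifnot(is.data.frame(fitTable))
  tab <- fitTable[!fitTable$unclassifiable, , drop = FALSE]
  if (gofOnly) {
    if (!"gof_pass" %in% names(tab))
      stop("gofOnly = TRUE requires a gof_pass column ",
           "(run fitBurstKinetics with gof = TRUE)")
    tab <- tab[!is.na(tab$gof_pass) & tab$gof_pass, , drop = FALSE]
  }
  stats <- t(vapply(seq_len(nrow(tab)), function(i) {
    th <- KineticParams(tab$a[i], tab$b[i],
                        k = if (tab$form[i] == "none") NA_real_
                            else tab$k[i],
                        h = tab$h[i])
    cv2AndRcv2(th, lambda, order)
  }, numeric(3)))
  out <- data.frame(gene = tab$gene,
                    feedback = factor(tab$form,
                                      levels = c("none", "negative",
                                                 "positive")),
                    bf = tab$a, bs = tab$b,
                    mean = stats[, "mean"], cv2 = stats[, "cv2"],
                    rcv2 = stats[, "rcv2"])
  if (!is.null(annotations)) {
    if (!"gene_id" %in% names(annotations))
      stop("annotations need a gene_id column")
    if ("promoter_width_bp" %in% names(annotations) &&
        !"tss_class" %in% names(annotations))
      annotations$tss_class <- ifelse(
        annotations$promoter_width_bp < sharpWidth, "sharp", "broad")
    out <- merge(out, annotations, by.x = "gene", by.y = "gene_id",
                 all.x = TRUE, sort = FALSE)
  }
  out
}

#' Promoter-architecture regression with interaction terms
#'
#' Ordinary least squares of a burst statistic on the promoter motif flags
#' with the model formula
#' \code{response ~ (TATA * Inr + CCAAT * GC) * feedback}: main effects of
#' the four motifs, the TATA:Inr and CCAAT:GC interactions, all crossed
#' with the three-level feedback factor (reference level \code{"none"}).
#' The reported t-values are the coefficient tests of the fit.  Terms
#' dropped for rank deficiency (e.g. a motif constant within a feedback
#' level) are returned with an \code{aliased} flag rather than silently
#' omitted.
#'
#' @param stats per-gene table from [burstStatsTable()] containing the
#'   motif columns and \code{feedback}.
#' @param response \code{"rcv2"}, \code{"log10_bf"} or \code{"log10_bs"}.
#' @return A data.frame with columns \code{term}, \code{estimate},
#'   \code{std_error}, \code{t_value}, \code{aliased}.
#' @export
regressionTvalues <- function(stats,
                              response = c("rcv2", "log10_bf", "log10_bs")) {
  response <- match.arg(response)
  need <- c("TATA", "Inr", "CCAAT", "GC", "feedback")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  stats$feedback <- droplevels(factor(stats$feedback))
  if ("none" %in% levels(stats$feedback))
    stats$feedback <- stats::relevel(stats$feedback, ref = "none")
  d <- stats
  d$.resp <- switch(response,
                    rcv2 = d$rcv2,
                    log10_bf = log10(d$bf),
                    log10_bs = log10(d$bs))
  d <- d[is.finite(d$.resp), , drop = FALSE]
  if (nrow(d) == 0) stop("no finite response values")
  one_level <- length(unique(d$feedback)) < 2
  form <- if (one_level) .resp ~ (TATA * Inr + CCAAT * GC)
          else .resp ~ (TATA * Inr + CCAAT * GC) * feedback
  fit <- lm(form, data = d)
  sm <- summary(fit)$coefficients
  all_terms <- names(coef(fit))
  out <- data.frame(term = all_terms,
                    estimate = coef(fit)[all_terms],
                    std_error = NA_real_, t_value = NA_real_,
                    aliased = !(all_terms %in% rownames(sm)) |
                              is.na(coef(fit)[all_terms]))
  ok <- intersect(all_terms, rownames(sm))
  out[match(ok, out$term), "std_error"] <- sm[ok, "Std. Error"]
  out[match(ok, out$term), "t_value"] <- sm[ok, "t value"]
  rownames(out) <- NULL
  out
}
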