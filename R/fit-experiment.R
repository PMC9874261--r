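#' Genome-wide burst-kinetics inference
#'
#' Runs the per-gene multi-restart fits ([fitGene()]), AICc model
#' selection ([selectModel()]) and optionally the Monte-Carlo
#' goodness-of-fit test ([gofTest()]) over every gene of a counts matrix
#' or \code{SummarizedExperiment}.  A logical \code{"keep"} assay (as
#' produced by [qcPipeline()]) restricts each gene's fit to its unmasked
#' cells.  Per-gene failures are recorded in the table and do not abort
#' the run.
#'
#' @param object a genes x cells integer matrix or
#'   \code{SummarizedExperiment} with assay \code{"counts"} (and optional
#'   logical assay \code{"keep"}).
#' @param lambda capture probability.
#' @param restarts optimizer restarts per feedback form.
#' @param order quadrature order.
#' @param gof logical; run the goodness-of-fit test on each selected fit?
#' @param gofReps Monte-Carlo replicates for the test.
#' @param seed master seed; per-gene seeds are derived from it.
#' @param verbose print one line per 100 genes.
#' @return A data.frame with one row per gene: \code{gene},
#'   \code{n_cells}, \code{form}, the selected parameters (\code{a},
#'   \code{b}, \code{k}, \code{h}), \code{nll}, per-form AICc columns,
#'   \code{unclassifiable}, and (with \code{gof = TRUE})
#'   \code{gof_chi2}, \code{gof_p}, \code{gof_pass}.
#' @export
fitBurstKinetics <- function(object, lambda = 0.5, restarts = 30,
                             order = 200, gof = FALSE, gofReps = 1000,
                             seed = 1, verbose = FALSE) {
  counts <- if (is.matrix(object)) object
            else SummarizedExperiment::assay(object, "counts")
  keep <- NULL
  if (!is.matrix(object) &&
      "keep" %in% SummarizedExperiment::assayNames(object))
    keep <- SummarizedExperiment::assay(object, "keep")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  rows <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    gene <- rownames(counts)[i]
    y <- counts[i, ]
    if (!is.null(keep)) y <- y[keep[i, ]]
    gs <- .derive_seed(seed, i)
    row <- data.frame(gene = gene, n_cells = length(y),
                      form = NA_character_, a = NA_real_, b = NA_real_,
                      k = NA_real_, h = NA_real_, nll = NA_real_,
                      aicc_none = NA_real_, aicc_negative = NA_real_,
                      aicc_positive = NA_real_, unclassifiable = TRUE)
    res <- tryCatch({
      fits <- fitGene(y, lambda = lambda, restarts = restarts,
                      order = order, seed = gs)
      inf <- selectModel(fits, gene = gene)
      if (!inf@unclassifiable) {
        th <- inf@theta
        row$form <- inf@selectedForm
        row$a <- th@a; row$b <- th@b
        row$k <- th@k; row$h <- th@h
        row$nll <- inf@nll
        for (f in names(inf@aicc))
          row[[paste0("aicc_", f)]] <- inf@aicc[[f]]
        row$unclassifiable <- FALSE
        if (gof) {
          g <- gofTest(y, th, lambda = lambda, reps = gofReps,
                       order = order, seed = gs + 1L)
          row$gof_chi2 <- g@chi2Obs
          row$gof_p <- g@empiricalP
          row$gof_pass <- g@pass
        }
      } else if (gof) {
        row$gof_chi2 <- NA_real_; row$gof_p <- NA_real_; row$gof_pass <- NA
      }
      row
    }, error = function(e) {
      if (gof) {
        row$gof_chi2 <- NA_real_; row$gof_p <- NA_real_; row$gof_pass <- NA
      }
      row
    })
    rows[[i]] <- res
    if (verbose && i %% 100 == 0)
      message("fitted ", i, "/", nrow(counts), " genes")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  out
}
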