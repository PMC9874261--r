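#' Kinetic parameters of the feedback-aware burst model
#'
#' The steady-state gene-product distribution is a Poisson mixture over the
#' kernel density
#' \deqn{f(x) \propto x^{a(1+\epsilon)-1} e^{-x/b} (1 + (x/k)^h)^{-a/h},}
#' whose parameters are the burst frequency \code{a} (bursts per cell
#' cycle), burst size \code{b} (mean products per burst), promoter
#' leakiness proportion \code{epsilon}, equilibrium binding constant
#' \code{k} (molecules) and Hill coefficient \code{h}.  The sign of
#' \code{h} encodes the feedback form: \code{h < 0} positive feedback,
#' \code{h > 0} negative feedback, \code{h = 0} the non-feedback
#' (Gamma-Poisson, i.e. negative binomial) limit, in which case \code{k}
#' is unused and may be \code{NA}.
#'
#' @slot a numeric(1), burst frequency, > 0.
#' @slot b numeric(1), burst size, > 0.
#' @slot epsilon numeric(1), leakiness proportion in [0, 1).
#' @slot k numeric(1), binding constant, > 0 (or \code{NA} when
#'   \code{h = 0}).
#' @slot h numeric(1), Hill coefficient.
#'
#' @seealso [KineticParams()] for the user-facing constructor,
#'   [feedbackForm()], [observedPmf()].
#' @exportClass KineticParams
setClass("KineticParams",
  representation(a = "numeric", b = "numeric", epsilon = "numeric",
                 k = "numeric", h = "numeric"),
  prototype(a = 1, b = 1, epsilon = 0.05, k = NA_real_, h = 0)
)

setValidity("KineticParams", function(object) {
  msg <- character()
  for (s in c("a", "b", "epsilon", "k", "h"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("slot '%s' must have length 1", s))
  if (length(msg)) return(msg)
  if (!is.finite(object@a) || object@a <= 0)
    msg <- c(msg, "burst frequency 'a' must be > 0")
  if (!is.finite(object@b) || object@b <= 0)
    msg <- c(msg, "burst size 'b' must be > 0")
  if (!is.finite(object@epsilon) || object@epsilon < 0 || object@epsilon >= 1)
    msg <- c(msg, "leakiness 'epsilon' must lie in [0, 1)")
  if (!is.finite(object@h))
    msg <- c(msg, "Hill coefficient 'h' must be finite")
  if (length(msg) == 0 && object@h != 0 &&
      (!is.finite(object@k) || object@k <= 0))
    msg <- c(msg, "binding constant 'k' must be > 0 for feedback models")
  if (length(msg) == 0 && object@h < 0 && object@epsilon == 0)
    msg <- c(msg,
      "positive feedback (h < 0) requires epsilon > 0 for an integrable kernel")
  if (length(msg)) msg else TRUE
})

#' Per-gene model selection result
#'
#' Holds the outcome of fitting all requested feedback forms to one gene's
#' counts and selecting among them by AICc after removing boundary-flagged
#' and non-converged fits.
#'
#' @slot gene character(1) gene identifier.
#' @slot selectedForm character(1), one of \code{"positive"},
#'   \code{"negative"}, \code{"none"}, or \code{NA} when no reliable fit
#'   survived filtering.
#' @slot theta the selected [KineticParams-class], meaningful only when
#'   \code{unclassifiable} is \code{FALSE}.
#' @slot bestFits data.frame with the minimum-AICc surviving fit per form.
#' @slot aicc named numeric, AICc of the best surviving fit per form.
#' @slot nll numeric(1), negative log-likelihood of the selected fit.
#' @slot nCells integer(1), number of cells used.
#' @slot unclassifiable logical(1), \code{TRUE} when every fit of every
#'   form was filtered out.
#'
#' @seealso [selectModel()], [fitGene()].
#' @exportClass GeneInference
setClass("GeneInference",
  representation(gene = "character", selectedForm = "character",
                 theta = "KineticParams", bestFits = "data.frame",
                 aicc = "numeric", nll = "numeric", nCells = "integer",
                 unclassifiable = "logical"),
  prototype(gene = NA_character_, selectedForm = NA_character_,
            aicc = numeric(), nll = NA_real_, nCells = NA_integer_,
            unclassifiable = TRUE)
)

#' Monte-Carlo chi-square goodness-of-fit result
#'
#' @slot chi2Obs numeric(1), observed chi-square statistic.
#' @slot chi2Null numeric, simulated null statistics.
#' @slot empiricalP numeric(1), add-one-smoothed empirical p-value,
#'   \code{(1 + #\{chi2Null >= chi2Obs\}) / (reps + 1)}.
#' @slot pass logical(1), \code{TRUE} iff \code{empiricalP >= 0.05}.
#'
#' @seealso [gofTest()].
#' @exportClass GOFResult
setClass("GOFResult",
  representation(chi2Obs = "numeric", chi2Null = "numeric",
                 empiricalP = "numeric", pass = "logical")
)

setValidity("GOFResult", function(object) {
  if (length(object@empiricalP) == 1 &&
      (object@empiricalP < 0 || object@empiricalP > 1))
    return("empiricalP must lie in [0, 1]")
  TRUE
})

#' Synthetic single-cell UMI dataset for one gene
#'
#' Ground-truth counts drawn from the observed-count distribution of a
#' known parameter set, used by the validation and robustness studies.
#'
#' @slot counts integer vector of per-cell UMI counts.
#' @slot theta the generating [KineticParams-class].
#' @slot lambda numeric(1), per-molecule capture probability used.
#' @slot seed numeric(1), seed the draw was made with (\code{NA} if none).
#'
#' @seealso [sampleDataset()], [applyDropout()].
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
  representation(counts = "integer", theta = "KineticParams",
                 lambda = "numeric", seed = "numeric")
)
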