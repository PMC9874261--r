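#' Construct a kinetic parameter set
#'
#' @param a burst frequency (bursts per cell cycle), > 0.
#' @param b burst size (mean products per burst), > 0.
#' @param epsilon promoter leakiness proportion in [0, 1); the inference
#'   fixes it at 0.05.
#' @param k equilibrium binding constant (molecules), > 0; unused (may be
#'   \code{NA}) in the non-feedback case \code{h = 0}.
#' @param h Hill coefficient; \code{h < 0} positive feedback, \code{h > 0}
#'   negative feedback, \code{h = 0} non-feedback.
#'
#' @return A validated [KineticParams-class] object.
#' @examples
#' KineticParams(a = 2, b = 5, k = 50, h = 3)   # negative feedback
#' KineticParams(a = 5, b = 3)                  # non-feedback
#' @export
KineticParams <- function(a, b, epsilon = 0.05, k = NA_real_, h = 0) {
  new("KineticParams", a = as.numeric(a), b = as.numeric(b),
      epsilon = as.numeric(epsilon), k = as.numeric(k), h = as.numeric(h))
}

#' @describeIn KineticParams burst frequency \code{a}.
#' @param object a \code{KineticParams} object.
#' @export
setMethod("burstFrequency", "KineticParams", function(object) object@a)

#' @describeIn KineticParams burst size \code{b}.
#' @export
setMethod("burstSize", "KineticParams", function(object) object@b)

#' @describeIn KineticParams leakiness proportion \code{epsilon}.
#' @export
setMethod("leakiness", "KineticParams", function(object) object@epsilon)

#' @describeIn KineticParams binding constant \code{k}.
#' @export
setMethod("bindingConstant", "KineticParams", function(object) object@k)

#' @describeIn KineticParams Hill coefficient \code{h}.
#' @export
setMethod("hillCoefficient", "KineticParams", function(object) object@h)

#' @describeIn KineticParams feedback form implied by \code{sign(h)}.
#' @export
setMethod("feedbackForm", "KineticParams", function(object) {
  if (object@h < 0) "positive" else if (object@h > 0) "negative" else "none"
})

setMethod("show", "KineticParams", function(object) {
  form <- feedbackForm(object)
  cat("KineticParams (", form, " feedback)\n", sep = "")
  cat(sprintf("  burst frequency a = %.4g, burst size b = %.4g\n",
              object@a, object@b))
  cat(sprintf("  leakiness epsilon = %.3g", object@epsilon))
  if (form != "none")
    cat(sprintf(", binding constant k = %.4g, Hill h = %.4g", object@k,
                object@h))
  cat("\n")
})

#' @describeIn KineticParams coerce to a named numeric vector.
#' @param x a \code{KineticParams} object.
#' @param ... unused.
#' @export
setMethod("as.numeric", "KineticParams", function(x, ...) {
  c(a = x@a, b = x@b, epsilon = x@epsilon, k = x@k, h = x@h)
})

# internal: k value that is safe to hand to the C++ evaluators when h == 0
.k_or_one <- function(theta) if (theta@h == 0) 1 else theta@k
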