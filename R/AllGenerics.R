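#' @name burstfeedback-generics
#' @title Accessor generics
#' @description Accessors for the S4 result classes.  \code{burstFrequency}
#'   and \code{burstSize} return the kinetic parameters \code{a} and
#'   \code{b}; \code{feedbackForm} maps the sign of the Hill coefficient to
#'   \code{"positive"}, \code{"negative"} or \code{"none"};
#'   \code{empiricalP} and \code{gofPass} extract the Monte-Carlo
#'   goodness-of-fit outcome.
#' @param object an object of the documented classes.
#' @return An atomic vector of length one (or the documented slot value).
NULL

#' @rdname burstfeedback-generics
#' @export
setGeneric("burstFrequency", function(object) standardGeneric("burstFrequency"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("burstSize", function(object) standardGeneric("burstSize"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("leakiness", function(object) standardGeneric("leakiness"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("bindingConstant", function(object) standardGeneric("bindingConstant"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("hillCoefficient", function(object) standardGeneric("hillCoefficient"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("feedbackForm", function(object) standardGeneric("feedbackForm"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("selectedForm", function(object) standardGeneric("selectedForm"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("selectedParams", function(object) standardGeneric("selectedParams"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("empiricalP", function(object) standardGeneric("empiricalP"))

#' @rdname burstfeedback-generics
#' @export
setGeneric("gofPass", function(object) standardGeneric("gofPass"))
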