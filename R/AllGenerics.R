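#' @rdname GenoSurvExperiment-class
#' @param x,object a \code{GenoSurvExperiment} (or, for
#'   \code{martingaleResiduals}, a \code{CoxNullFit}).
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname GenoSurvExperiment-class
#' @export
setGeneric("eventTime", function(x) standardGeneric("eventTime"))

#' @rdname GenoSurvExperiment-class
#' @export
setGeneric("eventStatus", function(x) standardGeneric("eventStatus"))

#' @rdname GenoSurvExperiment-class
#' @export
setGeneric("covariateMatrix", function(x) standardGeneric("covariateMatrix"))

#' @rdname GenoSurvExperiment-class
#' @export
setGeneric("snpMAF", function(x) standardGeneric("snpMAF"))

#' @rdname fitCoxNull
#' @export
setGeneric("fitCoxNull", function(x, ...) standardGeneric("fitCoxNull"))

#' @rdname martingaleResiduals
#' @export
setGeneric("martingaleResiduals",
           function(object, ...) standardGeneric("martingaleResiduals"))

#' @rdname esmdrSearch
#' @export
setGeneric("esmdrSearch", function(x, ...) standardGeneric("esmdrSearch"))

#' @rdname survmdrSearch
#' @export
setGeneric("survmdrSearch", function(x, ...) standardGeneric("survmdrSearch"))

#' @rdname MDRResult-class
#' @param x an \code{MDRResult}.
#' @export
setGeneric("bestModel", function(x, ...) standardGeneric("bestModel"))

#' @rdname MDRResult-class
#' @export
setGeneric("topModels", function(x, ...) standardGeneric("topModels"))
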