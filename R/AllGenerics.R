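#' @rdname BinaryMask-class
#' @param x a \code{BinaryMask} (or, for constructors, raw input).
#' @export
setGeneric("maskGrid", function(x) standardGeneric("maskGrid"))

#' @rdname BinaryMask-class
#' @export
setGeneric("positiveCount", function(x) standardGeneric("positiveCount"))

#' @rdname MetricConfig-class
#' @param object an object.
#' @export
setGeneric("nEnvironments", function(object) standardGeneric("nEnvironments"))

#' @rdname MetricConfig-class
#' @export
setGeneric("environmentWeights",
           function(object) standardGeneric("environmentWeights"))

#' @rdname MetricConfig-class
#' @export
setGeneric("connectivity", function(object) standardGeneric("connectivity"))

#' @rdname MetricConfig-class
#' @export
setGeneric("ldcEnvIndex", function(object) standardGeneric("ldcEnvIndex"))

#' @rdname EnvironmentStack-class
#' @param object an object.
#' @export
setGeneric("environmentRings",
           function(object) standardGeneric("environmentRings"))

#' @rdname EnvironmentStack-class
#' @export
setGeneric("weightMap", function(object) standardGeneric("weightMap"))

#' @rdname EnvironmentStack-class
#' @export
setGeneric("weightSum", function(object) standardGeneric("weightSum"))

#' @rdname MetricResult-class
#' @param object an object.
#' @export
setGeneric("metricValue", function(object) standardGeneric("metricValue"))

#' @rdname MetricResult-class
#' @export
setGeneric("metricName", function(object) standardGeneric("metricName"))

#' @rdname MetricResult-class
#' @export
setGeneric("degenerateFlag",
           function(object) standardGeneric("degenerateFlag"))

#' @rdname TestResult-class
#' @param object an object.
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname TestResult-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname TestResult-class
#' @export
setGeneric("pValueFdr", function(object) standardGeneric("pValueFdr"))
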