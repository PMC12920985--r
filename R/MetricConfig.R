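#' Configure the distance-aware Dice coefficients
#'
#' The default parameterisation uses three nested environments with
#' weights 0.7, 0.5, 0.3 (a simple, symmetric division of the unit
#' interval), edge-sharing connectivity (4-neighbourhood in 2-D,
#' face-sharing 6-neighbourhood in 3-D), and the outermost environment
#' \eqn{X_3} as the LDC tolerance region.
#'
#' Weights must decrease strictly within (0, 1): the range proof of the
#' weighted coefficient depends on \eqn{0 < \nu_n < \ldots < \nu_1 < 1},
#' so violations are rejected rather than reordered. \code{nEnv = 0}
#' (no environments, no weights) is allowed and makes the WDC identical
#' to the plain Dice coefficient.
#'
#' @param nEnv number of dilation environments \eqn{n}.
#' @param weights ring weights \eqn{\nu_1, \ldots, \nu_n}.
#' @param connectivity \code{"edge"} or \code{"full"}; one dilation step
#'   grows the set by the chosen neighbourhood.
#' @param ldcEnvIndex which environment is \eqn{X^*} in the LDC loss term;
#'   defaults to the outermost (\code{nEnv}).
#' @return a [MetricConfig-class].
#' @examples
#' MetricConfig()                       # the default: n = 3, 0.7/0.5/0.3
#' MetricConfig(nEnv = 0)               # degenerates WDC to DSC
#' MetricConfig(weights = c(0.8, 0.4, 0.2))
#' @export
MetricConfig <- function(nEnv = 3L,
                         weights = c(0.7, 0.5, 0.3)[seq_len(nEnv)],
                         connectivity = c("edge", "full"),
                         ldcEnvIndex = nEnv) {
  nEnv <- as.integer(nEnv)
  if (nEnv == 0L && missing(weights)) weights <- numeric(0)
  connectivity <- match.arg(connectivity)
  new("MetricConfig", nEnv = nEnv, weights = as.numeric(weights),
      connectivity = connectivity, ldcEnvIndex = as.integer(ldcEnvIndex))
}

#' @rdname MetricConfig-class
#' @aliases nEnvironments,MetricConfig-method
#' @export
setMethod("nEnvironments", "MetricConfig", function(object) object@nEnv)

#' @rdname MetricConfig-class
#' @aliases environmentWeights,MetricConfig-method
#' @export
setMethod("environmentWeights", "MetricConfig",
          function(object) object@weights)

#' @rdname MetricConfig-class
#' @aliases connectivity,MetricConfig-method
#' @export
setMethod("connectivity", "MetricConfig", function(object) object@connectivity)

#' @rdname MetricConfig-class
#' @aliases ldcEnvIndex,MetricConfig-method
#' @export
setMethod("ldcEnvIndex", "MetricConfig", function(object) object@ldcEnvIndex)

setMethod("show", "MetricConfig", function(object) {
  cat(sprintf(
    "MetricConfig: n = %d, weights = (%s), %s connectivity, LDC env = %d\n",
    object@nEnv, paste(format(object@weights), collapse = ", "),
    object@connectivity, object@ldcEnvIndex))
  invisible(NULL)
})

#' Write / read a metric configuration as JSON
#'
#' Round-trip safe: \code{readMetricConfig(writeMetricConfig(cfg, f))}
#' reconstructs an identical configuration.
#'
#' @param config a [MetricConfig-class].
#' @param path file path for the JSON document.
#' @return \code{writeMetricConfig} returns \code{path} invisibly;
#'   \code{readMetricConfig} returns a \code{MetricConfig}.
#' @export
writeMetricConfig <- function(config, path) {
  stopifnot(is(config, "MetricConfig"))
  jsonlite::write_json(
    list(nEnv = config@nEnv, weights = config@weights,
         connectivity = config@connectivity,
         ldcEnvIndex = config@ldcEnvIndex),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMetricConfig
#' @export
readMetricConfig <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  MetricConfig(nEnv = x$nEnv, weights = as.numeric(x$weights),
               connectivity = x$connectivity, ldcEnvIndex = x$ldcEnvIndex)
}
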