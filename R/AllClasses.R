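#' @import methods
NULL

#' Binary segmentation mask
#'
#' An N-dimensional (N = 2 or 3) boolean grid. The set of positive elements
#' plays the role of the segment \eqn{X}: pixels in a 2-D mask, voxels in a
#' 3-D one.
#'
#' @slot grid logical array of 2 or 3 dimensions; \code{TRUE} marks a
#'   positive element, no \code{NA}s allowed.
#'
#' @seealso [BinaryMask()] for the user-facing constructor, [maskGrid()],
#'   [positiveCount()].
#' @export
setClass("BinaryMask", representation(grid = "array"))

setValidity("BinaryMask", function(object) {
  g <- object@grid
  nd <- length(dim(g))
  if (nd < 2L || nd > 3L)
    return(sprintf("mask must have 2 or 3 dimensions, not %d", nd))
  if (!is.logical(g))
    return("mask grid must be stored as a logical array")
  if (anyNA(g))
    return("mask grid contains NA values")
  if (any(dim(g) < 1L))
    return("all mask extents must be positive")
  TRUE
})

#' Metric configuration
#'
#' Fully determines the weighted (WDC) and loss-based (LDC) Dice
#' coefficients: the number of nested dilation environments, their weights,
#' the structuring element, and which environment serves as the LDC
#' tolerance region.
#'
#' @slot nEnv non-negative integer, the number of environments \eqn{n}.
#'   With \code{nEnv = 0} the WDC degenerates to the plain Dice
#'   coefficient.
#' @slot weights numeric vector \eqn{\nu_1 > \nu_2 > \ldots > \nu_n}, all
#'   strictly inside (0, 1). Each \eqn{\nu_i} is the weight of the i-th
#'   dilation ring.
#' @slot connectivity \code{"edge"} (2-D 4-neighbourhood / 3-D
#'   6-neighbourhood; one dilation step adds elements sharing an edge or
#'   face) or \code{"full"} (8- / 26-neighbourhood).
#' @slot ldcEnvIndex integer in \code{[0, nEnv]}; the LDC uses
#'   \eqn{X^* = X_{index}} as the tolerated region around each mask.
#'
#' @seealso [MetricConfig()] for the constructor with the default
#'   parameterisation (n = 3, weights 0.7/0.5/0.3, edge connectivity).
#' @export
setClass("MetricConfig", representation(
  nEnv = "integer",
  weights = "numeric",
  connectivity = "character",
  ldcEnvIndex = "integer"
))

setValidity("MetricConfig", function(object) {
  n <- object@nEnv
  w <- object@weights
  if (length(n) != 1L || is.na(n) || n < 0L)
    return("nEnv must be a single non-negative integer")
  if (length(w) != n)
    return(sprintf("need %d weights for nEnv = %d, got %d", n, n, length(w)))
  if (n > 0L) {
    if (anyNA(w) || any(w <= 0) || any(w >= 1))
      return("weights must lie strictly inside (0, 1)")
    if (n > 1L && any(diff(w) >= 0))
      return("weights must be strictly decreasing: 1 > nu_1 > ... > nu_n > 0")
  }
  if (!identical(length(object@connectivity), 1L) ||
      !object@connectivity %in% c("edge", "full"))
    return("connectivity must be \"edge\" or \"full\"")
  k <- object@ldcEnvIndex
  if (length(k) != 1L || is.na(k) || k < 0L || k > n)
    return(sprintf("ldcEnvIndex must lie in [0, %d]", n))
  TRUE
})

#' Nested dilation environments of a mask
#'
#' The stack \eqn{X = X_0 \subseteq X_1 \subseteq \ldots \subseteq X_n}
#' obtained by repeated binary dilation, stored as disjoint rings
#' \eqn{X_i \setminus X_{i-1}} together with the per-element weight map
#' (1 on \eqn{X}, \eqn{\nu_i} on ring i, 0 outside \eqn{X_n}) and its sum
#' \eqn{s_X}.
#'
#' @slot rings list of logical arrays: the mask itself, then one ring per
#'   environment; pairwise disjoint, union equal to \eqn{X_n}.
#' @slot weightMap numeric array of the mask's shape.
#' @slot weightSum the scalar \eqn{s_X = |X| + \sum_i \nu_i |X_i \setminus
#'   X_{i-1}|}.
#' @slot config the [MetricConfig-class] used to build the stack.
#'
#' @seealso [buildEnvironments()]
#' @export
setClass("EnvironmentStack", representation(
  rings = "list",
  weightMap = "array",
  weightSum = "numeric",
  config = "MetricConfig"
))

setValidity("EnvironmentStack", function(object) {
  if (length(object@rings) != object@config@nEnv + 1L)
    return("rings must hold the mask plus one ring per environment")
  if (length(object@weightSum) != 1L || object@weightSum < 0)
    return("weightSum must be a single non-negative number")
  TRUE
})

#' Result of a mask-comparison metric
#'
#' @slot value the metric value in \code{[0, 1]}.
#' @slot metricName one of \code{"DSC"}, \code{"WDC"}, \code{"LDC"},
#'   \code{"hybrid-WDC"}.
#' @slot config the [MetricConfig-class] in force.
#' @slot degenerateFlag \code{"none"}, \code{"both_empty"} (both masks
#'   empty, value defined as 1), or \code{"one_empty"} (exactly one empty,
#'   value 0).
#'
#' @seealso [metricValue()], [degenerateFlag()]
#' @export
setClass("MetricResult", representation(
  value = "numeric",
  metricName = "character",
  config = "MetricConfig",
  degenerateFlag = "character"
))

setValidity("MetricResult", function(object) {
  v <- object@value
  if (length(v) != 1L || is.na(v) || v < -1e-12 || v > 1 + 1e-12)
    return("metric value must be a single number in [0, 1]")
  if (!object@metricName %in% c("DSC", "WDC", "LDC", "hybrid-WDC"))
    return("unknown metric name")
  if (!object@degenerateFlag %in% c("none", "both_empty", "one_empty"))
    return("unknown degeneracy flag")
  TRUE
})

#' Result of a statistical test
#'
#' @slot statistic the test statistic (Spearman's rho, or the variance
#'   ratio F).
#' @slot pValue two-sided p-value.
#' @slot pValueFdr Benjamini-Hochberg adjusted p-value; \code{NA} until a
#'   correction over a family of tests has been applied.
#' @slot method human-readable label of the procedure.
#'
#' @export
setClass("TestResult", representation(
  statistic = "numeric",
  pValue = "numeric",
  pValueFdr = "numeric",
  method = "character"
))

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    return("pValue must be a single number in [0, 1]")
  q <- object@pValueFdr
  if (length(q) != 1L)
    return("pValueFdr must be a single number or NA")
  if (!is.na(q) && (q < p - 1e-12 || q > 1))
    return("pValueFdr must lie in [pValue, 1]")
  TRUE
})
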