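#' Dice similarity coefficient and its distance-aware variants
#'
#' @description
#' Four overlap metrics on pairs of binary segmentation masks of matching
#' shape (2-D or 3-D):
#'
#' * `dsc()` — the Sorensen-Dice coefficient
#'   \eqn{2|X \cap Y| / (|X| + |Y|)}.
#' * `wdc()` — the weighted Dice coefficient: each mask is surrounded by
#'   \eqn{n} nested dilation environments with strictly decreasing weights
#'   \eqn{\nu_1 > \ldots > \nu_n}, so that a misplaced element close to
#'   the other segment still earns partial credit. Computed in the fast
#'   form \eqn{2s / (s_X + s_Y)}, where \eqn{s_X}, \eqn{s_Y} are the
#'   weight-map sums and \eqn{s} the sum of the element-wise minimum of
#'   the two weight maps.
#' * `wdcSetForm()` — the same coefficient evaluated literally from its
#'   set definition
#'   \deqn{2\,\frac{|X \cap Y| + \sum_i \nu_i |X_i \cap Y_i \setminus
#'     (X_{i-1} \cap Y_{i-1})|}{|X| + \sum_i \nu_i |X_i \setminus X_{i-1}|
#'     + |Y| + \sum_i \nu_i |Y_i \setminus Y_{i-1}|}.}
#'   The two formulations are mathematically identical; `wdcSetForm()`
#'   exists as the reference implementation against which `wdc()` is
#'   verified.
#' * `ldc()` — the loss-based Dice coefficient
#'   \eqn{2|X \cap Y| / (|X| + |Y| + |X \setminus Y^*| + |Y \setminus
#'   X^*|)}, where \eqn{X^*}, \eqn{Y^*} are the environments selected by
#'   \code{ldcEnvIndex}; elements far from the other segment enlarge the
#'   denominator, so \eqn{LDC \le DSC} always.
#' * `hybridWdc()` — the WDC forced to 0 whenever the plain DSC is 0,
#'   removing the WDC's small positive values for completely misplaced
#'   predictions.
#'
#' Degenerate pairs are handled identically by all metrics: both masks
#' empty gives value 1 (flag \code{"both_empty"}), exactly one empty gives
#' 0 (flag \code{"one_empty"}).
#'
#' @param x,y [BinaryMask-class] objects (or 0/1 arrays) of the same
#'   shape.
#' @param config a [MetricConfig-class]; ignored by `dsc()` except for
#'   record keeping.
#' @return a [MetricResult-class]; extract the number with
#'   [metricValue()].
#' @examples
#' a <- array(0, c(10, 10)); a[2:4, 2:4] <- 1
#' b <- array(0, c(10, 10)); b[4:6, 3:5] <- 1   # overlaps a in 2 pixels
#' metricValue(dsc(a, b))        # 2*2 / (9+9) = 0.2222
#' metricValue(wdc(a, b))        # higher: the masks nearly touch
#' metricValue(ldc(a, b))        # <= dsc by construction
#' @name diceCoefficients
NULL

.metricResult <- function(value, name, config, flag = "none") {
  new("MetricResult", value = value, metricName = name, config = config,
      degenerateFlag = flag)
}

# returns a MetricResult for the empty-mask cases, or NULL if both nonempty
.degenerateCase <- function(nx, ny, name, config) {
  if (nx == 0L && ny == 0L)
    return(.metricResult(1, name, config, "both_empty"))
  if (nx == 0L || ny == 0L)
    return(.metricResult(0, name, config, "one_empty"))
  NULL
}

#' @rdname diceCoefficients
#' @export
dsc <- function(x, y, config = MetricConfig()) {
  x <- .asMask(x); y <- .asMask(y)
  .checkSameShape(x, y)
  gx <- maskGrid(x); gy <- maskGrid(y)
  nx <- sum(gx); ny <- sum(gy)
  deg <- .degenerateCase(nx, ny, "DSC", config)
  if (!is.null(deg)) return(deg)
  .metricResult(2 * sum(gx & gy) / (nx + ny), "DSC", config)
}

#' @rdname diceCoefficients
#' @export
wdc <- function(x, y, config = MetricConfig()) {
  x <- .asMask(x); y <- .asMask(y)
  .checkSameShape(x, y)
  stopifnot(is(config, "MetricConfig")); validObject(config)
  nx <- positiveCount(x); ny <- positiveCount(y)
  deg <- .degenerateCase(nx, ny, "WDC", config)
  if (!is.null(deg)) return(deg)
  ex <- buildEnvironments(x, config)
  ey <- buildEnvironments(y, config)
  s <- sum(pmin(weightMap(ex), weightMap(ey)))
  .metricResult(2 * s / (weightSum(ex) + weightSum(ey)), "WDC", config)
}

#' @rdname diceCoefficients
#' @export
wdcSetForm <- function(x, y, config = MetricConfig()) {
  x <- .asMask(x); y <- .asMask(y)
  .checkSameShape(x, y)
  stopifnot(is(config, "MetricConfig")); validObject(config)
  gx <- maskGrid(x); gy <- maskGrid(y)
  nx <- sum(gx); ny <- sum(gy)
  deg <- .degenerateCase(nx, ny, "WDC", config)
  if (!is.null(deg)) return(deg)
  n <- config@nEnv
  ex <- .cumulativeEnvironments(gx, n, config@connectivity)
  ey <- .cumulativeEnvironments(gy, n, config@connectivity)
  num <- sum(gx & gy)
  den <- nx + ny
  for (i in seq_len(n)) {
    w <- config@weights[i]
    interNew <- (ex[[i + 1L]] & ey[[i + 1L]]) & !(ex[[i]] & ey[[i]])
    num <- num + w * sum(interNew)
    den <- den + w * (sum(ex[[i + 1L]] & !ex[[i]]) +
                      sum(ey[[i + 1L]] & !ey[[i]]))
  }
  .metricResult(2 * num / den, "WDC", config)
}

#' @rdname diceCoefficients
#' @export
ldc <- function(x, y, config = MetricConfig()) {
  x <- .asMask(x); y <- .asMask(y)
  .checkSameShape(x, y)
  stopifnot(is(config, "MetricConfig")); validObject(config)
  gx <- maskGrid(x); gy <- maskGrid(y)
  nx <- sum(gx); ny <- sum(gy)
  deg <- .degenerateCase(nx, ny, "LDC", config)
  if (!is.null(deg)) return(deg)
  k <- config@ldcEnvIndex
  xStar <- binaryDilate(gx, config@connectivity, steps = k)
  yStar <- binaryDilate(gy, config@connectivity, steps = k)
  lossX <- sum(gx & !yStar)
  lossY <- sum(gy & !xStar)
  .metricResult(2 * sum(gx & gy) / (nx + ny + lossX + lossY), "LDC", config)
}

#' @rdname diceCoefficients
#' @export
hybridWdc <- function(x, y, config = MetricConfig()) {
  x <- .asMask(x); y <- .asMask(y)
  .checkSameShape(x, y)
  nx <- positiveCount(x); ny <- positiveCount(y)
  deg <- .degenerateCase(nx, ny, "hybrid-WDC", config)
  if (!is.null(deg)) return(deg)
  if (sum(maskGrid(x) & maskGrid(y)) == 0L)
    return(.metricResult(0, "hybrid-WDC", config))
  w <- wdc(x, y, config)
  .metricResult(metricValue(w), "hybrid-WDC", config)
}

#' Compute all four coefficients at once
#'
#' @inheritParams diceCoefficients
#' @return named numeric vector with elements \code{DSC}, \code{WDC},
#'   \code{LDC}, \code{hybridWDC}.
#' @export
allMetrics <- function(x, y, config = MetricConfig()) {
  c(DSC = metricValue(dsc(x, y, config)),
    WDC = metricValue(wdc(x, y, config)),
    LDC = metricValue(ldc(x, y, config)),
    hybridWDC = metricValue(hybridWdc(x, y, config)))
}

#' @rdname MetricResult-class
#' @aliases metricValue,MetricResult-method
#' @export
setMethod("metricValue", "MetricResult", function(object) object@value)

#' @rdname MetricResult-class
#' @aliases metricName,MetricResult-method
#' @export
setMethod("metricName", "MetricResult", function(object) object@metricName)

#' @rdname MetricResult-class
#' @aliases degenerateFlag,MetricResult-method
#' @export
setMethod("degenerateFlag", "MetricResult",
          function(object) object@degenerateFlag)

setMethod("show", "MetricResult", function(object) {
  flag <- if (object@degenerateFlag == "none") ""
          else sprintf(" [%s]", object@degenerateFlag)
  cat(sprintf("%s = %.3f%s\n", object@metricName, object@value, flag))
  invisible(NULL)
})
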