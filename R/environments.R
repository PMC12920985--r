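#' Build the nested dilation environments of a mask
#'
#' Computes \eqn{X_0 = X, X_1, \ldots, X_n}, where each \eqn{X_i} is
#' \eqn{X_{i-1}} dilated once by the configured structuring element, and
#' derives the per-element weight map: 1 on \eqn{X}, \eqn{\nu_i} on the
#' ring \eqn{X_i \setminus X_{i-1}}, 0 outside \eqn{X_n}. The sum of the
#' weight map is the quantity \eqn{s_X} entering the fast form of the
#' weighted Dice coefficient.
#'
#' Environments are clipped at the grid borders; an empty mask yields an
#' all-zero weight map with \eqn{s_X = 0}.
#'
#' @param x a [BinaryMask-class] (or a 0/1 array).
#' @param config a [MetricConfig-class].
#' @return an [EnvironmentStack-class].
#' @examples
#' m <- array(0, c(9, 9)); m[5, 5] <- 1
#' es <- buildEnvironments(BinaryMask(m), MetricConfig())
#' weightSum(es)  # 1 + 4*0.7 + 8*0.5 + 12*0.3 = 11.4
#' @export
buildEnvironments <- function(x, config = MetricConfig()) {
  x <- .asMask(x)
  stopifnot(is(config, "MetricConfig"))
  validObject(config)
  g <- maskGrid(x)
  n <- config@nEnv
  rings <- vector("list", n + 1L)
  rings[[1L]] <- g
  wmap <- array(as.numeric(g), dim(g))
  prev <- g
  for (i in seq_len(n)) {
    cur <- binaryDilate(prev, config@connectivity)
    ring <- cur & !prev
    rings[[i + 1L]] <- ring
    wmap[ring] <- config@weights[i]
    prev <- cur
  }
  new("EnvironmentStack", rings = rings, weightMap = wmap,
      weightSum = sum(wmap), config = config)
}

#' @rdname EnvironmentStack-class
#' @aliases environmentRings,EnvironmentStack-method
#' @export
setMethod("environmentRings", "EnvironmentStack",
          function(object) object@rings)

#' @rdname EnvironmentStack-class
#' @aliases weightMap,EnvironmentStack-method
#' @export
setMethod("weightMap", "EnvironmentStack", function(object) object@weightMap)

#' @rdname EnvironmentStack-class
#' @aliases weightSum,EnvironmentStack-method
#' @export
setMethod("weightSum", "EnvironmentStack", function(object) object@weightSum)

setMethod("show", "EnvironmentStack", function(object) {
  sizes <- vapply(object@rings, sum, numeric(1))
  cat(sprintf(
    "EnvironmentStack: |X| = %d, ring sizes (%s), weight sum s_X = %g\n",
    as.integer(sizes[1L]),
    paste(as.integer(sizes[-1L]), collapse = ", "),
    object@weightSum))
  invisible(NULL)
})

# cumulative environments X_0 ... X_k as logical arrays
.cumulativeEnvironments <- function(grid, k, connectivity) {
  envs <- vector("list", k + 1L)
  envs[[1L]] <- grid
  for (i in seq_len(k))
    envs[[i + 1L]] <- binaryDilate(envs[[i]], connectivity)
  envs
}
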