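#' Create a binary segmentation mask
#'
#' Wraps a 2-D or 3-D array into a validated [BinaryMask-class]. Numeric
#' input must be exactly binary: every element 0 or 1 (logical input is
#' taken as is). Anything else is rejected rather than thresholded, so
#' that soft masks cannot slip in unnoticed; use [resizeMask()] or an
#' explicit comparison to binarise real-valued fields.
#'
#' @param grid a logical or 0/1 numeric matrix or array with 2 or 3
#'   dimensions.
#' @return a \code{BinaryMask}.
#' @examples
#' m <- matrix(0, 8, 8); m[3:5, 3:5] <- 1
#' BinaryMask(m)
#' @export
BinaryMask <- function(grid) {
  if (is.null(dim(grid)))
    stop("mask input must be a matrix or array, not a plain vector")
  if (is.numeric(grid)) {
    if (anyNA(grid) || !all(grid == 0 | grid == 1))
      stop("mask input is not binary: every element must be exactly 0 or 1")
    g <- array(grid != 0, dim = dim(grid))
  } else if (is.logical(grid)) {
    g <- grid
  } else {
    stop("mask input must be logical or numeric")
  }
  new("BinaryMask", grid = g)
}

#' @rdname BinaryMask-class
#' @aliases maskGrid maskGrid,BinaryMask-method
#' @export
setMethod("maskGrid", "BinaryMask", function(x) x@grid)

#' @rdname BinaryMask-class
#' @aliases positiveCount,BinaryMask-method
#' @export
setMethod("positiveCount", "BinaryMask", function(x) sum(x@grid))

#' @rdname BinaryMask-class
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@grid))

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@grid)
  cat(sprintf("BinaryMask: %s grid, %d positive element%s (%.1f%%)\n",
              paste(d, collapse = " x "), sum(object@grid),
              if (sum(object@grid) == 1L) "" else "s",
              100 * mean(object@grid)))
  invisible(NULL)
})

.checkSameShape <- function(x, y) {
  dx <- dim(x)
  dy <- dim(y)
  if (!identical(dx, dy))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dx, collapse = "x"), paste(dy, collapse = "x")))
  invisible(NULL)
}

.asMask <- function(x) {
  if (is(x, "BinaryMask")) x else BinaryMask(x)
}
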