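# N-dimensional binary morphology on logical arrays (N = 2, 3).
#
# One dilation step with "edge" connectivity adds every element sharing an
# edge (2-D) or a face (3-D) with the set: the cross-shaped structuring
# element. "full" connectivity uses the complete 3^N - 1 neighbourhood.
# Dilation is clipped at the array borders: environments never escape the
# grid.

# shift a logical array by an integer offset per axis, filling with FALSE
.shiftArray <- function(a, by) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- vector("list", length(d))
  dst <- vector("list", length(d))
  for (k in seq_along(d)) {
    s <- by[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0L) {
      dst[[k]] <- (1L + s):d[k]
      src[[k]] <- 1L:(d[k] - s)
    } else {
      dst[[k]] <- 1L:(d[k] + s)
      src[[k]] <- (1L - s):d[k]
    }
  }
  piece <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(piece)))
}

.neighbourOffsets <- function(ndim, connectivity) {
  if (connectivity == "edge") {
    offs <- list()
    for (k in seq_len(ndim)) {
      for (s in c(-1L, 1L)) {
        v <- integer(ndim)
        v[k] <- s
        offs[[length(offs) + 1L]] <- v
      }
    }
    offs
  } else {
    g <- do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), ndim))
    g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
}

#' One binary dilation step
#'
#' Dilates a logical 2-D or 3-D array by the cross-shaped
#' (\code{"edge"}: 4- / 6-neighbourhood) or box-shaped (\code{"full"}:
#' 8- / 26-neighbourhood) structuring element, clipped at the grid
#' borders.
#'
#' @param grid logical matrix or array (2 or 3 dimensions).
#' @param connectivity \code{"edge"} or \code{"full"}.
#' @param steps number of dilation iterations (0 returns the input).
#' @return logical array of the same shape.
#' @examples
#' m <- array(FALSE, c(5, 5)); m[3, 3] <- TRUE
#' sum(binaryDilate(m, steps = 1))  # 5: the pixel plus its 4 neighbours
#' @export
binaryDilate <- function(grid, connectivity = c("edge", "full"), steps = 1L) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.logical(grid), !is.null(dim(grid)), steps >= 0L)
  offs <- .neighbourOffsets(length(dim(grid)), connectivity)
  out <- grid
  for (i in seq_len(steps)) {
    acc <- out
    for (o in offs) acc <- acc | .shiftArray(out, o)
    out <- acc
  }
  out
}

#' Label connected components
#'
#' Labels the connected components of a logical array under the same
#' connectivity rule the metrics use, so that "fully false-positive"
#' components in the quality rubric are defined consistently with the
#' dilation environments.
#'
#' @inheritParams binaryDilate
#' @return integer array of the input shape: 0 on background, components
#'   numbered from 1 in first-encounter order.
#' @export
labelComponents <- function(grid, connectivity = c("edge", "full")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.logical(grid), !is.null(dim(grid)))
  labels <- array(0L, dim(grid))
  nextLabel <- 0L
  remaining <- grid
  # flood fill by masked dilation: exact for any component shape
  while (any(remaining)) {
    nextLabel <- nextLabel + 1L
    seed <- array(FALSE, dim(grid))
    seed[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- binaryDilate(seed, connectivity) & remaining
      if (identical(grown, seed)) break
      seed <- grown
    }
    labels[seed] <- nextLabel
    remaining <- remaining & !seed
  }
  labels
}
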