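#' Resize a 2-D mask with threshold binarisation
#'
#' Interpolates the mask as a real-valued field to the target shape and
#' binarises at a coverage threshold (element positive iff the
#' interpolated value is strictly greater than the threshold). For
#' integer downscale factors on both axes the interpolation is the block
#' mean, which makes the threshold an exact fractional-coverage rule: a
#' coarse pixel turns positive when more than the threshold fraction of
#' the fine pixels it covers are positive. Otherwise bilinear
#' interpolation at target pixel centres is used.
#'
#' The default threshold of 0.25 matches common practice when collapsing
#' 512 x 512 annotation masks to the 128 x 128 grids segmentation
#' networks work on.
#'
#' @param mask a 2-D [BinaryMask-class] (or 0/1 matrix).
#' @param targetShape integer vector of length 2 (rows, columns).
#' @param threshold coverage threshold in (0, 1).
#' @return a 2-D \code{BinaryMask} of the target shape.
#' @examples
#' m <- matrix(0, 16, 16); m[7:10, 7:10] <- 1
#' resizeMask(m, c(4, 4))   # the 4x4 block becomes one positive coarse pixel
#' @export
resizeMask <- function(mask, targetShape, threshold = 0.25) {
  mask <- .asMask(mask)
  d <- dim(mask)
  if (length(d) != 2L)
    stop("resizeMask operates on 2-D masks")
  targetShape <- as.integer(targetShape)
  if (length(targetShape) != 2L || any(targetShape < 1L))
    stop("targetShape must be two positive integers")
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  g <- maskGrid(mask)
  if (identical(d, targetShape))
    return(BinaryMask(g))
  field <- array(as.numeric(g), d)
  f <- d / targetShape
  if (all(f >= 1) && all(f == round(f))) {
    out <- .blockMean(field, as.integer(f))
  } else {
    out <- .bilinear(field, targetShape)
  }
  BinaryMask(out > threshold)
}

# exact block mean for integer downscale factors
.blockMean <- function(field, f) {
  d <- dim(field)
  out1 <- d[1L] %/% f[1L]
  out2 <- d[2L] %/% f[2L]
  m1 <- matrix(0, out1, d[1L])
  for (i in seq_len(out1)) m1[i, ((i - 1L) * f[1L] + 1L):(i * f[1L])] <- 1 / f[1L]
  m2 <- matrix(0, out2, d[2L])
  for (j in seq_len(out2)) m2[j, ((j - 1L) * f[2L] + 1L):(j * f[2L])] <- 1 / f[2L]
  m1 %*% field %*% t(m2)
}

# bilinear interpolation at target pixel centres, edges clamped
.bilinear <- function(field, targetShape) {
  d <- dim(field)
  coord <- function(nOut, nIn) {
    x <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5   # 1-based source coords
    pmin(pmax(x, 1), nIn)
  }
  xs <- coord(targetShape[1L], d[1L])
  ys <- coord(targetShape[2L], d[2L])
  x0 <- pmin(floor(xs), d[1L] - 1L); x1 <- x0 + 1L; tx <- xs - x0
  if (d[1L] == 1L) { x0 <- x1 <- rep(1L, length(xs)); tx <- rep(0, length(xs)) }
  y0 <- pmin(floor(ys), d[2L] - 1L); y1 <- y0 + 1L; ty <- ys - y0
  if (d[2L] == 1L) { y0 <- y1 <- rep(1L, length(ys)); ty <- rep(0, length(ys)) }
  out <- matrix(0, targetShape[1L], targetShape[2L])
  for (j in seq_len(targetShape[2L])) {
    c00 <- field[cbind(x0, y0[j])]; c10 <- field[cbind(x1, y0[j])]
    c01 <- field[cbind(x0, y1[j])]; c11 <- field[cbind(x1, y1[j])]
    out[, j] <- (1 - tx) * ((1 - ty[j]) * c00 + ty[j] * c01) +
                tx * ((1 - ty[j]) * c10 + ty[j] * c11)
  }
  out
}

#' Filter masks by minimum positive count
#'
#' Retains the masks with at least \code{minCount} positive elements,
#' preserving order; used to drop slices whose segment is too small to
#' evaluate meaningfully (fewer than 6 positive pixels by default, the
#' standard inclusion rule after threshold resizing).
#'
#' @param masks list of [BinaryMask-class] objects (or 0/1 arrays).
#' @param minCount minimum number of positive elements; non-negative.
#' @return list with components \code{retained} (the passing masks,
#'   unmodified) and \code{excluded} (integer indices of the dropped
#'   masks).
#' @export
minPositiveFilter <- function(masks, minCount = 6L) {
  stopifnot(is.list(masks), minCount >= 0L)
  masks <- lapply(masks, .asMask)
  counts <- vapply(masks, positiveCount, numeric(1))
  keep <- counts >= minCount
  list(retained = masks[keep], excluded = which(!keep))
}

#' Stack 2-D slices into a 3-D mask
#'
#' Combines an ordered list of 2-D masks of one shape into a 3-D mask,
#' slice index on the first axis (acquisition order for transaxial
#' slices). The total positive count is conserved. [sliceMask()] is the
#' inverse.
#'
#' @param slices list of 2-D [BinaryMask-class] objects (or 0/1 matrices)
#'   sharing one shape.
#' @return a 3-D \code{BinaryMask} of shape (n slices, rows, columns).
#' @export
stackSlices <- function(slices) {
  stopifnot(is.list(slices), length(slices) >= 1L)
  slices <- lapply(slices, .asMask)
  shapes <- lapply(slices, dim)
  if (any(vapply(shapes, length, integer(1)) != 2L))
    stop("every slice must be 2-D")
  if (length(unique(lapply(shapes, paste, collapse = "x"))) != 1L)
    stop("slices have inconsistent shapes")
  d <- shapes[[1L]]
  out <- array(FALSE, c(length(slices), d))
  for (i in seq_along(slices)) out[i, , ] <- maskGrid(slices[[i]])
  BinaryMask(out)
}

#' @rdname stackSlices
#' @param mask a 3-D \code{BinaryMask}.
#' @return \code{sliceMask}: list of 2-D \code{BinaryMask} slices.
#' @export
sliceMask <- function(mask) {
  mask <- .asMask(mask)
  d <- dim(mask)
  if (length(d) != 3L) stop("sliceMask expects a 3-D mask")
  g <- maskGrid(mask)
  lapply(seq_len(d[1L]), function(i) BinaryMask(array(g[i, , ], d[2:3])))
}
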