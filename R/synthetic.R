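# Seeded synthetic phantoms and graded degradations for metric validation.
#
# The generator stands in for physician-drawn tumour masks: unions of
# filled ellipses / ellipsoids. Degradations emulate a five-level visual
# quality rubric (0 fully wrong ... 4 excellent) so the metrics can be
# validated against ordinal scores without any patient data.

#' Reference mask with a scored degraded prediction
#'
#' @slot reference the ground-truth [BinaryMask-class].
#' @slot prediction the degraded mask.
#' @slot score intended ordinal quality class, 0 (fully wrong) to 4
#'   (excellent).
#' @slot provenance list recording how the prediction was produced
#'   (degradation kind, magnitudes, seed).
#' @export
setClass("ScoredPair", representation(
  reference = "BinaryMask",
  prediction = "BinaryMask",
  score = "integer",
  provenance = "list"
))

setValidity("ScoredPair", function(object) {
  if (!identical(dim(object@reference), dim(object@prediction)))
    return("reference and prediction shapes differ")
  s <- object@score
  if (length(s) != 1L || is.na(s) || s < 0L || s > 4L)
    return("score must be an integer in 0..4")
  TRUE
})

setMethod("show", "ScoredPair", function(object) {
  cat(sprintf("ScoredPair: score %d, |X| = %d, |Y| = %d (%s)\n",
              object@score, positiveCount(object@reference),
              positiveCount(object@prediction),
              if (is.null(object@provenance$kind)) "?"
              else object@provenance$kind))
  invisible(NULL)
})

# run expr with a private RNG stream, restoring global state afterwards
.withSeed <- function(seed, expr) {
  glob <- globalenv()
  had <- exists(".Random.seed", envir = glob, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = glob)
  on.exit({
    if (had) assign(".Random.seed", old, envir = glob)
    else suppressWarnings(rm(".Random.seed", envir = glob))
  })
  set.seed(seed)
  expr
}

# integer sub-seeds derived from one master seed
.subSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.fillEllipsoid <- function(grid, centre, semiAxes) {
  d <- dim(grid)
  axes <- lapply(seq_along(d), function(k) {
    ((seq_len(d[k]) - centre[k]) / semiAxes[k])^2
  })
  if (length(d) == 2L) {
    inside <- outer(axes[[1L]], axes[[2L]], `+`) <= 1
  } else {
    inside <- outer(outer(axes[[1L]], axes[[2L]], `+`), axes[[3L]], `+`) <= 1
  }
  grid | inside
}

#' Generate a seeded phantom mask
#'
#' Produces a deterministic union of randomly placed filled ellipses
#' (2-D) or ellipsoids (3-D). The semi-axis lower bound guarantees at
#' least 6 positive elements per blob, consistent with the minimum-size
#' inclusion rule applied to real slices; should clipping at the borders
#' ever drop the total below 6, a central 3 x 3 block is added as a
#' fallback.
#'
#' @param shape grid extents, length 2 or 3.
#' @param nBlobs number of blobs.
#' @param sizeRange range of blob semi-axes, in elements; the lower bound
#'   is clamped to 1.5.
#' @param seed integer seed; the output is a pure function of the
#'   arguments.
#' @return a [BinaryMask-class].
#' @examples
#' generatePhantom(c(32, 32), nBlobs = 2, seed = 7)
#' @export
generatePhantom <- function(shape, nBlobs = 2L, sizeRange = c(2, 5),
                            seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) %in% c(2L, 3L), all(shape >= 4L), nBlobs >= 1L)
  sizeRange[1L] <- max(sizeRange[1L], 1.5)
  if (sizeRange[2L] < sizeRange[1L])
    stop("sizeRange upper bound below its lower bound")
  if (any(sizeRange[1L] * 2 + 1 > shape))
    stop("blob size range incompatible with grid shape")
  .withSeed(seed, {
    g <- array(FALSE, shape)
    for (b in seq_len(nBlobs)) {
      a <- stats::runif(length(shape), sizeRange[1L], sizeRange[2L])
      a <- pmin(a, (shape - 1) / 2)
      ctr <- vapply(seq_along(shape), function(k) {
        stats::runif(1, 1 + a[k] * 0.5, shape[k] - a[k] * 0.5)
      }, numeric(1))
      g <- .fillEllipsoid(g, ctr, a)
    }
    if (sum(g) < 6L) {
      ctr <- pmax(2L, shape %/% 2L)
      idx <- lapply(seq_along(shape), function(k) {
        if (k <= 2L) (ctr[k] - 1L):(ctr[k] + 1L) else ctr[k]
      })
      g <- do.call(`[<-`, c(list(g), idx, list(TRUE)))
    }
    BinaryMask(g)
  })
}

.boundaryLayer <- function(g, connectivity) {
  g & binaryDilate(!g, connectivity)
}

# logical half-space mask through a point, random unit direction
.halfSpace <- function(shape, centre, direction) {
  coords <- lapply(seq_along(shape), function(k) seq_len(shape[k]) - centre[k])
  if (length(shape) == 2L) {
    proj <- outer(coords[[1L]] * direction[1L], coords[[2L]] * direction[2L], `+`)
  } else {
    proj <- outer(outer(coords[[1L]] * direction[1L],
                        coords[[2L]] * direction[2L], `+`),
                  coords[[3L]] * direction[3L], `+`)
  }
  array(proj >= 0, shape)
}

.maskCentroid <- function(g) {
  w <- which(g, arr.ind = TRUE)
  colMeans(w)
}

# translate: find a shift along `axis` meeting a predicate, else NULL
.shiftMask <- function(g, by) .shiftArray(g, as.integer(by))

#' Degrade a reference mask to a target quality class
#'
#' Produces a prediction emulating one of five visual quality levels:
#' \describe{
#'   \item{4 (excellent)}{the reference with sparse one-step boundary
#'     noise (each outer-boundary neighbour added, and each boundary
#'     element removed, with small probability).}
#'   \item{3 (good)}{asymmetric boundary error: two-step dilation on a
#'     random half of the mask, one-step erosion on the other, so the
#'     outlines clearly intersect but some errors exceed one step.}
#'   \item{2 (decent)}{uniform two-step over- or under-segmentation
#'     (outline fully outside/inside), or the reference plus one
#'     substantial, distant fully-false-positive component.}
#'   \item{1 (poor)}{translation until the masks only barely overlap
#'     (majority of each mask outside the other).}
#'   \item{0 (fully wrong)}{relocation with zero overlap and a gap wider
#'     than twice the environment depth (so even the weighted coefficient
#'     is 0), or an empty prediction; when the phantom leaves no room for
#'     relocation the empty form is used.}
#' }
#'
#' @param reference a nonempty [BinaryMask-class].
#' @param scoreClass target class, integer 0..4.
#' @param seed integer seed; output is deterministic given
#'   (reference, scoreClass, seed).
#' @param config [MetricConfig-class]; supplies the connectivity rule and
#'   the environment depth used for class-0 separation.
#' @param noise boundary-flip probability for class 4 (0 gives an exact
#'   copy).
#' @return a [ScoredPair-class].
#' @export
degradeMask <- function(reference, scoreClass, seed = 1L,
                        config = MetricConfig(), noise = 0.15) {
  reference <- .asMask(reference)
  scoreClass <- as.integer(scoreClass)
  stopifnot(scoreClass >= 0L, scoreClass <= 4L)
  if (positiveCount(reference) == 0L)
    stop("cannot degrade an empty reference mask")
  g <- maskGrid(reference)
  conn <- config@connectivity
  prov <- list(class = scoreClass, seed = seed)
  pred <- .withSeed(seed, switch(as.character(scoreClass),
    "4" = {
      prov$kind <- "boundary-noise"
      outer <- binaryDilate(g, conn) & !g
      inner <- .boundaryLayer(g, conn)
      add <- outer & array(stats::runif(length(g)) < noise, dim(g))
      # never drop a pixel anchoring an added one: an added element losing
      # all its reference neighbours would become a fully-FP component
      protect <- binaryDilate(add, conn)
      drop <- inner & !protect &
        array(stats::runif(length(g)) < noise * 0.6, dim(g))
      (g | add) & !drop
    },
    "3" = {
      prov$kind <- "asymmetric-boundary"
      ctr <- .maskCentroid(g)
      dirRaw <- stats::rnorm(length(dim(g)))
      dir <- dirRaw / sqrt(sum(dirRaw^2))
      side <- .halfSpace(dim(g), ctr, dir)
      d2 <- binaryDilate(g, conn, steps = 2L)
      eroded <- g & !(.boundaryLayer(g, conn) & !side)
      p3 <- eroded | (d2 & side)
      # restore any reference component the erosion removed entirely:
      # a fully-FN component belongs to class 2, not 3
      refLab <- labelComponents(g, conn)
      for (k in seq_len(max(refLab))) {
        sel <- refLab == k
        if (!any(p3 & sel)) p3 <- p3 | sel
      }
      # the outlines must cross: force at least one under-segmented pixel
      if (!any(g & !p3)) {
        cand <- which(.boundaryLayer(g, conn) & !side)
        if (length(cand) == 0L) cand <- which(.boundaryLayer(g, conn))
        p3[cand[1L]] <- FALSE
      }
      p3
    },
    "2" = {
      mode <- sample(c("dilate", "erode", "far-fp"), 1L)
      if (mode == "erode") {
        e2 <- !binaryDilate(!g, conn, steps = 2L) & g
        if (sum(e2) < 6L) mode <- "dilate" else {
          prov$kind <- "uniform-erode"
        }
      }
      if (mode == "far-fp") {
        fp <- .placeFarComponent(g, conn, gap = config@nEnv + 2L,
                                 frac = 0.3)
        if (is.null(fp)) mode <- "dilate" else {
          prov$kind <- "far-fp-component"
        }
      }
      if (mode == "dilate") prov$kind <- "uniform-dilate"
      switch(mode,
             dilate = binaryDilate(g, conn, steps = 2L),
             erode = !binaryDilate(!g, conn, steps = 2L) & g,
             `far-fp` = g | fp)
    },
    "1" = {
      prov$kind <- "barely-touching-translate"
      .barelyTouching(g, conn)
    },
    "0" = {
      if (stats::runif(1) < 0.2) {
        prov$kind <- "empty-prediction"
        array(FALSE, dim(g))
      } else {
        prov$kind <- "distant-relocation"
        .relocateFar(g, conn, gap = 2L * config@nEnv + 1L)
      }
    }))
  new("ScoredPair", reference = reference, prediction = BinaryMask(pred),
      score = scoreClass, provenance = prov)
}

# an ellipse component of ~frac*|X| elements, placed so that its support
# stays more than `gap` dilation steps away from the reference
.placeFarComponent <- function(g, conn, gap, frac) {
  d <- dim(g)
  forbidden <- binaryDilate(g, conn, steps = gap)
  a <- max(1.5, (frac * sum(g) / pi)^(1 / length(d)) * 1.2)
  for (try in seq_len(40L)) {
    ctr <- vapply(d, function(e) stats::runif(1, 1 + a, e - a), numeric(1))
    if (any(d < 2 * a + 2)) return(NULL)
    blob <- .fillEllipsoid(array(FALSE, d), ctr, rep(a, length(d)))
    halo <- binaryDilate(blob, conn, steps = gap)
    if (!any(halo & forbidden) && sum(blob) >= 0.1 * sum(g)) return(blob)
  }
  NULL
}

# translate until the masks overlap in >= 1 element but less than half of
# the smaller mask
.barelyTouching <- function(g, conn) {
  d <- dim(g)
  axis <- sample(seq_along(d), 1L)
  sgn <- sample(c(-1L, 1L), 1L)
  best <- NULL
  bestFrac <- Inf
  for (s in rev(seq_len(d[axis] - 1L))) {
    by <- integer(length(d)); by[axis] <- sgn * s
    cand <- .shiftMask(g, by)
    ov <- sum(cand & g)
    if (ov == 0L || sum(cand) == 0L) next
    frac <- ov / min(sum(g), sum(cand))
    if (frac < bestFrac) { bestFrac <- frac; best <- cand }
    if (frac >= 0.5) break   # shifts only get smaller-overlap no more
  }
  if (is.null(best))
    stop("no translation yields a barely-touching prediction")
  best
}

# relocate the mask so the gap to the original exceeds `gap` steps:
# translation if possible, else an equivalent-size blob elsewhere, else an
# empty prediction (the other legitimate fully-wrong form)
.relocateFar <- function(g, conn, gap) {
  d <- dim(g)
  forbidden <- binaryDilate(g, conn, steps = gap)
  for (axis in sample(seq_along(d))) {
    for (sgn in c(1L, -1L)) {
      for (s in seq_len(d[axis] - 1L)) {
        by <- integer(length(d)); by[axis] <- sgn * s
        cand <- .shiftMask(g, by)
        if (sum(cand) == sum(g) && !any(cand & forbidden)) return(cand)
      }
    }
  }
  blob <- .placeFarComponent(g, conn, gap, frac = 1)
  if (!is.null(blob)) return(blob)
  array(FALSE, d)
}

#' Score a prediction against the five-level quality rubric
#'
#' Operationalises the visual grading rubric with explicit, documented
#' thresholds. Fully false-positive components are connected components
#' of the prediction (under the metric connectivity) with zero reference
#' overlap; fully false-negative components likewise for the reference.
#' The decision ladder:
#' \enumerate{
#'   \item empty prediction, or zero overlap anywhere: 0;
#'   \item overlap smaller than \code{majorityFraction} of the smaller
#'     mask (masks mostly do not overlap): 1;
#'   \item any fully FP or FN component, or outlines strictly nested
#'     (one mask inside the other with margin beyond one step): 2;
#'   \item remaining errors all within one dilation step of the other
#'     mask: 4; otherwise 3.
#' }
#'
#' @param reference,prediction [BinaryMask-class] objects of one shape.
#' @param config [MetricConfig-class] supplying the connectivity rule.
#' @param majorityFraction overlap fraction of the smaller mask below
#'   which the pair is graded 1.
#' @return integer score 0..4.
#' @export
rubricScore <- function(reference, prediction, config = MetricConfig(),
                        majorityFraction = 0.5) {
  reference <- .asMask(reference); prediction <- .asMask(prediction)
  .checkSameShape(reference, prediction)
  gx <- maskGrid(reference); gy <- maskGrid(prediction)
  conn <- config@connectivity
  overlap <- sum(gx & gy)
  if (sum(gy) == 0L || overlap == 0L) return(0L)
  if (overlap / min(sum(gx), sum(gy)) < majorityFraction) return(1L)
  predLab <- labelComponents(gy, conn)
  refLab <- labelComponents(gx, conn)
  fullyFP <- setdiff(unique(predLab[predLab > 0L]), unique(predLab[gx & gy]))
  fullyFN <- setdiff(unique(refLab[refLab > 0L]), unique(refLab[gx & gy]))
  if (length(fullyFP) > 0L || length(fullyFN) > 0L) return(2L)
  x1 <- binaryDilate(gx, conn)
  y1 <- binaryDilate(gy, conn)
  nestedOver <- all(gy[gx]) && any(gy & !x1)   # X inside Y, margin > 1
  nestedUnder <- all(gx[gy]) && any(gx & !y1)  # Y inside X, margin > 1
  if (nestedOver || nestedUnder) return(2L)
  near <- all(y1[gx & !gy]) && all(x1[gy & !gx])
  if (near) 4L else 3L
}

#' Generate a seeded suite of scored reference/prediction pairs
#'
#' Balanced over the requested score classes; each pair gets its own
#' sub-seed derived from the master seed, so the whole suite is a pure
#' function of its arguments.
#'
#' @param nPairs total number of pairs (rounded up to a multiple of the
#'   number of classes).
#' @param shape grid extents for the phantoms.
#' @param classes score classes to cover.
#' @param seed master seed.
#' @param config [MetricConfig-class] passed to [degradeMask()].
#' @param nBlobs,sizeRange phantom parameters, see [generatePhantom()].
#' @return list of [ScoredPair-class] objects.
#' @export
generateScoredSuite <- function(nPairs = 200L, shape = c(48L, 48L),
                                classes = 0:4, seed = 1L,
                                config = MetricConfig(),
                                nBlobs = 2L, sizeRange = c(2, 5)) {
  perClass <- ceiling(nPairs / length(classes))
  total <- perClass * length(classes)
  seeds <- .subSeeds(seed, 2L * total)
  pairs <- vector("list", total)
  i <- 0L
  for (cls in classes) {
    for (r in seq_len(perClass)) {
      i <- i + 1L
      ref <- generatePhantom(shape, nBlobs = nBlobs, sizeRange = sizeRange,
                             seed = seeds[i])
      pairs[[i]] <- degradeMask(ref, cls, seed = seeds[total + i],
                                config = config)
    }
  }
  pairs
}
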