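#' Read a binary mask from PNG, TIFF, or NIfTI
#'
#' Any nonzero stored value (in any channel, for multi-channel images)
#' becomes a positive element; zeros are negative. NIfTI volumes must be
#' integer-valued to within a small tolerance — soft probability maps
#' are rejected so that thresholding stays an explicit, user-visible
#' step. NIfTI voxel spacing is read and reported but never used by the
#' metrics, which treat one dilation step as one element along any axis;
#' anisotropic spacing triggers a warning to make that assumption
#' visible.
#'
#' @param path file path; format inferred from the extension unless
#'   \code{format} is given.
#' @param format \code{"auto"}, \code{"png"}, \code{"tiff"}, or
#'   \code{"nifti"}.
#' @return a [BinaryMask-class]; 2-D for PNG/TIFF, 3-D for NIfTI (axis
#'   order as stored, no reorientation).
#' @export
readMask <- function(path, format = c("auto", "png", "tiff", "nifti")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
    format <- switch(ext, png = "png", tif = "tiff", tiff = "tiff",
                     nii = "nifti",
                     stop(sprintf("cannot infer mask format from '%s'", path)))
  }
  arr <- switch(format,
    png = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    nifti = {
      img <- RNifti::readNifti(path)
      pd <- attr(img, "pixdim")
      if (!is.null(pd) && length(pd) >= 3 &&
          length(unique(round(pd[1:min(3, length(pd))], 6))) > 1L)
        warning(sprintf(
          "anisotropic voxel spacing (%s) ignored: dilation treats voxels as isotropic",
          paste(signif(pd, 4), collapse = " x ")))
      v <- as.array(img)
      if (any(abs(v - round(v)) > 1e-6))
        stop("NIfTI volume is not integer-valued: refusing to binarise implicitly")
      v
    })
  d <- dim(arr)
  if (format %in% c("png", "tiff") && length(d) == 3L) {
    arr <- apply(arr != 0, c(1L, 2L), any)   # any channel nonzero
    d <- dim(arr)
  }
  if (length(d) > 3L) {
    # drop trailing singleton dimensions (common in NIfTI files)
    while (length(d) > 3L && d[length(d)] == 1L) d <- d[-length(d)]
    if (length(d) > 3L)
      stop(sprintf("mask has more than 3 dimensions: %s",
                   paste(dim(arr), collapse = " x ")))
    arr <- array(arr, d)
  }
  BinaryMask(arr != 0)
}

#' Write a binary mask to PNG, TIFF, or NIfTI
#'
#' 2-D masks are written as 8-bit grayscale images (0 / maximum
#' intensity); 3-D masks as NIfTI volumes of 0/1. A written mask read
#' back with [readMask()] reproduces the grid bit-exactly.
#'
#' @param mask a [BinaryMask-class] (or 0/1 array).
#' @param path destination path; the extension selects the format
#'   (.png, .tif/.tiff, .nii).
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  mask <- .asMask(mask)
  g <- maskGrid(mask)
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", path)))
  if (ext %in% c("png", "tif", "tiff") && length(dim(g)) != 2L)
    stop("PNG/TIFF output requires a 2-D mask; use NIfTI for volumes")
  if (ext == "nii" && length(dim(g)) != 3L)
    stop("NIfTI output expects a 3-D mask")
  switch(ext,
    png = png::writePNG(array(as.numeric(g), dim(g)), path),
    tif = ,
    tiff = tiff::writeTIFF(array(as.numeric(g), dim(g)), path),
    nii = RNifti::writeNifti(RNifti::asNifti(array(as.integer(g), dim(g))),
                             path),
    stop(sprintf("unsupported mask output extension '.%s'", ext)))
  invisible(path)
}

#' Read a batch manifest
#'
#' A CSV pairing reference and prediction mask files, with columns
#' \code{id}, \code{reference}, \code{prediction}, and optionally
#' \code{score} (ordinal 0..4). Relative paths are resolved against the
#' manifest's directory.
#'
#' @param path CSV file path.
#' @return data frame with resolved paths.
#' @export
readManifest <- function(path) {
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "reference", "prediction")
  if (!all(need %in% names(mf)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  mf$reference <- resolve(mf$reference)
  mf$prediction <- resolve(mf$prediction)
  if ("score" %in% names(mf) && any(!mf$score %in% 0:4))
    stop("manifest scores must be integers in 0..4")
  mf
}

#' Evaluate a batch of mask pairs
#'
#' Computes DSC, WDC, LDC, and hybrid WDC for every row of a manifest.
#' Per-row failures (unreadable files, shape mismatches) are recorded in
#' the \code{error} column and do not stop the batch. When scores are
#' present, the statistical battery (per-metric Spearman correlation
#' with the scores, per-class summaries, pairwise variance tests with
#' FDR correction) is attached as attributes.
#'
#' @param manifest data frame from [readManifest()], or a list of
#'   [ScoredPair-class] objects.
#' @param config a [MetricConfig-class].
#' @return data frame with one row per pair (id, metrics, degeneracy
#'   flag, error); attributes \code{spearman}, \code{classSummaries},
#'   \code{varianceTests} when scores are available, and \code{nFailed}.
#' @export
evaluateBatch <- function(manifest, config = MetricConfig()) {
  if (is.list(manifest) && !is.data.frame(manifest) &&
      all(vapply(manifest, is, logical(1), "ScoredPair")))
    return(.evaluatePairs(manifest, config))
  if (nrow(manifest) == 0L) {
    warning("empty manifest: nothing to evaluate")
    out <- data.frame(id = character(), DSC = numeric(), WDC = numeric(),
                      LDC = numeric(), hybridWDC = numeric(),
                      degenerate = character(), error = character())
    attr(out, "nFailed") <- 0L
    return(out)
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    res <- tryCatch({
      x <- readMask(r$reference)
      y <- readMask(r$prediction)
      v <- allMetrics(x, y, config)
      data.frame(id = as.character(r$id), DSC = v[["DSC"]],
                 WDC = v[["WDC"]], LDC = v[["LDC"]],
                 hybridWDC = v[["hybridWDC"]],
                 degenerate = degenerateFlag(dsc(x, y, config)),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(id = as.character(r$id), DSC = NA_real_, WDC = NA_real_,
                 LDC = NA_real_, hybridWDC = NA_real_,
                 degenerate = NA_character_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "nFailed") <- sum(!is.na(out$error))
  if ("score" %in% names(manifest)) {
    ok <- is.na(out$error)
    out$score <- manifest$score
    if (sum(ok) >= 3L)
      out <- .attachStats(out, out[ok, , drop = FALSE])
  }
  out
}

.evaluatePairs <- function(pairs, config) {
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    v <- allMetrics(p@reference, p@prediction, config)
    data.frame(id = as.character(i), DSC = v[["DSC"]], WDC = v[["WDC"]],
               LDC = v[["LDC"]], hybridWDC = v[["hybridWDC"]],
               degenerate = degenerateFlag(dsc(p@reference, p@prediction,
                                               config)),
               error = NA_character_, score = p@score)
  })
  out <- do.call(rbind, rows)
  attr(out, "nFailed") <- 0L
  .attachStats(out, out)
}

.attachStats <- function(out, ok) {
  mcols <- c("DSC", "WDC", "LDC", "hybridWDC")
  sp <- lapply(mcols, function(m)
    spearmanCorrelation(ok[[m]], ok$score))
  names(sp) <- mcols
  attr(out, "spearman") <- sp
  attr(out, "classSummaries") <-
    classSummaries(ok[mcols], ok$score)
  attr(out, "varianceTests") <-
    varianceTestTable(ok[c("DSC", "WDC", "LDC")], ok$score)
  out
}

#' Write a synthetic fixture set to disk
#'
#' Emits a seeded suite of scored pairs as PNG (2-D) or NIfTI (3-D)
#' files plus a CSV manifest (columns id, reference, prediction, score,
#' seed) that [readManifest()] and [evaluateBatch()] consume directly.
#'
#' @param dir output directory (created if needed).
#' @inheritParams generateScoredSuite
#' @return the manifest path, invisibly.
#' @export
writeFixtures <- function(dir, nPairs = 10L, shape = c(32L, 32L),
                          seed = 1L, config = MetricConfig()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- generateScoredSuite(nPairs, shape = shape, seed = seed,
                               config = config)
  ext <- if (length(shape) == 2L) "png" else "nii"
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    rf <- sprintf("pair%03d_ref.%s", i, ext)
    pf <- sprintf("pair%03d_pred.%s", i, ext)
    writeMask(p@reference, file.path(dir, rf))
    writeMask(p@prediction, file.path(dir, pf))
    data.frame(id = sprintf("pair%03d", i), reference = rf,
               prediction = pf, score = p@score,
               seed = p@provenance$seed)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
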