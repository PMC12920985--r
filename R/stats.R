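#' Spearman rank correlation with ordinal scores
#'
#' Tie-corrected Spearman correlation: both sequences are converted to
#' average ranks and the product-moment correlation of the ranks is
#' taken, which handles the heavy ties that ordinal quality scores
#' produce. The two-sided p-value uses the t approximation with n - 2
#' degrees of freedom (\code{method = "asymptotic"}, appropriate for the
#' sample sizes metric-validation runs use); for very small samples an
#' exact permutation p-value over all n! orderings is available
#' (\code{method = "exact"}, n <= 8).
#'
#' @param values numeric metric values.
#' @param scores ordinal scores of equal length (>= 3).
#' @param method \code{"asymptotic"} or \code{"exact"}.
#' @return a [TestResult-class] with rho as the statistic.
#' @export
spearmanCorrelation <- function(values, scores,
                                method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  n <- length(values)
  if (length(scores) != n || n < 3L)
    stop("values and scores must have equal length >= 3")
  if (anyNA(values) || anyNA(scores))
    stop("missing values are not supported")
  rv <- rank(values)
  rs <- rank(scores)
  if (stats::sd(rv) == 0 || stats::sd(rs) == 0)
    stop("correlation undefined: an input sequence is constant")
  rho <- stats::cor(rv, rs)
  if (method == "exact") {
    if (n > 8L) stop("exact permutation method limited to n <= 8")
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rv[p], rs))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    lbl <- "Spearman rank correlation (exact permutation)"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    lbl <- "Spearman rank correlation (t approximation)"
  }
  new("TestResult", statistic = rho, pValue = min(p, 1),
      pValueFdr = NA_real_, method = lbl)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

#' Two-sided F test of equality of variances
#'
#' F = var(a) / var(b) with sample variances (n - 1 denominator) and the
#' two-sided p-value 2 min(P(F <= f), P(F >= f)) capped at 1, from the F
#' distribution with (n_a - 1, n_b - 1) degrees of freedom (delegated to
#' \code{stats::var.test}). Requires nonzero variance in at least one
#' sample; an all-constant pair is rejected, mirroring score classes
#' where a metric is identically zero and no variance comparison is
#' possible.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param level significance level for the reported decision flag.
#' @return a [TestResult-class] with the variance ratio as statistic and
#'   an extra \code{significant} attribute (logical, at \code{level}).
#' @export
fTestVariances <- function(a, b, level = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    stop("both samples have zero variance: F test undefined")
  ht <- stats::var.test(a, b)
  res <- new("TestResult", statistic = unname(ht$statistic),
             pValue = min(unname(ht$p.value), 1), pValueFdr = NA_real_,
             method = "F test of equality of variances (two-sided)")
  attr(res, "significant") <- unname(ht$p.value) < level
  res
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1
#' (delegated to \code{stats::p.adjust(method = "BH")} after range
#' validation).
#'
#' @param pValues numeric vector in \code{[0, 1]}.
#' @return adjusted p-values, same length and order.
#' @export
fdrCorrect <- function(pValues) {
  if (anyNA(pValues) || any(pValues < 0) || any(pValues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Per-score-class metric summaries
#'
#' Minimum, mean, maximum, and sample standard deviation (n - 1
#' denominator) of each metric within each score class; the per-class
#' descriptive table used to compare metric spread across quality
#' levels. Classes with a single member report \code{NA} for the sd;
#' classes absent from the data are omitted with a warning.
#'
#' @param metrics data frame (or named list) of numeric metric columns.
#' @param scores integer scores 0..4, one per row of \code{metrics}.
#' @return long-format data frame with columns \code{score},
#'   \code{metric}, \code{n}, \code{min}, \code{mean}, \code{max},
#'   \code{sd}.
#' @export
classSummaries <- function(metrics, scores) {
  metrics <- as.data.frame(metrics)
  if (nrow(metrics) != length(scores))
    stop("metrics and scores lengths differ")
  if (any(!scores %in% 0:4))
    stop("scores must be integers in 0..4")
  present <- sort(unique(scores))
  missing <- setdiff(0:4, present)
  if (length(missing) > 0L)
    warning(sprintf("no pairs in score class(es) %s; omitted",
                    paste(missing, collapse = ", ")))
  rows <- list()
  for (cls in present) {
    sel <- scores == cls
    for (m in names(metrics)) {
      v <- metrics[[m]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        score = cls, metric = m, n = length(v),
        min = min(v), mean = mean(v), max = max(v),
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Pairwise variance-equality tests per score class
#'
#' For every score class and every unordered pair of metric columns,
#' runs the two-sided F test of equality of variances and corrects the
#' whole family of p-values with Benjamini-Hochberg FDR control. Classes
#' where a pairing has zero variance on both sides (for example a class
#' where two metrics are identically 0) are skipped for that pairing.
#'
#' @inheritParams classSummaries
#' @param level significance level for the decision flags.
#' @return data frame with columns \code{score}, \code{metricA},
#'   \code{metricB}, \code{fStatistic}, \code{pValue}, \code{pValueFdr},
#'   \code{significant} (after FDR, at \code{level}).
#' @export
varianceTestTable <- function(metrics, scores, level = 0.05) {
  metrics <- as.data.frame(metrics)
  nm <- names(metrics)
  rows <- list()
  for (cls in sort(unique(scores))) {
    sel <- scores == cls
    if (sum(sel) < 2L) next
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      if (j <= i) next
      a <- metrics[[i]][sel]; b <- metrics[[j]][sel]
      if (stats::var(a) == 0 && stats::var(b) == 0) next
      ht <- fTestVariances(a, b, level = level)
      rows[[length(rows) + 1L]] <- data.frame(
        score = cls, metricA = nm[i], metricB = nm[j],
        fStatistic = testStatistic(ht), pValue = pValue(ht))
    }
  }
  if (length(rows) == 0L)
    return(data.frame(score = integer(), metricA = character(),
                      metricB = character(), fStatistic = numeric(),
                      pValue = numeric(), pValueFdr = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$pValueFdr <- fdrCorrect(out$pValue)
  out$significant <- out$pValueFdr < level
  out
}

#' @rdname TestResult-class
#' @aliases testStatistic,TestResult-method
#' @export
setMethod("testStatistic", "TestResult", function(object) object@statistic)

#' @rdname TestResult-class
#' @aliases pValue,TestResult-method
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname TestResult-class
#' @aliases pValueFdr,TestResult-method
#' @export
setMethod("pValueFdr", "TestResult", function(object) object@pValueFdr)

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s\n  statistic = %.4f, p = %.4g%s\n", object@method,
              object@statistic, object@pValue,
              if (is.na(object@pValueFdr)) ""
              else sprintf(", FDR-adjusted p = %.4g", object@pValueFdr)))
  invisible(NULL)
})
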