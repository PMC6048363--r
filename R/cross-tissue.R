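# Cross-tissue procedure: CPM expression filter, quantile
# normalization, sample dichotomization (mean-expression or
# density-minimum), and per-gene t-statistic ranking feeding GSEA.

#' Counts per million
#'
#' @param counts gene x sample non-negative count matrix.
#' @param lib_size per-sample library sizes; column sums by default.
#' @return CPM matrix (`count * 1e6 / library size`).
#' @export
cpm <- function(counts, lib_size = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (any(lib_size <= 0))
    stop(sprintf("degenerate sample: zero library size in column(s) %s",
                 paste(which(lib_size <= 0), collapse = ", ")))
  sweep(counts, 2L, lib_size, "/") * 1e6
}

#' Expression filter on summed CPM
#'
#' Keeps a gene iff the sum of its counts-per-million across all
#' samples is strictly greater than `threshold` (default 10).
#'
#' @inheritParams cpm
#' @param threshold strict lower bound on the CPM sum (default 10).
#' @return The filtered count matrix.
#' @export
cpmFilter <- function(counts, threshold = 10, lib_size = NULL) {
  keep <- rowSums(cpm(counts, lib_size)) > threshold
  as.matrix(counts)[keep, , drop = FALSE]
}

#' Quantile normalization
#'
#' Rank-based quantile normalization across columns (each column's
#' sorted values are replaced by the across-column mean of sorted
#' values; ties receive the mean of the reference values they span),
#' delegated to the standard microarray implementation. A single-row
#' matrix is returned unchanged.
#'
#' @param mat numeric matrix without missing values.
#' @return The normalized matrix; sorted columns are identical after
#'   normalization and the operation is idempotent.
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("quantile normalization requires complete data")
  if (nrow(mat) == 1L) return(mat)  # documented identity convention
  out <- limma::normalizeBetweenArrays(mat, method = "quantile")
  dimnames(out) <- dimnames(mat)
  out
}

#' Dichotomize samples by the mean
#'
#' Cutoff = arithmetic mean of the per-sample values; a sample exactly
#' at the cutoff is labeled `high` (documented boundary convention).
#'
#' @param values named numeric vector (one value per sample, >= 2).
#' @return list of class `SampleDichotomy`: `labels`
#'   (`high`/`low` per sample), `cutoff`, `cutoff_method`.
#' @export
dichotomizeByMean <- function(values) {
  if (length(values) < 2L) stop("need >= 2 samples")
  cutoff <- mean(values)
  labels <- ifelse(values >= cutoff, "high", "low")
  if (length(unique(labels)) < 2L)
    stop("empty-group error: all samples fall on one side of the mean")
  structure(list(labels = setNames(labels, names(values)),
                 cutoff = cutoff, cutoff_method = "mean_expression"),
            class = "SampleDichotomy")
}

#' @export
print.SampleDichotomy <- function(x, ...) {
  cat(sprintf("SampleDichotomy (%s): cutoff %.4g, high = %d, low = %d\n",
              x$cutoff_method, x$cutoff, sum(x$labels == "high"),
              sum(x$labels == "low")))
  invisible(x)
}

#' Density-minimum cutoff for a bimodal PSI distribution
#'
#' Gaussian-kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) on a uniform grid over [0, 1]; the cutoff is the grid
#' location of the minimum density strictly between the two highest
#' local maxima. A unimodal estimate raises a bimodality error (the
#' caller may fall back to a fixed cutoff).
#'
#' @param values PSI values in [0, 1].
#' @param grid_points density grid size (default 512).
#' @param min_peak_frac local maxima below this fraction of the global
#'   density maximum are treated as numerical ripple, not modes
#'   (default 0.05).
#' @return numeric cutoff.
#' @export
densityMinimumCutoff <- function(values, grid_points = 512L,
                                 min_peak_frac = 0.05) {
  if (any(values < 0 | values > 1)) stop("PSI values must lie in [0, 1]")
  d <- density(values, bw = "nrd0", n = grid_points, from = 0, to = 1)
  y <- d$y
  n <- length(y)
  is_max <- c(y[1L] > y[2L],
              y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              y[n] > y[n - 1])
  peaks <- which(is_max & y >= min_peak_frac * max(y))
  if (length(peaks) < 2L)
    stop("bimodality error: density estimate has fewer than 2 local maxima")
  top2 <- peaks[order(-y[peaks])][1:2]
  lo <- min(top2); hi <- max(top2)
  between <- (lo + 1L):(hi - 1L)
  d$x[between[which.min(y[between])]]
}

#' Dichotomize samples at the PSI density minimum
#'
#' @param values named PSI vector.
#' @inheritParams densityMinimumCutoff
#' @return A `SampleDichotomy` (see [dichotomizeByMean()]); `high`
#'   means at or above the density-minimum cutoff.
#' @export
dichotomizeByDensityMinimum <- function(values, grid_points = 512L) {
  cutoff <- densityMinimumCutoff(values, grid_points)
  labels <- ifelse(values >= cutoff, "high", "low")
  structure(list(labels = setNames(labels, names(values)),
                 cutoff = cutoff, cutoff_method = "density_minimum"),
            class = "SampleDichotomy")
}

#' Rank genes by two-sample t-statistic
#'
#' Per gene, the ordinary pooled-variance (Student) t-statistic of
#' high vs low samples (`high - low`); no empirical-Bayes variance
#' moderation is applied. The output is sorted by descending t, ties
#' broken by gene id. Genes with zero pooled variance get t = 0 and a
#' flag.
#'
#' @param mat gene x sample numeric matrix (typically
#'   quantile-normalized expression).
#' @param dichotomy a `SampleDichotomy`, or a character vector of
#'   `high`/`low` labels aligned with the columns.
#' @return data.frame: `gene, score` (the t-statistic),
#'   `zero_variance` flag; sorted as a ranked list for
#'   [gseaPreranked()].
#' @export
rankGenesByT <- function(mat, dichotomy) {
  labels <- if (inherits(dichotomy, "SampleDichotomy"))
    dichotomy$labels else dichotomy
  mat <- as.matrix(mat)
  if (length(labels) != ncol(mat))
    stop("one label per sample column is required")
  hi <- labels == "high"
  n1 <- sum(hi); n2 <- sum(!hi)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples")
  m1 <- rowMeans(mat[, hi, drop = FALSE])
  m2 <- rowMeans(mat[, !hi, drop = FALSE])
  v1 <- apply(mat[, hi, drop = FALSE], 1L, var)
  v2 <- apply(mat[, !hi, drop = FALSE], 1L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  zero <- !is.finite(t)
  t[zero] <- 0
  out <- data.frame(gene = rownames(mat), score = t,
                    zero_variance = zero, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene), ]
  rownames(out) <- NULL
  out
}
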