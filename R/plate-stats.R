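# Per-plate normalization of screen readouts: two-way median-polish
# B-scores and control-based normalized percent inhibition (NPI).

#' Two-way median polish
#'
#' Decomposes a plate matrix into `overall + row + column + residual`
#' by alternating row and column median sweeps (rows first), iterating
#' until the change in the total absolute residual is at most `tol` or
#' `max_iter` is reached. Missing values (masked wells) are allowed and
#' ignored by the medians.
#'
#' @param values numeric matrix (rows x columns), `NA` = masked well.
#' @param max_iter maximum sweep iterations (default 100).
#' @param tol convergence tolerance on the change in the sum of
#'   absolute residuals (default 1e-6).
#' @return An object of class `MedianPolishFit`: list with `overall`,
#'   `row_effects`, `col_effects`, `residuals`, `iterations`,
#'   `converged`. `overall + row + col + residual` reproduces the input
#'   exactly (to floating tolerance).
#' @examples
#' fit <- medianPolish(outer(1:4, 1:5, "+"))
#' max(abs(fit$residuals))  # additive input: all residuals ~ 0
#' @export
medianPolish <- function(values, max_iter = 100L, tol = 1e-6) {
  x <- as.matrix(values)
  if (any(rowSums(!is.na(x)) < 2L))
    stop("degenerate input: a row has fewer than 2 non-missing values")
  if (any(colSums(!is.na(x)) < 2L))
    stop("degenerate input: a column has fewer than 2 non-missing values")
  overall <- 0
  re <- numeric(nrow(x))
  ce <- numeric(ncol(x))
  r <- x
  old_sum <- sum(abs(r), na.rm = TRUE)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    rm_ <- apply(r, 1L, median, na.rm = TRUE)
    r <- r - rm_
    re <- re + rm_
    dc <- median(ce)
    ce <- ce - dc
    overall <- overall + dc

    cm_ <- apply(r, 2L, median, na.rm = TRUE)
    r <- sweep(r, 2L, cm_)
    ce <- ce + cm_
    dr <- median(re)
    re <- re - dr
    overall <- overall + dr

    new_sum <- sum(abs(r), na.rm = TRUE)
    if (abs(old_sum - new_sum) <= tol) { converged <- TRUE; break }
    old_sum <- new_sum
  }
  structure(
    list(overall = overall, row_effects = re, col_effects = ce,
         residuals = r, iterations = it, converged = converged),
    class = "MedianPolishFit")
}

#' @export
print.MedianPolishFit <- function(x, ...) {
  cat(sprintf(
    "MedianPolishFit: %d x %d, overall %.4g, %d iteration(s)%s\n",
    nrow(x$residuals), ncol(x$residuals), x$overall, x$iterations,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

.plateMatrix <- function(w, readout, n_row, n_col, roles) {
  m <- matrix(NA_real_, n_row, n_col)
  keep <- w$well_role %in% roles
  m[cbind(w$row[keep], w$col[keep])] <- w[[readout]][keep]
  m
}

#' B-scores for a plate set
#'
#' For every plate (plate_id x replicate) the selected readout is
#' decomposed by [medianPolish()] fitted on the wells selected by
#' `fit_on` (sample wells by default: controls occupy fixed positions
#' and would bias the positional effects). Every well's residual is
#' `value - overall - row effect - column effect`, and the B-score is
#' `residual / (1.4826 x MAD of the plate's sample-well residuals)`.
#' Control wells are scored through the fit obtained from sample wells.
#'
#' @param plates a [PlateSet-class].
#' @param readout readout column to normalize.
#' @param fit_on well roles used to fit the polish (default `"sample"`).
#' @param max_iter,tol passed to [medianPolish()].
#' @return data.frame in long format: `plate_id, replicate, row, col,
#'   well_role, sirna_id, gene_id, readout, residual, b, mad_scale`.
#' @export
bScore <- function(plates, readout, fit_on = "sample", max_iter = 100L,
                   tol = 1e-6) {
  stopifnot(is(plates, "PlateSet"))
  if (!readout %in% readoutNames(plates))
    stop(sprintf("unknown readout '%s'", readout))
  w <- wells(plates)
  key <- paste(w$plate_id, w$replicate, sep = "\r")
  out <- lapply(split(w, key), function(pw) {
    m <- .plateMatrix(pw, readout, plates@n_row, plates@n_col, fit_on)
    # rows/columns with < 2 fitted wells (an all-control column, the
    # tail of a partial plate) cannot support a positional estimate and
    # are excluded from the polish; wells there are scored with a zero
    # effect for the missing dimension (effects are median-centered,
    # so 0 is neutral)
    good_r <- seq_len(nrow(m)); good_c <- seq_len(ncol(m))
    repeat {
      mm <- m[good_r, good_c, drop = FALSE]
      gr <- which(rowSums(!is.na(mm)) >= 2L)
      gc <- which(colSums(!is.na(mm)) >= 2L)
      if (length(gr) == length(good_r) && length(gc) == length(good_c))
        break
      good_r <- good_r[gr]; good_c <- good_c[gc]
      if (length(good_r) < 2L || length(good_c) < 2L)
        stop(sprintf(
          "degenerate plate: too few fitted wells on plate %s replicate %s",
          pw$plate_id[1L], pw$replicate[1L]))
    }
    fit <- medianPolish(m[good_r, good_c, drop = FALSE],
                        max_iter = max_iter, tol = tol)
    re_full <- numeric(plates@n_row)
    ce_full <- numeric(plates@n_col)
    re_full[good_r] <- fit$row_effects
    ce_full[good_c] <- fit$col_effects
    res <- pw[[readout]] - fit$overall - re_full[pw$row] -
      ce_full[pw$col]
    samp_res <- res[pw$well_role %in% fit_on]
    scale <- mad(samp_res)  # 1.4826 * median absolute deviation
    if (!is.finite(scale) || scale == 0)
      stop(sprintf("degenerate plate: MAD of residuals is 0 on plate %s replicate %s",
                   pw$plate_id[1L], pw$replicate[1L]))
    data.frame(pw[, c("plate_id", "replicate", "row", "col", "well_role",
                      "sirna_id", "gene_id")],
               readout = readout, residual = res, b = res / scale,
               mad_scale = scale, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plate_id, out$replicate, out$col, out$row), ]
}

#' Normalized percent inhibition (NPI)
#'
#' Rescales every well of a plate between the plate's own control
#' means: `npi(x) = (x - pos_mean) / (neg_mean - pos_mean)`, so 1 means
#' indistinguishable from the negative (scramble) controls and 0 from
#' the positive controls. With inhibitory positive controls, a well
#' with NPI below 0.8 shows at least 20% of the control inhibition.
#'
#' @param plates a [PlateSet-class] with at least 2 negative and 2
#'   positive control wells per plate.
#' @param readout readout column.
#' @return data.frame: `plate_id, replicate, row, col, well_role,
#'   sirna_id, gene_id, readout, npi, neg_mean, pos_mean`.
#' @export
npi <- function(plates, readout) {
  stopifnot(is(plates, "PlateSet"))
  if (!readout %in% readoutNames(plates))
    stop(sprintf("unknown readout '%s'", readout))
  w <- wells(plates)
  key <- paste(w$plate_id, w$replicate, sep = "\r")
  out <- lapply(split(w, key), function(pw) {
    neg <- pw[[readout]][pw$well_role == "negative_control"]
    pos <- pw[[readout]][pw$well_role == "positive_control"]
    if (length(neg) < 2L || length(pos) < 2L)
      stop(sprintf(
        "plate %s replicate %s needs >= 2 negative and >= 2 positive control wells",
        pw$plate_id[1L], pw$replicate[1L]))
    nm <- mean(neg); pm <- mean(pos)
    if (nm == pm)
      stop(sprintf(
        "degenerate controls: negative and positive means equal on plate %s replicate %s",
        pw$plate_id[1L], pw$replicate[1L]))
    data.frame(pw[, c("plate_id", "replicate", "row", "col", "well_role",
                      "sirna_id", "gene_id")],
               readout = readout,
               npi = (pw[[readout]] - pm) / (nm - pm),
               neg_mean = nm, pos_mean = pm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$plate_id, out$replicate, out$col, out$row), ]
}

#' Scramble-control cutoffs
#'
#' Mean +/- k SD (n-1 denominator) of the negative-control (scramble)
#' B-scores; the screen's hit-calling cutoff lines.
#'
#' @param scramble_b numeric vector of scramble B-scores (>= 3 values).
#' @param k number of SDs (default 2).
#' @return numeric `c(lower, upper)`.
#' @export
scrambleSdCutoffs <- function(scramble_b, k = 2) {
  if (length(scramble_b) < 3L)
    stop("sample-size error: need at least 3 scramble B-scores")
  m <- mean(scramble_b)
  s <- sd(scramble_b)
  c(lower = m - k * s, upper = m + k * s)
}
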