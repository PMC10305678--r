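#' Pair augmented absorption spectra with fluorescence feature blocks
#'
#' Fluorescence blocks exist only at the measured mixture labels, while the
#' augmented absorption dataset is dense in COD. Each absorption spectrum
#' is paired with the elementwise linear interpolation of the two measured
#' blocks bracketing its label; labels outside the measured range clamp to
#' the nearest block.
#'
#' @param labels COD labels of the absorption spectra (mg/L).
#' @param block_labels COD labels of the measured blocks (ascending).
#' @param blocks List of `feature_block`s (or 5 x 128 matrices) matching
#'   `block_labels`.
#' @return Matrix with one flattened block row per label.
#' @export
pair_fluorescence <- function(labels, block_labels, blocks) {
  if (length(blocks) == 0) abort("need at least one measured block")
  if (length(blocks) != length(block_labels)) {
    abort("blocks and block_labels must align")
  }
  ord <- order(block_labels)
  block_labels <- block_labels[ord]
  blocks <- blocks[ord]
  bm <- do.call(rbind, lapply(blocks, function(b) {
    as.vector(if (inherits(b, "feature_block")) b$matrix else b)
  }))
  if (nrow(bm) == 1) {
    return(bm[rep(1, length(labels)), , drop = FALSE])
  }
  x <- pmin(pmax(labels, block_labels[1]), block_labels[length(block_labels)])
  lo <- findInterval(x, block_labels, rightmost.closed = TRUE)
  lo <- pmin(lo, length(block_labels) - 1L)
  w <- (x - block_labels[lo]) / (block_labels[lo + 1L] - block_labels[lo])
  (1 - w) * bm[lo, , drop = FALSE] + w * bm[lo + 1L, , drop = FALSE]
}

#' COD retrieval metrics
#'
#' Computes the standard retrieval quality measures: mean squared error
#' (mg^2 L^-2), residual sum of squares `RSS = n * MSE`, coefficient of
#' determination `R^2 = 1 - RSS/TSS`, relative root mean square error of
#' prediction `RRMSEP = 100 * RMSE / mean(truth)` (%), the ordinary
#' least-squares slope of predictions on truths, and the percentage of
#' predictions within the relative-error tolerance (default 5%).
#'
#' @param predictions,truths Equal-length numeric vectors (mg/L).
#' @param tolerance Acceptable relative error for the accuracy measure.
#' @return An object of class `retrieval_metrics` (named list with
#'   `r_square`, `mse`, `rrmsep`, `rss`, `fit_slope`, `accuracy_at_tol`,
#'   `n`, `tolerance`).
#' @export
evaluate_retrieval <- function(predictions, truths, tolerance = 0.05) {
  if (length(predictions) != length(truths) || length(truths) == 0) {
    abort("predictions and truths must be non-empty and equal length")
  }
  err <- predictions - truths
  mse <- mean(err^2)
  rss <- sum(err^2)
  tss <- sum((truths - mean(truths))^2)
  if (tss == 0) abort("R^2 undefined: truths have zero variance")
  r_square <- 1 - rss / tss
  rrmsep <- 100 * sqrt(mse) / mean(truths)
  fit_slope <- sum((truths - mean(truths)) * (predictions - mean(predictions))) / tss
  pos <- truths > 0
  if (!all(pos)) {
    warn(sprintf("%d non-positive truths excluded from the accuracy measure",
                 sum(!pos)))
  }
  accuracy <- 100 * mean(abs(err[pos]) / truths[pos] <= tolerance)
  structure(list(r_square = r_square, mse = mse, rrmsep = rrmsep, rss = rss,
                 fit_slope = fit_slope, accuracy_at_tol = accuracy,
                 n = length(truths), tolerance = tolerance),
            class = "retrieval_metrics")
}

#' @export
print.retrieval_metrics <- function(x, ...) {
  cat(sprintf(paste0("<retrieval_metrics> n = %d\n  R^2 %.4f | MSE %.4g | ",
                     "RRMSEP %.3f%% | RSS %.4g | slope %.4f | ",
                     "accuracy@%.0f%% %.1f%%\n"),
              x$n, x$r_square, x$mse, x$rrmsep, x$rss, x$fit_slope,
              100 * x$tolerance, x$accuracy_at_tol))
  invisible(x)
}
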