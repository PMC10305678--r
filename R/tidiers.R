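#' Tidy the training history of a fitted fusion network
#'
#' @param x A `fusion_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble (cycle, epoch, lr, train_loss,
#'   val_loss, val_r2).
#' @method tidy fusion_fit
#' @export
tidy.fusion_fit <- function(x, ...) x$history

#' One-row summary of a fitted fusion network
#'
#' @param x A `fusion_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the parameter count, epochs trained, best
#'   epoch and best validation R-squared.
#' @method glance fusion_fit
#' @export
glance.fusion_fit <- function(x, ...) {
  tibble::tibble(n_params = n_params(x), epochs = nrow(x$history),
                 best_epoch = x$best_epoch, best_val_r2 = x$best_val_r2)
}

#' Tidy a coefficient-of-variation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A tibble with one row per feature vector (`kernel`, `cv`).
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) {
  tibble::tibble(kernel = seq_along(x$cv), cv = x$cv)
}

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(method = x$method, mean_cv = x$mean_cv, n = length(x$cv))
}

#' Tidy retrieval metrics into a one-row tibble
#'
#' @param x A `retrieval_metrics`.
#' @param ... Unused.
#' @return A one-row tibble of all metrics.
#' @method glance retrieval_metrics
#' @export
glance.retrieval_metrics <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
generics::tidy

#' @export
generics::glance
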