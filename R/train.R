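#' Training configuration for the fusion network
#'
#' Adam with a per-epoch exponentially decaying learning rate, MSE loss,
#' and a best-validation-R-squared checkpoint. The default regimen is three
#' cycles of 50 epochs.
#'
#' @param lr0 Initial learning rate.
#' @param decay Multiplicative learning-rate factor per epoch, in (0, 1].
#' @param cycles Training cycles (>= 1).
#' @param epochs_per_cycle Epochs per cycle.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of the training set held out for validation.
#' @param seed Seed controlling the validation split, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-3, decay = 0.96, cycles = 3L,
                         epochs_per_cycle = 50L, batch_size = 32L,
                         val_fraction = 0.1, seed = 1L) {
  if (lr0 <= 0) abort("lr0 must be positive")
  if (decay <= 0 || decay > 1) abort("decay must lie in (0, 1]")
  if (cycles < 1) abort("cycles must be >= 1")
  structure(list(lr0 = lr0, decay = decay, cycles = as.integer(cycles),
                 epochs_per_cycle = as.integer(epochs_per_cycle),
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the fusion network
#'
#' Minimizes the mean squared error between predicted and true COD with
#' Adam, shuffled minibatches, per-epoch exponential learning-rate decay
#' and inverted dropout on the fused features. Inputs and labels are
#' z-standardized internally from the training set (statistics are stored
#' in the returned model, so predictions are in mg/L). After every epoch
#' the held-out validation loss and R-squared are logged; the parameters
#' with the best validation R-squared are the ones returned.
#'
#' @param net A [build_fusion_net()] network.
#' @param xabs Training absorption spectra (rows = samples).
#' @param xfluor Training fluorescence blocks, flattened (rows = samples);
#'   pass zeros for an absorption-only model.
#' @param y COD labels in mg/L.
#' @param cfg A [train_config()].
#' @return An object of class `fusion_fit`: list with `net` (best
#'   checkpoint), `history` (tibble: cycle, epoch, lr, train_loss,
#'   val_loss, val_r2), `best_epoch`, `cfg`.
#' @export
train_fusion <- function(net, xabs, xfluor, y, cfg = train_config()) {
  stopifnot(inherits(net, "fusion_net"), inherits(cfg, "train_config"))
  xa <- as_input_matrix(xabs, net$input_len, "xabs")
  xf <- as_input_matrix(xfluor, prod(net$fluor_dim), "xfluor")
  n <- nrow(xa)
  if (n != length(y) || n != nrow(xf)) abort("inputs and labels must align")
  if (n < 10) abort("training set too small")
  # standardization from the full training input
  net$norm$xa_center <- colMeans(xa)
  net$norm$xa_scale <- max(sd(xa), 1e-8)
  net$norm$xf_center <- colMeans(xf)
  net$norm$xf_scale <- max(sd(xf), 1e-8)
  net$norm$y_center <- mean(y)
  net$norm$y_scale <- max(sd(y), 1e-8)
  st <- standardize_inputs(net, xa, xf)
  ys <- (y - net$norm$y_center) / net$norm$y_scale
  n_val <- max(2L, round(cfg$val_fraction * n))
  val_idx <- with_seed(cfg$seed, sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  xa_tr <- st$xa[tr_idx, , drop = FALSE]; xf_tr <- st$xf[tr_idx, , drop = FALSE]
  ys_tr <- ys[tr_idx]
  xa_val <- st$xa[val_idx, , drop = FALSE]; xf_val <- st$xf[val_idx, , drop = FALSE]
  y_val <- y[val_idx]
  opt <- adam_init(net$params)
  total_epochs <- cfg$cycles * cfg$epochs_per_cycle
  history <- vector("list", total_epochs)
  best <- list(r2 = -Inf, params = net$params, epoch = 0L)
  rng_seed <- cfg$seed + 1000L
  for (epoch in seq_len(total_epochs)) {
    lr <- cfg$lr0 * cfg$decay^(epoch - 1)
    ord <- with_seed(rng_seed + epoch, sample.int(length(tr_idx)))
    epoch_loss <- 0
    n_batches <- 0L
    drop_seed <- rng_seed + 50000L + epoch
    batch_starts <- seq(1, length(ord), by = cfg$batch_size)
    masks_seed_counter <- 0L
    for (start in batch_starts) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
      masks_seed_counter <- masks_seed_counter + 1L
      fused <- nrow(net$params$Wh)
      dropmask <- with_seed(drop_seed + masks_seed_counter,
        matrix((runif(length(idx) * fused) >= net$dropout) / (1 - net$dropout),
               nrow = length(idx)))
      fw <- net_forward(net, xa_tr[idx, , drop = FALSE],
                        xf_tr[idx, , drop = FALSE],
                        training = TRUE, dropmask = dropmask)
      err <- fw$out - ys_tr[idx]
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      }
      epoch_loss <- epoch_loss + loss
      n_batches <- n_batches + 1L
      grads <- net_backward(net, fw$cache, 2 * err / length(err))
      upd <- adam_step(net$params, grads, opt, lr)
      net$params <- upd$params
      opt <- upd$state
    }
    pred_val <- batched_forward(net, xa_val, xf_val) * net$norm$y_scale +
      net$norm$y_center
    val_mse <- mean((pred_val - y_val)^2)
    tss <- sum((y_val - mean(y_val))^2)
    val_r2 <- if (tss > 0) 1 - sum((pred_val - y_val)^2) / tss else NA_real_
    history[[epoch]] <- tibble::tibble(
      cycle = ((epoch - 1L) %/% cfg$epochs_per_cycle) + 1L,
      epoch = epoch, lr = lr,
      train_loss = epoch_loss / n_batches,
      val_loss = val_mse, val_r2 = val_r2)
    if (is.finite(val_r2) && val_r2 > best$r2) {
      best <- list(r2 = val_r2, params = net$params, epoch = epoch)
    }
  }
  net$params <- best$params
  structure(list(net = net, history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, best_val_r2 = best$r2, cfg = cfg),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("<fusion_fit> %d epochs, best validation R^2 %.4f at epoch %d\n",
              nrow(x$history), x$best_val_r2, x$best_epoch))
  invisible(x)
}
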