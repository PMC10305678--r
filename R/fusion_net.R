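# Dual-branch fusion network for COD regression.
#
# The absorption branch is a 1D CNN of four dual-channel blocks (two
# sequential conv stages per block; each stage is two parallel length-3
# convolutions merged by elementwise addition, followed by ReLU and -- for
# all but the last stage -- max-pooling of length 2). Channels grow
# 16/16/32/32/64/64/128/128, so a 2559-point spectrum shrinks
# 2559 -> 1279 -> 639 -> 319 -> 159 -> 79 -> 39 -> 19 and the branch emits a
# 19 x 128 feature matrix. The 5 x 128 fluorescence feature block is
# concatenated (24 x 128 = 3072 values), flattened, passed through dropout,
# a ReLU hidden dense layer and a linear single-output layer.
#
# Everything (forward, backprop, Adam, dropout, exponential LR decay) is
# implemented with base matrix algebra; convolutions are im2col matrix
# products so the heavy lifting is BLAS. Because the two parallel
# convolutions of a stage act on the same input and are merged by addition,
# the forward pass may use their summed weights, and both receive the same
# gradient -- an exact identity, not an approximation.

conv_stage_plan <- function(input_len, channels = c(16, 32, 64, 128)) {
  in_ch <- c(1, rep(channels[-length(channels)], each = 2), channels[length(channels)])
  out_ch <- rep(channels, each = 2)
  n_stage <- length(out_ch)
  len_in <- integer(n_stage)
  len_out <- integer(n_stage)
  l <- input_len
  for (s in seq_len(n_stage)) {
    len_in[s] <- l
    if (s < n_stage) l <- l %/% 2L # conv is length-preserving; pool halves
    len_out[s] <- l
  }
  list(in_ch = in_ch, out_ch = out_ch, len_in = len_in, len_out = len_out,
       pooled = c(rep(TRUE, n_stage - 1), FALSE))
}

#' Build the dual-branch fusion network
#'
#' @param input_len Absorption spectrum length (default 2559).
#' @param channels Output channels of the four conv blocks.
#' @param fluor_dim Shape of the fluorescence feature block (default 5 x 128).
#' @param hidden Hidden dense width between the fused features and the
#'   linear output (default 175).
#' @param dropout Dropout rate on the flattened fused features (default 0.5,
#'   training only).
#' @param seed Seed for the (He-normal) weight initialization.
#' @return An object of class `fusion_net`.
#' @export
build_fusion_net <- function(input_len = 2559L, channels = c(16L, 32L, 64L, 128L),
                             fluor_dim = c(5L, 128L), hidden = 175L,
                             dropout = 0.5, seed = 1L) {
  plan <- conv_stage_plan(input_len, channels)
  if (plan$len_out[length(plan$len_out)] < 1) abort("input too short for the pooling plan")
  fluor_len <- prod(fluor_dim)
  branch_flat <- plan$len_out[length(plan$len_out)] * tail(plan$out_ch, 1)
  fused <- branch_flat + fluor_len
  params <- with_seed(seed, {
    p <- list()
    for (s in seq_along(plan$out_ch)) {
      fan_in <- 3 * plan$in_ch[s]
      sd0 <- sqrt(1 / fan_in) # two parallel convs sum, halving the variance each
      p[[paste0("W1_", s)]] <- matrix(rnorm(fan_in * plan$out_ch[s], sd = sd0), fan_in)
      p[[paste0("W2_", s)]] <- matrix(rnorm(fan_in * plan$out_ch[s], sd = sd0), fan_in)
      p[[paste0("b1_", s)]] <- numeric(plan$out_ch[s])
      p[[paste0("b2_", s)]] <- numeric(plan$out_ch[s])
    }
    p$Wh <- matrix(rnorm(fused * hidden, sd = sqrt(2 / fused)), fused)
    p$bh <- numeric(hidden)
    p$Wo <- matrix(rnorm(hidden, sd = sqrt(1 / hidden)), hidden)
    p$bo <- 0
    p
  })
  norm <- list(xa_center = numeric(input_len), xa_scale = 1,
               xf_center = numeric(fluor_len), xf_scale = 1,
               y_center = 0, y_scale = 1)
  structure(list(input_len = as.integer(input_len), channels = channels,
                 fluor_dim = fluor_dim, hidden = as.integer(hidden),
                 dropout = dropout, seed = as.integer(seed),
                 plan = plan, params = params, norm = norm),
            class = "fusion_net")
}

#' Number of trainable parameters
#'
#' @param net A `fusion_net` or `fusion_fit`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) {
  if (inherits(net, "fusion_fit")) net <- net$net
  sum(vapply(net$params, length, integer(1)))
}

#' @export
print.fusion_net <- function(x, ...) {
  cat(sprintf("<fusion_net> input %d, branch %d x %d, fluor %d x %d, hidden %d, %d parameters\n",
              x$input_len, x$plan$len_out[length(x$plan$len_out)],
              tail(x$plan$out_ch, 1), x$fluor_dim[1], x$fluor_dim[2],
              x$hidden, n_params(x)))
  invisible(x)
}

# --- layer primitives on the (L*B) x C activation layout ------------------
# conv3_fwd / conv3_bwd / maxpool2_fwd / maxpool2_bwd live in src/

net_forward <- function(net, xa, xf, training = FALSE, dropmask = NULL,
                        keep = FALSE) {
  plan <- net$plan
  p <- net$params
  b <- nrow(xa)
  a <- matrix(t(xa), ncol = 1) # (L*B) x 1, sample-major blocks
  cache <- list(acts = list(), pre_pool = list(), take1 = list())
  shapes <- list()
  for (s in seq_along(plan$out_ch)) {
    l <- plan$len_in[s]
    w <- p[[paste0("W1_", s)]] + p[[paste0("W2_", s)]]
    bias <- p[[paste0("b1_", s)]] + p[[paste0("b2_", s)]]
    a_out <- conv3_fwd(a, w, bias, l)
    if (plan$pooled[s]) {
      pooled <- maxpool2_fwd(a_out, l)
      a_next <- pooled$out
      take1 <- pooled$take1
    } else {
      take1 <- NULL
      a_next <- a_out
    }
    if (keep) shapes[[s]] <- c(len = plan$len_out[s], ch = plan$out_ch[s])
    if (training) {
      cache$acts[[s]] <- a
      cache$pre_pool[[s]] <- a_out
      cache$take1[s] <- list(take1)
    }
    a <- a_next
  }
  l_out <- plan$len_out[length(plan$len_out)]
  c_out <- tail(plan$out_ch, 1)
  # per-sample flatten of the 19 x 128 branch output
  a3 <- array(a, dim = c(l_out, b, c_out))
  f <- t(matrix(aperm(a3, c(1, 3, 2)), nrow = l_out * c_out, ncol = b))
  h <- cbind(f, xf)
  if (training) {
    if (is.null(dropmask)) {
      dropmask <- matrix((runif(length(h)) >= net$dropout) / (1 - net$dropout),
                         nrow = b)
    }
    h <- h * dropmask
  }
  z1 <- sweep(h %*% p$Wh, 2, p$bh, `+`)
  r1_mask <- z1 > 0
  r1 <- z1 * r1_mask
  out <- as.numeric(r1 %*% p$Wo + p$bo)
  res <- list(out = out)
  if (keep) res$shapes <- shapes
  if (training) {
    cache$branch_flat <- f
    cache$h <- h
    cache$dropmask <- dropmask
    cache$r1 <- r1
    cache$r1_mask <- r1_mask
    cache$b <- b
    res$cache <- cache
  }
  res
}

net_backward <- function(net, cache, dout) {
  plan <- net$plan
  p <- net$params
  b <- cache$b
  grads <- list()
  d1 <- matrix(dout, ncol = 1)
  grads$Wo <- crossprod(cache$r1, d1)
  grads$bo <- sum(d1)
  dr1 <- d1 %*% t(p$Wo)
  dz1 <- dr1 * cache$r1_mask
  grads$Wh <- crossprod(cache$h, dz1)
  grads$bh <- colSums(dz1)
  dh <- (dz1 %*% t(p$Wh)) * cache$dropmask
  branch_flat <- ncol(cache$branch_flat)
  df <- dh[, seq_len(branch_flat), drop = FALSE]
  l_out <- plan$len_out[length(plan$len_out)]
  c_out <- tail(plan$out_ch, 1)
  d3 <- aperm(array(t(df), dim = c(l_out, c_out, b)), c(1, 3, 2))
  da <- matrix(d3, nrow = l_out * b, ncol = c_out)
  for (s in rev(seq_along(plan$out_ch))) {
    l <- plan$len_in[s]
    if (!is.null(cache$take1[[s]])) {
      da <- maxpool2_bwd(cache$take1[[s]], da, l)
    }
    w <- p[[paste0("W1_", s)]] + p[[paste0("W2_", s)]]
    bw <- conv3_bwd(cache$acts[[s]], w, cache$pre_pool[[s]], da, l)
    grads[[paste0("W1_", s)]] <- bw$dW
    grads[[paste0("W2_", s)]] <- bw$dW
    grads[[paste0("b1_", s)]] <- as.numeric(bw$db)
    grads[[paste0("b2_", s)]] <- as.numeric(bw$db)
    if (s > 1) da <- bw$dA
  }
  grads
}

standardize_inputs <- function(net, xa, xf) {
  xa <- sweep(xa, 2, net$norm$xa_center) / net$norm$xa_scale
  xf <- sweep(xf, 2, net$norm$xf_center) / net$norm$xf_scale
  list(xa = xa, xf = xf)
}

as_input_matrix <- function(x, len, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != len) {
    abort(sprintf("%s must have %d columns, got %d", what, len, ncol(x)))
  }
  x
}

#' Predict COD from absorption spectra and fluorescence blocks
#'
#' Deterministic inference (dropout inactive).
#'
#' @param object A `fusion_net` or trained `fusion_fit`.
#' @param xabs Matrix of absorption spectra (rows = samples) or one vector.
#' @param xfluor Matrix of flattened 5 x 128 fluorescence blocks (rows =
#'   samples) or one vector. Use zeros for an absorption-only model.
#' @param ... Unused.
#' @return Numeric vector of COD predictions in mg/L.
#' @export
predict.fusion_net <- function(object, xabs, xfluor, ...) {
  xa <- as_input_matrix(xabs, object$input_len, "xabs")
  xf <- as_input_matrix(xfluor, prod(object$fluor_dim), "xfluor")
  if (nrow(xa) != nrow(xf)) abort("xabs and xfluor must have matching rows")
  st <- standardize_inputs(object, xa, xf)
  out <- batched_forward(object, st$xa, st$xf)
  out * object$norm$y_scale + object$norm$y_center
}

#' @rdname predict.fusion_net
#' @export
predict.fusion_fit <- function(object, xabs, xfluor, ...) {
  predict(object$net, xabs, xfluor, ...)
}

batched_forward <- function(net, xa, xf, batch = 256L) {
  n <- nrow(xa)
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx] <- net_forward(net, xa[idx, , drop = FALSE],
                            xf[idx, , drop = FALSE])$out
  }
  out
}
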