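#' Gabor kernel parameters
#'
#' A 2D Gabor kernel is a Gaussian-windowed complex sinusoid with
#' wavelength `lam` (pixels), orientation `theta` (radians, in `[0, pi/2)`
#' -- orientations at and beyond pi/2 mirror the ones below it), phase
#' `psi`, Gaussian bandwidth `sigma` (default `2*pi`) and aspect ratio
#' `gamma` (default 0.5).
#'
#' @param lam Sinusoid wavelength in pixels (> 0).
#' @param theta Orientation in radians, in `[0, pi/2)`.
#' @param psi Phase in radians, in `[-pi, pi]`.
#' @param sigma Gaussian bandwidth in pixels (> 0).
#' @param gamma Aspect ratio in `(0, 1]`.
#' @return An object of class `gabor_params`.
#' @export
gabor_params <- function(lam, theta, psi = 0, sigma = 2 * pi, gamma = 0.5) {
  if (lam <= 0) abort("lam must be positive")
  if (theta < 0 || theta >= pi / 2) abort("theta must lie in [0, pi/2)")
  if (psi < -pi || psi > pi) abort("psi must lie in [-pi, pi]")
  if (sigma <= 0) abort("sigma must be positive")
  if (gamma <= 0 || gamma > 1) abort("gamma must lie in (0, 1]")
  structure(list(lam = lam, theta = theta, psi = psi, sigma = sigma,
                 gamma = gamma), class = "gabor_params")
}

#' Spatial extent of a Gabor kernel
#'
#' The Gaussian envelope is an ellipse with short-axis radius `3*sigma` and
#' long-axis radius `3*sigma/gamma` (the 3-sigma rule). Its largest x/y
#' projections are
#' `Xmax = max(3*sigma*cos(theta), (3*sigma/gamma)*sin(theta))` and
#' `Ymax = max(3*sigma*sin(theta), (3*sigma/gamma)*cos(theta))`; the kernel
#' side is `ceil(max(Xmax, Ymax))` rounded up to the nearest odd integer so
#' the kernel has a center pixel.
#'
#' @param params A [gabor_params()].
#' @return Odd integer side length in pixels.
#' @export
kernel_extent <- function(params) {
  s3 <- 3 * params$sigma
  xmax <- max(s3 * cos(params$theta), s3 / params$gamma * sin(params$theta))
  ymax <- max(s3 * sin(params$theta), s3 / params$gamma * cos(params$theta))
  k <- ceiling(max(xmax, ymax))
  if (k %% 2 == 0) k <- k + 1
  as.integer(k)
}

#' Evaluate a Gabor kernel on its integer grid
#'
#' Real and imaginary parts of
#' `exp(-(x'^2 + gamma^2 y'^2) / (2 sigma^2)) * exp(i (2 pi x' / lam + psi))`
#' with rotated coordinates `x' = x cos(theta) + y sin(theta)`,
#' `y' = -x sin(theta) + y cos(theta)`, evaluated at integer offsets
#' centered at 0 with side [kernel_extent()].
#'
#' @param params A [gabor_params()].
#' @return An object of class `gabor_kernel`: list with `real`, `imag`
#'   (K x K matrices, rows indexing y, columns indexing x), `params`, `K`.
#' @export
gabor_kernel <- function(params) {
  k <- kernel_extent(params)
  h <- (k - 1L) / 2L
  x <- matrix(-h:h, nrow = k, ncol = k, byrow = TRUE)
  y <- matrix(-h:h, nrow = k, ncol = k)
  xr <- x * cos(params$theta) + y * sin(params$theta)
  yr <- -x * sin(params$theta) + y * cos(params$theta)
  env <- exp(-(xr^2 + params$gamma^2 * yr^2) / (2 * params$sigma^2))
  phase <- 2 * pi * xr / params$lam + params$psi
  structure(list(real = env * cos(phase), imag = env * sin(phase),
                 params = params, K = k), class = "gabor_kernel")
}

#' @export
print.gabor_kernel <- function(x, ...) {
  cat(sprintf("<gabor_kernel> %dx%d, lam=%g theta=%.4f psi=%g sigma=%.4f gamma=%g\n",
              x$K, x$K, x$params$lam, x$params$theta, x$params$psi,
              x$params$sigma, x$params$gamma))
  invisible(x)
}

#' Build a Gabor filter bank
#'
#' Kernels are ordered wavelength-major (all orientations of the first
#' wavelength, then the next). The defaults -- five wavelengths
#' `{3, 6, 9, 12, 15}` by seven orientations
#' `{0, pi/12, pi/8, pi/6, pi/4, pi/3, 3 pi/8}` -- give a 35-kernel bank.
#'
#' @param lams Sinusoid wavelengths in pixels.
#' @param thetas Orientations in radians.
#' @inheritParams gabor_params
#' @return An object of class `gabor_bank`: list of `gabor_kernel`s plus a
#'   parameter tibble.
#' @export
gabor_bank <- function(lams = c(3, 6, 9, 12, 15),
                       thetas = c(0, pi / 12, pi / 8, pi / 6, pi / 4,
                                  pi / 3, 3 * pi / 8),
                       psi = 0, sigma = 2 * pi, gamma = 0.5) {
  if (length(lams) == 0 || length(thetas) == 0) {
    abort("parameter grids must be non-empty")
  }
  grid <- expand.grid(theta = thetas, lam = lams)[c("lam", "theta")]
  if (anyDuplicated(grid)) abort("duplicate (lam, theta) pairs in the bank")
  kernels <- purrr::pmap(grid, function(lam, theta) {
    gabor_kernel(gabor_params(lam, theta, psi, sigma, gamma))
  })
  structure(list(kernels = kernels,
                 params = tibble::as_tibble(grid) |>
                   dplyr::mutate(psi = psi, sigma = sigma, gamma = gamma,
                                 K = vapply(kernels, `[[`, integer(1), "K"))),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank> %d kernels, lam in {%s}, theta in {%s} rad\n",
              length(x$kernels),
              paste(unique(x$params$lam), collapse = ", "),
              paste(signif(unique(x$params$theta), 4), collapse = ", ")))
  invisible(x)
}

#' @export
length.gabor_bank <- function(x) length(x$kernels)

# smallest integer >= n whose prime factors are all <= 7 (fast for R's fft)
good_fft_size <- function(n) {
  smooth <- function(m) {
    for (p in c(2, 3, 5, 7)) while (m %% p == 0) m <- m / p
    m == 1
  }
  while (!smooth(n)) n <- n + 1
  n
}

# reflect-pad (mirror without edge repetition) a matrix by hk on every side
reflect_pad <- function(m, hk) {
  n1 <- nrow(m); n2 <- ncol(m)
  if (hk >= n1 || hk >= n2) abort("kernel larger than image")
  ri <- c((hk + 1):2, 1:n1, (n1 - 1):(n1 - hk))
  ci <- c((hk + 1):2, 1:n2, (n2 - 1):(n2 - hk))
  m[ri, ci]
}

# complex cross-correlation of a real image with one Gabor kernel via FFT,
# same-size output, reflect border handling; fa is the precomputed FFT of
# the image embedded at top-left of a P x P zero matrix after hk-padding
correlate_kernel_fft <- function(fa, p_side, n1, n2, hk, kern) {
  k <- kern$K
  h <- (k - 1L) / 2L
  kc <- complex(real = kern$real, imaginary = kern$imag)
  dim(kc) <- c(k, k)
  kf <- kc[k:1, k:1, drop = FALSE] # flip: correlation via convolution
  kemb <- matrix(complex(real = 0, imaginary = 0), p_side, p_side)
  kemb[1:k, 1:k] <- kf
  conv <- fft(fa * fft(kemb), inverse = TRUE) / (p_side^2)
  rows <- (1:n1) + hk + h
  cols <- (1:n2) + hk + h
  conv[rows, cols, drop = FALSE]
}

# bilinear resize via separable corner-aligned weight matrices
bilinear_weights <- function(n_in, n_out) {
  if (n_in == 1) return(matrix(1, n_out, 1))
  u <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
  i0 <- pmin(floor(u), n_in - 1)
  f <- u - i0
  w <- matrix(0, n_out, n_in)
  w[cbind(seq_len(n_out), i0)] <- 1 - f
  w[cbind(seq_len(n_out), i0 + 1)] <- f
  w
}

resize_bilinear <- function(m, out_rows, out_cols = out_rows) {
  bilinear_weights(nrow(m), out_rows) %*% m %*% t(bilinear_weights(ncol(m), out_cols))
}

#' Apply a Gabor bank to an upsampled EEM
#'
#' Each kernel is cross-correlated with the EEM intensity image (complex
#' response from the real and imaginary parts jointly, computed by FFT with
#' reflect border padding), the complex magnitude is taken, min-max scaled
#' to the 0--255 grayscale range per response (a flat response scales to all
#' zeros), and bilinearly resized to the feature grid.
#'
#' @param eem An upsampled `eem` (default pipeline: 2217 x 2217).
#' @param bank A [gabor_bank()].
#' @param feature_side Side of the output feature grid (default 554, giving
#'   306,916 pixels per response); `NULL` keeps the input grid.
#' @param scale Min-max scale responses to `[0, 255]` (default TRUE; turn
#'   off to inspect raw magnitudes).
#' @return An object of class `response_stack`: list with `responses`
#'   (array `H x W x n_kernels`), `bank`, `feature_side`.
#' @export
apply_bank <- function(eem, bank, feature_side = 554L, scale = TRUE) {
  stopifnot(inherits(eem, "eem"), inherits(bank, "gabor_bank"))
  img <- eem$intensity
  n1 <- nrow(img); n2 <- ncol(img)
  kmax <- max(vapply(bank$kernels, `[[`, integer(1), "K"))
  if (kmax > n1 || kmax > n2) abort("kernel larger than image")
  hk <- (kmax - 1L) / 2L
  p_side <- good_fft_size(max(n1, n2) + 2L * hk + kmax - 1L)
  apad <- reflect_pad(img, hk)
  aemb <- matrix(0, p_side, p_side)
  aemb[seq_len(nrow(apad)), seq_len(ncol(apad))] <- apad
  fa <- fft(aemb)
  rm(aemb, apad)
  out_r <- if (is.null(feature_side)) n1 else feature_side
  out_c <- if (is.null(feature_side)) n2 else feature_side
  responses <- array(0, dim = c(out_r, out_c, length(bank$kernels)))
  for (ki in seq_along(bank$kernels)) {
    resp <- Mod(correlate_kernel_fft(fa, p_side, n1, n2, hk, bank$kernels[[ki]]))
    if (scale) {
      rng <- range(resp)
      resp <- if (diff(rng) == 0) resp * 0 else (resp - rng[1]) / diff(rng) * 255
    }
    if (!is.null(feature_side) && (out_r != n1 || out_c != n2)) {
      resp <- resize_bilinear(resp, out_r, out_c)
      if (scale) resp <- pmin(pmax(resp, 0), 255)
    }
    responses[, , ki] <- resp
  }
  structure(list(responses = responses, params = bank$params,
                 feature_side = c(out_r, out_c)), class = "response_stack")
}

#' @export
print.response_stack <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<response_stack> %d responses of %d x %d\n", d[3], d[1], d[2]))
  invisible(x)
}

#' Flatten Gabor responses into the fluorescence feature matrix
#'
#' Each response image is raster-flattened with the excitation index varying
#' slowest (responses are emission x excitation, so this is column-major
#' order); columns follow the bank order. On the default 554 x 554 grid with
#' the default 35-kernel bank the result is 306,916 x 35.
#'
#' @param stack A `response_stack`.
#' @param order `"excitation"` (excitation-major, default) or `"emission"`.
#' @return A pixels x kernels numeric matrix.
#' @export
flatten_features <- function(stack, order = c("excitation", "emission")) {
  order <- match.arg(order)
  stopifnot(inherits(stack, "response_stack"))
  d <- dim(stack$responses)
  out <- matrix(0, nrow = d[1] * d[2], ncol = d[3])
  for (ki in seq_len(d[3])) {
    r <- stack$responses[, , ki]
    out[, ki] <- if (order == "excitation") as.vector(r) else as.vector(t(r))
  }
  out
}

#' Export Gabor responses as 8-bit grayscale PNGs
#'
#' Writes one PNG per response (values are already in the 0--255 grayscale
#' range) for visual inspection.
#'
#' @param stack A `response_stack`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
export_response_png <- function(stack, dir, prefix = "response") {
  stopifnot(inherits(stack, "response_stack"))
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the png package is required for PNG export")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$responses)
  paths <- character(d[3])
  for (ki in seq_len(d[3])) {
    paths[ki] <- file.path(dir, sprintf("%s_%02d.png", prefix, ki))
    png::writePNG(pmin(pmax(stack$responses[, , ki] / 255, 0), 1), paths[ki])
  }
  invisible(paths)
}
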