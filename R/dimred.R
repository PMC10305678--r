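# Dimensionality reduction of the fluorescence feature matrix.
#
# The pixels x kernels feature matrix is treated as 35 samples (one per
# Gabor kernel) living in pixel space; each method embeds those samples
# into `n_components` dimensions. PCA and the random projections are
# implemented directly (no suitable packaged implementation is installed
# for FastICA/LLE, so both follow their standard published algorithms);
# Isomap is delegated to vegan::isomap.

reduce_methods <- function() c("PCA", "FastICA", "Isomap", "LLE", "GRP", "SRP")

pca_embed <- function(x, n_components) {
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc, nu = n_components, nv = 0)
  sweep(sv$u, 2, sv$d[seq_len(n_components)], `*`)
}

fastica_embed <- function(x, n_components, seed, max_iter = 200, tol = 1e-6) {
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  # whiten via the economy SVD (samples x dims, dims may be huge)
  sv <- svd(xc, nu = n_components, nv = 0)
  z <- t(sv$u) * sqrt(n) # n_components x n, unit covariance rows
  w <- with_seed(seed, matrix(rnorm(n_components^2), n_components))
  sym_decorrelate <- function(w) {
    e <- eigen(w %*% t(w), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*% t(e$vectors) %*% w
  }
  w <- sym_decorrelate(w)
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    w_new <- (g %*% t(z)) / n - diag(rowMeans(gp)) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) break
  }
  t(w %*% z) # n x n_components
}

knn_index <- function(d, k) {
  # d: dist matrix (n x n); returns n x k neighbor indices (self excluded)
  n <- nrow(d)
  t(vapply(seq_len(n), function(i) order(d[i, ])[2:(k + 1)], integer(k)))
}

lle_embed <- function(x, n_components, n_neighbors = 10, reg = 1e-3) {
  n <- nrow(x)
  if (n_neighbors >= n) abort("n_neighbors must be smaller than the sample count")
  d <- as.matrix(stats::dist(x))
  nb <- knn_index(d, n_neighbors)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    zi <- sweep(x[nb[i, ], , drop = FALSE], 2, x[i, ])
    g <- zi %*% t(zi)
    g <- g + diag(n_neighbors) * reg * sum(diag(g)) / n_neighbors
    wi <- solve(g, rep(1, n_neighbors))
    w[i, nb[i, ]] <- wi / sum(wi)
  }
  m <- t(diag(n) - w) %*% (diag(n) - w)
  e <- eigen(m, symmetric = TRUE)
  idx <- order(e$values)[2:(n_components + 1)] # drop the constant eigenvector
  e$vectors[, idx, drop = FALSE] * sqrt(n)
}

grp_embed <- function(x, n_components, seed) {
  d <- ncol(x)
  r <- with_seed(seed, matrix(rnorm(d * n_components, sd = 1 / sqrt(n_components)), d))
  x %*% r
}

srp_embed <- function(x, n_components, seed) {
  d <- ncol(x)
  density <- 1 / sqrt(d)
  scale <- sqrt(1 / (density * n_components))
  r <- with_seed(seed, {
    u <- runif(d * n_components)
    v <- numeric(d * n_components)
    v[u < density / 2] <- -scale
    v[u > 1 - density / 2] <- scale
    matrix(v, d)
  })
  x %*% r
}

#' Reduce the fluorescence feature matrix
#'
#' Embeds the kernel columns of a pixels x kernels feature matrix (each
#' kernel's flattened response is one high-dimensional sample) into
#' `n_components` dimensions, returned as a components x kernels matrix
#' (default 20 x 35).
#'
#' @param matrix Pixels x kernels feature matrix from [flatten_features()].
#' @param method One of `"PCA"`, `"FastICA"`, `"Isomap"`, `"LLE"`, `"GRP"`,
#'   `"SRP"`. PCA, Isomap and LLE are deterministic; the others use `seed`.
#' @param n_components Embedding dimension (default 20).
#' @param seed Seed for the stochastic methods.
#' @param n_neighbors Neighborhood size for Isomap/LLE (default 10).
#' @return An object of class `reduced_features`: list with `matrix`
#'   (components x kernels), `method`, `n_components`, `seed`.
#' @export
reduce_features <- function(matrix, method = "Isomap", n_components = 20L,
                            seed = 1L, n_neighbors = 10L) {
  method <- match.arg(method, reduce_methods())
  n_samples <- ncol(matrix)
  if (n_components >= n_samples) {
    abort("n_components must be smaller than the number of kernel columns")
  }
  x <- t(matrix) # samples x dims
  emb <- switch(method,
    PCA = pca_embed(x, n_components),
    FastICA = fastica_embed(x, n_components, seed),
    Isomap = {
      res <- tryCatch(
        vegan::isomap(stats::dist(x), ndim = n_components, k = n_neighbors),
        error = function(e) {
          abort(paste0("Isomap failed (", conditionMessage(e),
                       "); the neighborhood graph may be disconnected -- ",
                       "raise n_neighbors"))
        })
      pts <- res$points
      if (ncol(pts) < n_components) {
        # the double-centered geodesic matrix can have < n_components
        # positive eigenvalues; missing axes carry no variance and are
        # padded with zeros to keep the embedding width fixed
        inform(sprintf("Isomap produced %d positive axes; padding to %d",
                       ncol(pts), n_components))
        pts <- cbind(pts, matrix(0, nrow(pts), n_components - ncol(pts)))
      }
      pts[, seq_len(n_components), drop = FALSE]
    },
    LLE = lle_embed(x, n_components, n_neighbors),
    GRP = grp_embed(x, n_components, seed),
    SRP = srp_embed(x, n_components, seed)
  )
  structure(list(matrix = t(emb), method = method,
                 n_components = as.integer(n_components),
                 seed = as.integer(seed)),
            class = "reduced_features")
}

#' @export
print.reduced_features <- function(x, ...) {
  cat(sprintf("<reduced_features> %s: %d x %d (components x kernels)\n",
              x$method, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

column_cv <- function(m, eps = 1e-12) {
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2)) # population form
  cv <- ifelse(abs(mu) < eps, 0, sdev / abs(mu))
  cv
}

#' Mean coefficient of variation of a reduced feature matrix
#'
#' For each feature vector (column) the coefficient of variation is the
#' population standard deviation over the absolute mean; columns with
#' near-zero mean contribute 0. The summary score is the arithmetic mean
#' over columns -- larger means the feature vectors are more dispersed and
#' hence more discriminative.
#'
#' @param x A `reduced_features` object or a plain matrix (columns =
#'   feature vectors).
#' @return An object of class `cv_report`: list with `cv` (per column),
#'   `mean_cv`, `method`.
#' @export
mean_cv <- function(x) {
  m <- if (inherits(x, "reduced_features")) x$matrix else as.matrix(x)
  if (length(m) == 0) abort("matrix must be non-empty")
  cv <- column_cv(m)
  structure(list(cv = cv, mean_cv = mean(cv),
                 method = if (inherits(x, "reduced_features")) x$method else NA_character_),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s: mean Cv = %.4f over %d feature vectors\n",
              x$method %||% "?", x$mean_cv, length(x$cv)))
  invisible(x)
}

#' Compare dimensionality-reduction methods by mean Cv
#'
#' Runs each method, scores it with [mean_cv()], records the wall time, and
#' ranks by mean Cv (descending). A method failure is recorded in the
#' result rather than aborting the comparison. GRP is omitted from the
#' default method list because random-projection Cv scores are unstable
#' across draws; it can be requested explicitly.
#'
#' @inheritParams reduce_features
#' @param methods Character vector of methods to compare.
#' @return A tibble with columns `method`, `mean_cv`, `seconds`, `seed`,
#'   `error` and a `cv` list-column, ranked by `mean_cv` descending.
#' @export
compare_methods <- function(matrix,
                            methods = c("PCA", "FastICA", "Isomap", "LLE", "SRP"),
                            n_components = 20L, seed = 1L, n_neighbors = 10L) {
  if (length(methods) == 0) abort("need at least one method")
  rows <- purrr::map(methods, function(m) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      red <- reduce_features(matrix, m, n_components, seed, n_neighbors)
      rep <- mean_cv(red)
      list(mean_cv = rep$mean_cv, cv = list(rep$cv), error = NA_character_)
    }, error = function(e) {
      list(mean_cv = NA_real_, cv = list(NULL), error = conditionMessage(e))
    })
    tibble::tibble(method = m, mean_cv = res$mean_cv,
                   seconds = proc.time()[["elapsed"]] - t0,
                   seed = as.integer(seed), error = res$error, cv = res$cv)
  })
  dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$mean_cv))
}

#' Select high-Cv kernels and reshape to the fusion feature block
#'
#' Ranks the kernel columns of a 20 x 35 reduced matrix by their
#' coefficient of variation, keeps the top 32 (640 values), and reshapes
#' them kernel-major into the 5 x 128 fluorescence feature block consumed
#' by the fusion network.
#'
#' @param reduced A `reduced_features` object (components x kernels) with
#'   at least 32 kernel columns.
#' @param n_keep Number of kernels to keep (default 32).
#' @param block_rows Rows of the output block (default 5).
#' @return An object of class `feature_block`: list with `matrix`
#'   (5 x 128), `kept_kernels` (column indices in bank order), `method`.
#' @export
select_and_reshape <- function(reduced, n_keep = 32L, block_rows = 5L) {
  m <- if (inherits(reduced, "reduced_features")) reduced$matrix else as.matrix(reduced)
  if (ncol(m) < n_keep) abort("fewer kernel columns than n_keep")
  n_el <- nrow(m) * n_keep
  if (n_el %% block_rows != 0) abort("selected elements do not reshape to block_rows")
  cv <- column_cv(m)
  kept <- sort(order(cv, decreasing = TRUE)[seq_len(n_keep)])
  sel <- m[, kept, drop = FALSE]
  block <- matrix(as.vector(sel), nrow = block_rows)
  structure(list(matrix = block, kept_kernels = kept,
                 method = if (inherits(reduced, "reduced_features")) reduced$method else NA_character_),
            class = "feature_block")
}

#' @export
print.feature_block <- function(x, ...) {
  cat(sprintf("<feature_block> %d x %d (%d values) from %d kernels\n",
              nrow(x$matrix), ncol(x$matrix), length(x$matrix),
              length(x$kept_kernels)))
  invisible(x)
}

#' Recover the selected components x kernels matrix from a feature block
#'
#' Inverse of the flatten/reshape in [select_and_reshape()].
#'
#' @param block A `feature_block`.
#' @param n_components Rows of the recovered matrix (default 20).
#' @return A components x kept-kernels matrix.
#' @export
unreshape_block <- function(block, n_components = 20L) {
  matrix(as.vector(block$matrix), nrow = n_components)
}
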