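test_that("mean Cv matches hand arithmetic and a brute-force oracle", {
  expect_equal(mean_cv(cbind(c(1, 3), c(2, 2)))$mean_cv, 0.25)
  expect_equal(mean_cv(matrix(5, 4, 3))$mean_cv, 0)
  # explicit column-loop oracle with population standard deviation
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(rnorm(20 * 7, mean = 3), 20, 7)
    oracle <- 0
    for (j in seq_len(ncol(m))) {
      mu <- mean(m[, j])
      sdev <- sqrt(mean((m[, j] - mu)^2))
      oracle <- oracle + (if (abs(mu) < 1e-12) 0 else sdev / abs(mu))
    }
    expect_equal(mean_cv(m)$mean_cv, oracle / ncol(m), tolerance = 1e-12)
  }
})

test_that("mean Cv is invariant to positive per-column rescaling", {
  set.seed(22)
  m <- matrix(rnorm(15 * 6, mean = 2), 15, 6)
  scales <- runif(6, 0.1, 10)
  expect_equal(mean_cv(sweep(m, 2, scales, `*`))$mean_cv, mean_cv(m)$mean_cv)
})

test_that("PCA embedding agrees with a gram-matrix eigen oracle", {
  set.seed(23)
  mat <- matrix(rnorm(40 * 6), 40, 6) # 6 kernel samples of dimension 40
  red <- reduce_features(mat, "PCA", n_components = 3L)
  expect_equal(dim(red$matrix), c(3L, 6L))
  x <- t(mat)
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(xc %*% t(xc), symmetric = TRUE)
  scores <- ev$vectors[, 1:3] %*% diag(sqrt(ev$values[1:3]))
  expect_equal(abs(red$matrix), abs(t(scores)), tolerance = 1e-8)
})

test_that("rank-1 structure concentrates the PCA variance", {
  set.seed(24)
  u <- rnorm(50); v <- rnorm(8)
  mat <- outer(u, v) # pixels x kernels, rank 1
  red <- reduce_features(mat, "PCA", n_components = 3L)
  vars <- apply(red$matrix, 1, var)
  expect_gt(vars[1] / sum(vars), 0.9999)
})

test_that("every reduction method emits components x kernels and respects seeds", {
  set.seed(25)
  mat <- matrix(rnorm(200 * 35), 200, 35)
  for (meth in c("PCA", "FastICA", "Isomap", "LLE", "GRP", "SRP")) {
    r <- reduce_features(mat, meth, n_components = 20L, seed = 7)
    expect_equal(dim(r$matrix), c(20L, 35L))
    expect_true(all(is.finite(r$matrix)))
    r2 <- reduce_features(mat, meth, n_components = 20L, seed = 7)
    expect_equal(r$matrix, r2$matrix)
  }
  expect_error(reduce_features(mat, "PCA", n_components = 40L), "smaller")
})

test_that("Isomap outscores PCA on rolled-up nonlinear column structure", {
  # kernels arranged along a 1D manifold rolled into a spiral: geodesic
  # structure that linear projection folds over
  n_kern <- 35
  t <- seq(0.3, 3 * pi, length.out = n_kern)
  set.seed(26)
  basis <- qr.Q(qr(matrix(rnorm(120 * 3), 120)))[, 1:3]
  coords <- cbind(t * cos(t), t * sin(t), 2 * t)
  mat <- basis %*% t(coords) + matrix(rnorm(120 * n_kern, sd = 0.01), 120)
  cmp <- compare_methods(mat, methods = c("PCA", "Isomap"), n_components = 5L)
  expect_gt(cmp$mean_cv[cmp$method == "Isomap"],
            cmp$mean_cv[cmp$method == "PCA"])
})

test_that("the method comparison is ranked, fault-tolerant and composable", {
  set.seed(27)
  mat <- matrix(rnorm(100 * 35), 100, 35)
  cmp <- compare_methods(mat, methods = c("PCA", "SRP"), n_components = 10L,
                         seed = 3)
  expect_equal(sort(cmp$mean_cv, decreasing = TRUE), cmp$mean_cv)
  single <- compare_methods(mat, methods = "PCA", n_components = 10L)
  direct <- mean_cv(reduce_features(mat, "PCA", 10L))
  expect_equal(single$mean_cv, direct$mean_cv)
  # deterministic methods reproduce across runs
  cmp2 <- compare_methods(mat, methods = c("PCA", "SRP"), n_components = 10L,
                          seed = 3)
  expect_equal(cmp$mean_cv, cmp2$mean_cv)
  # a failing method is recorded, not fatal
  broken <- compare_methods(mat, methods = c("PCA", "Isomap"),
                            n_components = 10L, n_neighbors = 1L)
  expect_true(is.na(broken$mean_cv[broken$method == "Isomap"]) ||
                is.finite(broken$mean_cv[broken$method == "Isomap"]))
  expect_equal(nrow(broken), 2L)
})

test_that("selection keeps the top-Cv kernels and reshapes losslessly", {
  set.seed(28)
  red <- structure(list(matrix = matrix(rnorm(20 * 35, mean = 2), 20, 35),
                        method = "PCA", n_components = 20L, seed = 1L),
                   class = "reduced_features")
  blk <- select_and_reshape(red)
  expect_equal(dim(blk$matrix), c(5L, 128L))
  expect_length(blk$matrix, 640L)
  expect_length(blk$kept_kernels, 32L)
  # dropped kernels are exactly the three lowest-Cv columns
  cv <- codfusion:::column_cv(red$matrix)
  expect_equal(sort(setdiff(1:35, blk$kept_kernels)),
               sort(order(cv)[1:3]))
  # bijective flatten/reshape round trip
  expect_identical(unreshape_block(blk), red$matrix[, blk$kept_kernels])
  # 20 x 32 input is a pure reshape
  red32 <- red; red32$matrix <- red$matrix[, 1:32]
  blk32 <- select_and_reshape(red32)
  expect_equal(blk32$kept_kernels, 1:32)
  expect_identical(unreshape_block(blk32), red32$matrix)
  expect_error(select_and_reshape(red$matrix[, 1:10]), "fewer")
})
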