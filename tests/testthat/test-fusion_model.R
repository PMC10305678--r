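test_that("the absorption branch reproduces the published stage shapes", {
  net <- build_fusion_net(seed = 1)
  fw <- codfusion:::net_forward(net, matrix(rnorm(2 * 2559), 2),
                                matrix(0, 2, 640), keep = TRUE)
  shapes <- do.call(rbind, fw$shapes)
  # dual-channel block outputs: 639x16, 159x32, 39x64, 19x128
  expect_equal(unname(shapes[c(2, 4, 6, 8), "len"]), c(639, 159, 39, 19))
  expect_equal(unname(shapes[c(2, 4, 6, 8), "ch"]), c(16, 32, 64, 128))
  # fused feature matrix is 24 x 128 = 3072 values
  expect_equal(nrow(net$params$Wh), 24 * 128)
  expect_true(all(is.finite(fw$out)))
  # zero inputs give a finite scalar per sample
  z <- codfusion:::net_forward(net, matrix(0, 1, 2559), matrix(0, 1, 640))
  expect_length(z$out, 1L)
  expect_true(is.finite(z$out))
})

test_that("the default parameter count sits at the published scale", {
  net <- build_fusion_net()
  expect_gt(n_params(net), 733729 / 2)
  expect_lt(n_params(net), 733729 * 2)
})

test_that("backpropagation matches finite differences", {
  net <- small_net(seed = 3)
  # biases perturbed away from 0 so no ReLU sits exactly on its kink
  set.seed(42)
  for (nm in grep("^b", names(net$params), value = TRUE)) {
    net$params[[nm]] <- rnorm(length(net$params[[nm]]), sd = 0.1)
  }
  B <- 3
  xa <- matrix(rnorm(B * 300), B)
  xf <- matrix(rnorm(B * 8), B)
  y <- rnorm(B)
  fused <- nrow(net$params$Wh)
  dm <- matrix(sample(c(0, 2), B * fused, replace = TRUE), B)
  fw <- codfusion:::net_forward(net, xa, xf, training = TRUE, dropmask = dm)
  gr <- codfusion:::net_backward(net, fw$cache, 2 * (fw$out - y) / B)
  eps <- 1e-6
  set.seed(11)
  for (nm in names(net$params)) {
    for (t in 1:min(3, length(net$params[[nm]]))) {
      i <- if (length(net$params[[nm]]) > 1) sample(length(net$params[[nm]]), 1) else 1
      n2 <- net
      n2$params[[nm]][i] <- n2$params[[nm]][i] + eps
      l1 <- mean((codfusion:::net_forward(n2, xa, xf, training = TRUE,
                                          dropmask = dm)$out - y)^2)
      n2$params[[nm]][i] <- n2$params[[nm]][i] - 2 * eps
      l2 <- mean((codfusion:::net_forward(n2, xa, xf, training = TRUE,
                                          dropmask = dm)$out - y)^2)
      fd <- (l1 - l2) / (2 * eps)
      expect_lt(abs(fd - gr[[nm]][i]) / max(1e-4, abs(fd) + abs(gr[[nm]][i])),
                1e-4)
    }
  }
})

test_that("inference is deterministic and smooth; dropout trains only", {
  net <- small_net(seed = 5)
  xa <- rnorm(300); xf <- rnorm(8)
  p1 <- predict(net, xa, xf)
  p2 <- predict(net, xa, xf)
  expect_identical(p1, p2) # dropout inactive at inference
  p3 <- predict(net, xa + 1e-9, xf)
  expect_lt(abs(p3 - p1), 1e-3)
  # zeroed output layer predicts the bias alone
  net0 <- net
  net0$params$Wo[] <- 0
  net0$params$bo <- 1.5
  expect_equal(predict(net0, xa, xf), 1.5)
  expect_error(predict(net, rnorm(100), xf), "columns")
})

test_that("training reduces the loss and is seed-reproducible", {
  # noiseless linear problem: y is a linear functional of the spectrum
  set.seed(31)
  n <- 60
  xa <- matrix(rnorm(n * 300), n)
  w <- rnorm(300, sd = 0.1)
  y <- as.numeric(xa %*% w)
  xf <- matrix(0, n, 8)
  cfg <- train_config(cycles = 1L, epochs_per_cycle = 5L, batch_size = 16L,
                      seed = 2)
  fit <- train_fusion(small_net(seed = 7), xa, xf, y, cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  fit2 <- train_fusion(small_net(seed = 7), xa, xf, y, cfg)
  expect_identical(fit$history, fit2$history)
  expect_equal(nrow(fit$history), 5L)
  g <- glance(fit)
  expect_equal(g$epochs, 5L)
  expect_equal(tidy(fit), fit$history)
})

test_that("fluorescence blocks pair by bracketing-label interpolation", {
  b1 <- matrix(1, 2, 3); b2 <- matrix(3, 2, 3); b3 <- matrix(7, 2, 3)
  blocks <- list(b1, b2, b3)
  labels <- c(10, 20, 40)
  # at a measured label: exactly that block
  expect_equal(pair_fluorescence(20, labels, blocks)[1, ], rep(3, 6))
  # midpoint: elementwise mean
  expect_equal(pair_fluorescence(15, labels, blocks)[1, ], rep(2, 6))
  expect_equal(pair_fluorescence(30, labels, blocks)[1, ], rep(5, 6))
  # clamping below and above the measured range
  expect_equal(pair_fluorescence(c(1, 99), labels, blocks),
               rbind(rep(1, 6), rep(7, 6)))
  expect_error(pair_fluorescence(1, numeric(), list()), "at least one")
})

test_that("retrieval metrics match hand arithmetic and their identities", {
  perfect <- evaluate_retrieval(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r_square, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$rrmsep, 0)
  expect_equal(perfect$accuracy_at_tol, 100)
  m <- evaluate_retrieval(c(11, 19), c(10, 20))
  expect_equal(m$mse, 1)
  expect_equal(m$rss, 2)
  expect_equal(m$rrmsep, 100 * 1 / 15, tolerance = 1e-12)
  expect_equal(m$accuracy_at_tol, 50) # only |19-20|/20 = 5% passes
  expect_equal(m$fit_slope, 0.8)
  # constant predictor at the truth mean scores R^2 = 0
  const <- evaluate_retrieval(rep(15, 4), c(10, 14, 16, 20))
  expect_equal(const$r_square, 0)
  # rss = n * mse always
  set.seed(33)
  for (i in 1:10) {
    p <- runif(17, 1, 100); t <- runif(17, 1, 100)
    mm <- evaluate_retrieval(p, t)
    expect_equal(mm$rss, mm$n * mm$mse)
  }
  expect_error(evaluate_retrieval(c(1, 2), c(3, 3)), "zero variance")
  expect_warning(evaluate_retrieval(c(1, 2), c(0, 2)), "non-positive")
})
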