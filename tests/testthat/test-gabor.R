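test_that("kernel extent follows the 3-sigma envelope rule, rounded to odd", {
  expect_equal(kernel_extent(gabor_params(3, 0)), 39L) # long axis 3*sigma/gamma
  expect_equal(kernel_extent(gabor_params(3, 0, gamma = 1)), 19L)
  expect_equal(kernel_extent(gabor_params(3, pi / 4)), 27L)
  # always odd
  for (th in c(0, pi / 12, pi / 8, pi / 6, pi / 4, pi / 3, 3 * pi / 8)) {
    expect_equal(kernel_extent(gabor_params(3, th)) %% 2, 1)
  }
})

test_that("kernel values match the closed-form Gabor expression", {
  k <- gabor_kernel(gabor_params(3, 0))
  h <- (k$K - 1) / 2
  expect_equal(k$real[h + 1, h + 1], 1.0) # center, psi = 0
  expect_equal(k$imag[h + 1, h + 1], 0.0)
  # one pixel along x: exp(-1/(2 sigma^2)) * cos(2 pi / 3)
  expect_equal(k$real[h + 1, h + 2], -0.49371, tolerance = 1e-5)
  # even real part: g(-x, -y) = g(x, y)
  expect_equal(k$real, k$real[k$K:1, k$K:1])
  # psi shifts the center value to cos(psi)
  k2 <- gabor_kernel(gabor_params(5, pi / 6, psi = 0.7))
  h2 <- (k2$K - 1) / 2
  expect_equal(k2$real[h2 + 1, h2 + 1], cos(0.7))
  expect_equal(k2$imag[h2 + 1, h2 + 1], sin(0.7))
})

test_that("kernel energy is orientation-invariant up to support truncation", {
  thetas <- c(0, pi / 12, pi / 8, pi / 6, pi / 4, pi / 3, 3 * pi / 8)
  # closed-form oracle on one fixed wide grid: energy of the untruncated
  # kernel is exactly orientation-invariant (rotation preserves the
  # envelope integral)
  h <- 60
  x <- matrix(-h:h, 2 * h + 1, 2 * h + 1, byrow = TRUE)
  y <- matrix(-h:h, 2 * h + 1, 2 * h + 1)
  for (lam in c(3, 9, 15)) {
    e_wide <- vapply(thetas, function(th) {
      xr <- x * cos(th) + y * sin(th)
      yr <- -x * sin(th) + y * cos(th)
      sum(exp(-(xr^2 + 0.25 * yr^2) / (4 * pi^2))^2)
    }, numeric(1))
    expect_lt(diff(range(e_wide)) / mean(e_wide), 0.01)
    # the packaged kernels clip the envelope by the printed extent rule, so
    # their energies agree only to the truncation level
    e_pkg <- vapply(thetas, function(th) {
      k <- gabor_kernel(gabor_params(lam, th))
      sum(k$real^2 + k$imag^2)
    }, numeric(1))
    expect_lt(diff(range(e_pkg)) / mean(e_pkg), 0.10)
  }
})

test_that("the default bank has 35 kernels in wavelength-major order", {
  bank <- gabor_bank()
  expect_length(bank, 35L)
  expect_equal(bank$params$lam, rep(c(3, 6, 9, 12, 15), each = 7))
  # kernel index = (lam index) * 7 + (theta index), wavelength-major
  thetas <- c(0, pi / 12, pi / 8, pi / 6, pi / 4, pi / 3, 3 * pi / 8)
  for (li in 0:4) {
    for (ti in 0:6) {
      k <- bank$kernels[[li * 7 + ti + 1]]
      expect_equal(k$params$lam, c(3, 6, 9, 12, 15)[li + 1])
      expect_equal(k$params$theta, thetas[ti + 1])
    }
  }
  expect_length(gabor_bank(lams = 6, thetas = pi / 8), 1L)
  expect_error(gabor_bank(lams = c(3, 3), thetas = 0), "duplicate")
})

test_that("FFT filtering equals direct sliding-window correlation", {
  set.seed(10)
  img <- matrix(rnorm(64 * 64), 64)
  eem <- make_eem(img)
  bank <- gabor_bank(lams = c(3, 6), thetas = c(0, pi / 4),
                     sigma = 3, gamma = 0.8) # modest kernels keep this fast
  stack <- apply_bank(eem, bank, feature_side = NULL, scale = FALSE)
  for (ki in seq_along(bank$kernels)) {
    direct <- direct_gabor_response(img, bank$kernels[[ki]])
    expect_lt(max(abs(stack$responses[, , ki] - direct)), 1e-8)
  }
})

test_that("a unit impulse reproduces the kernel magnitude", {
  n <- 101
  img <- matrix(0, n, n); img[51, 51] <- 1
  eem <- make_eem(img)
  bank <- gabor_bank(lams = 3, thetas = pi / 6, sigma = 3, gamma = 0.8)
  k <- bank$kernels[[1]]
  h <- (k$K - 1) / 2
  stack <- apply_bank(eem, bank, feature_side = NULL, scale = FALSE)
  got <- stack$responses[(51 - h):(51 + h), (51 - h):(51 + h), 1]
  mag <- sqrt(k$real^2 + k$imag^2)
  # the Gaussian envelope is centro-symmetric, so the correlation image of
  # an impulse is the kernel magnitude itself
  expect_lt(max(abs(got - mag)), 1e-10)
  # all-zero image gives all-zero responses
  z <- apply_bank(make_eem(matrix(0, 64, 64)), bank, feature_side = NULL)
  expect_true(all(z$responses == 0))
})

test_that("scaled responses are gain-invariant in [0, 255]", {
  set.seed(3)
  img <- matrix(rnorm(64 * 64), 64)
  bank <- gabor_bank(lams = 3, thetas = 0, sigma = 3, gamma = 0.8)
  r1 <- apply_bank(make_eem(img), bank, feature_side = NULL)
  expect_true(all(r1$responses >= 0 & r1$responses <= 255))
  r2 <- apply_bank(make_eem(5 * img), bank, feature_side = NULL)
  expect_equal(r1$responses, r2$responses, tolerance = 1e-9)
})

test_that("the odd (imaginary) channel of every default kernel is DC-free", {
  # the sine factor is odd in x' on the symmetric integer grid, so its
  # kernel sum cancels exactly: the imaginary response channel ignores
  # constant image offsets (the even channel keeps the DC the closed-form
  # kernel expression carries)
  for (k in gabor_bank()$kernels) {
    expect_lt(abs(sum(k$imag)), 1e-10)
  }
})

test_that("mirrored orientations respond equivariantly to mirrored images", {
  set.seed(4)
  img <- matrix(rnorm(80 * 80), 80)
  th <- pi / 6
  b1 <- gabor_bank(lams = 6, thetas = th, sigma = 3, gamma = 0.8)
  # reflection of theta about pi/2 equals pi - theta; with the even real /
  # odd imaginary parts the magnitude response of pi - theta on the
  # x-flipped image mirrors the theta response
  k2 <- gabor_kernel(gabor_params(6, th, sigma = 3, gamma = 0.8))
  k2$real <- k2$real[, k2$K:1]
  k2$imag <- k2$imag[, k2$K:1]
  r1 <- apply_bank(make_eem(img), b1, feature_side = NULL, scale = FALSE)
  flipped <- img[, ncol(img):1]
  r2 <- direct_gabor_response(flipped, k2)
  expect_lt(max(abs(r1$responses[, , 1] - r2[, ncol(r2):1])), 1e-8)
})

test_that("flattening is excitation-major with bank-ordered columns", {
  set.seed(6)
  responses <- array(rnorm(4 * 3 * 2), dim = c(4, 3, 2)) # em x ex x kernels
  stack <- structure(list(responses = responses, feature_side = c(4L, 3L)),
                     class = "response_stack")
  flat <- flatten_features(stack)
  expect_equal(dim(flat), c(12L, 2L))
  # pixel (emission i, excitation j) maps to row (j-1)*H + i
  for (i in 1:4) for (j in 1:3) {
    expect_equal(flat[(j - 1) * 4 + i, 1], responses[i, j, 1])
  }
  # emission-major alternative
  flat2 <- flatten_features(stack, order = "emission")
  expect_equal(flat2[, 2], as.vector(t(responses[, , 2])))
  # single kernel gives a single column
  one <- structure(list(responses = responses[, , 1, drop = FALSE],
                        feature_side = c(4L, 3L)), class = "response_stack")
  expect_equal(ncol(flatten_features(one)), 1L)
})
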