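test_that("scatter bands are located from planted blank ridges", {
  ex <- excitation_grid(); em <- emission_grid()
  zero <- make_eem(matrix(0, 32, 9))
  b0 <- detect_scatter_bands(zero)
  expect_equal(b0$half_width_nm, c(0, 0))
  # planted first-order ridge: cells within 10 nm of em = ex
  exg <- matrix(ex, 32, 9, byrow = TRUE); emg <- matrix(em, 32, 9)
  ridge1 <- make_eem(1000 * (abs(emg - exg) <= 10))
  b1 <- detect_scatter_bands(ridge1)
  # perpendicular half-width of that band is 10/sqrt(2); allow one em step
  expect_lt(abs(b1$half_width_nm[1] - 10 / sqrt(2)), diff(em[1:2]))
  # second-order-only ridge
  ridge2 <- make_eem(1000 * (abs(emg - 2 * exg) <= 10))
  b2 <- detect_scatter_bands(ridge2)
  expect_equal(b2$half_width_nm[1], 0)
  expect_gt(b2$half_width_nm[2], 0)
})

test_that("Delaunay interpolation recovers affine fields in masked bands", {
  ex <- excitation_grid(); em <- emission_grid()
  f <- outer(em, ex, function(E, X) 2 + 0.01 * X - 0.005 * E)
  eem <- make_eem(f)
  bands <- tibble::tibble(order = c(1L, 2L), half_width_nm = c(12, 8))
  mask <- codfusion:::scatter_mask(eem, bands)
  expect_gt(sum(mask), 0)
  out <- remove_scatter(eem, bands)
  # affine fields are reproduced by barycentric-linear interpolation
  expect_lt(max(abs(out$intensity - f)), 1e-6)
  # unmasked cells bit-exact
  expect_identical(out$intensity[!mask], f[!mask])
})

test_that("scatter removal is idempotent, identity on empty bands, sign-safe", {
  set.seed(5)
  eem <- make_eem(matrix(abs(rnorm(32 * 9, 50, 20)), 32, 9))
  none <- tibble::tibble(order = c(1L, 2L), half_width_nm = c(0, 0))
  expect_identical(remove_scatter(eem, none)$intensity, eem$intensity)
  bands <- tibble::tibble(order = c(1L, 2L), half_width_nm = c(15, 10))
  once <- remove_scatter(eem, bands)
  twice <- remove_scatter(once, bands)
  expect_equal(twice$intensity, once$intensity)
  expect_true(all(once$intensity >= 0)) # convex combinations of >= 0 values
})

test_that("spline upsampling preserves knots, constants and scaling", {
  const <- make_eem(matrix(7, 32, 9))
  up <- upsample_eem(const, 65L)
  expect_equal(dim(up$intensity), c(65L, 65L))
  expect_equal(max(abs(up$intensity - 7)), 0, tolerance = 1e-9)
  # knot fidelity on grids where the fine grid contains the raw knots:
  # raw 5 x 9 grids upsampled to 33 (8 and 4 subdivisions per interval)
  set.seed(8)
  raw <- codfusion:::new_eem(seq(250, 378, length.out = 9),
                             seq(300, 620, length.out = 5),
                             matrix(abs(rnorm(45, 100, 30)), 5, 9))
  up2 <- upsample_eem(raw, 33L)
  ri <- seq(1, 33, by = 8); ci <- seq(1, 33, by = 4)
  expect_equal(up2$intensity[ri, ci], unname(raw$intensity), tolerance = 1e-9)
  # scalar homogeneity
  raw3 <- codfusion:::new_eem(raw$ex_wavelengths, raw$em_wavelengths,
                              3 * raw$intensity)
  expect_equal(upsample_eem(raw3, 33L)$intensity, 3 * up2$intensity,
               tolerance = 1e-12)
})

test_that("upsampling reaches the published fine grid from the raw grid", {
  e <- simulate_eem(c(tryptophan = 2), noise = noise_spec(0))
  up <- quiet(upsample_eem(e))
  expect_equal(dim(up$intensity), c(2217L, 2217L))
  expect_equal(range(up$ex_wavelengths), range(e$ex_wavelengths))
  expect_equal(range(up$em_wavelengths), range(e$em_wavelengths))
})

test_that("augmentation fills half-open label segments with exact counts", {
  noise0 <- noise_spec(0)
  s1 <- simulate_absorption(c(tyrosine = 5, tryptophan = 2), noise = noise0)
  s1$cod_label <- 9.34
  s2 <- simulate_absorption(c(tyrosine = 10, tryptophan = 4), noise = noise0)
  s2$cod_label <- 18.78
  aug <- quiet(augment_absorption(list(s1, s2), step = 0.01))
  # the printed two-knot segment count plus the blank-anchored prefix
  seg <- aug$cod_label > 9.34 & aug$cod_label <= 18.78
  expect_equal(sum(seg), 944L)
  expect_equal(nrow(aug$absorbance), fill_count(0, 18.78))
  # measured spectra preserved bit-exactly at their grid labels
  expect_identical(aug$absorbance[abs(aug$cod_label - 9.34) < 1e-9, ],
                   s1$absorbance)
  expect_identical(aug$absorbance[abs(aug$cod_label - 18.78) < 1e-9, ],
                   s2$absorbance)
  expect_equal(sum(aug$provenance == "measured"), 2L)
  expect_error(quiet(augment_absorption(list(s1, s1))), "duplicate")
})

test_that("augmented spectra vary continuously with the label", {
  ds <- quiet(generate_design_dataset(tiny_design(), noise = noise_spec(0)))
  aug <- quiet(augment_absorption(ds$spectra, step = 0.05))
  step_diffs <- apply(abs(diff(aug$absorbance)), 1, max)
  knot_mat <- do.call(rbind, lapply(ds$spectra, `[[`, "absorbance"))
  knot_gap <- max(abs(diff(rbind(0, knot_mat))))
  expect_lt(max(step_diffs), knot_gap)
})

test_that("the test split is disjoint, exhaustive and reproducible", {
  ds <- quiet(generate_design_dataset(tiny_design(), noise = noise_spec(0)))
  aug <- quiet(augment_absorption(ds$spectra, step = 0.05))
  n_all <- nrow(aug$absorbance)
  sp <- split_test(aug, n = 40L, seed = 11)
  expect_equal(nrow(sp$test$absorbance), 40L)
  expect_equal(nrow(sp$train$absorbance), n_all - 40L)
  expect_equal(sort(c(sp$train$cod_label, sp$test$cod_label)),
               sort(aug$cod_label))
  sp2 <- split_test(aug, n = 40L, seed = 11)
  expect_identical(sp$test_idx, sp2$test_idx)
  expect_error(split_test(aug, n = n_all), "smaller")
  sp3 <- split_test(aug, n = n_all - 1L, seed = 2)
  expect_equal(nrow(sp3$train$absorbance), 1L)
})

test_that("a 1000-sample split of the full design spans the label range", {
  ds <- quiet(generate_design_dataset(noise = noise_spec(0.002, 2)))
  aug <- quiet(augment_absorption(ds$spectra, step = 0.1))
  sp <- split_test(aug, n = 1000L, seed = 4)
  expect_lt(min(sp$test$cod_label), 10)
  expect_gt(max(sp$test$cod_label), 140)
})
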