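#' Locate Rayleigh scatter bands from a blank EEM
#'
#' Cells of the deionized-water blank brighter than `mean + k * sd` are
#' assigned to the nearest scatter order line (first order `em = ex`, second
#' order `em = 2 ex`); each order's half-width is the maximum perpendicular
#' distance (in nm) of its assigned cells from the line. A flat blank yields
#' empty bands (half-widths 0), not an error.
#'
#' @param blank An `eem` measured on the raw grid.
#' @param k Threshold multiplier (default 3).
#' @return An object of class `scatter_bands`: tibble with columns `order`,
#'   `half_width_nm`.
#' @export
detect_scatter_bands <- function(blank, k = 3) {
  stopifnot(inherits(blank, "eem"))
  z <- blank$intensity
  thr <- mean(z) + k * sd(z)
  hot <- which(z > thr, arr.ind = TRUE)
  half_widths <- c(`1` = 0, `2` = 0)
  if (nrow(hot) > 0) {
    em <- blank$em_wavelengths[hot[, 1]]
    ex <- blank$ex_wavelengths[hot[, 2]]
    # cells join the order line minimizing |em - o*ex|; each order's width
    # is then the largest perpendicular offset, |em - o*ex| / sqrt(1 + o^2)
    d1 <- abs(em - 1 * ex) / sqrt(2)
    d2 <- abs(em - 2 * ex) / sqrt(5)
    nearest <- ifelse(abs(em - 1 * ex) <= abs(em - 2 * ex), 1L, 2L)
    for (o in c(1L, 2L)) {
      d <- if (o == 1L) d1 else d2
      if (any(nearest == o)) half_widths[[as.character(o)]] <- max(d[nearest == o])
    }
  }
  structure(tibble::tibble(order = c(1L, 2L),
                           half_width_nm = as.numeric(half_widths)),
            class = c("scatter_bands", "tbl_df", "tbl", "data.frame"))
}

scatter_mask <- function(eem, bands) {
  exg <- matrix(eem$ex_wavelengths, nrow = length(eem$em_wavelengths),
                ncol = length(eem$ex_wavelengths), byrow = TRUE)
  emg <- matrix(eem$em_wavelengths, nrow = length(eem$em_wavelengths),
                ncol = length(eem$ex_wavelengths))
  mask <- matrix(FALSE, nrow = nrow(exg), ncol = ncol(exg))
  for (r in seq_len(nrow(bands))) {
    o <- bands$order[r]
    hw <- bands$half_width_nm[r]
    if (hw <= 0) next
    mask <- mask | (abs(emg - o * exg) / sqrt(1 + o^2) <= hw)
  }
  mask
}

#' Remove scatter ridges by Delaunay interpolation
#'
#' Cells within any scatter band are masked; the remaining
#' (excitation, emission, intensity) points are triangulated in the
#' wavelength plane and masked cells are refilled by barycentric-linear
#' interpolation. Masked cells outside the convex hull of the unmasked
#' points are set to 0. Unmasked cells are returned unchanged.
#'
#' @param eem An `eem` on a rectangular grid.
#' @param bands A `scatter_bands` object from [detect_scatter_bands()] or a
#'   tibble with columns `order`, `half_width_nm`.
#' @return The scatter-corrected `eem`.
#' @export
remove_scatter <- function(eem, bands) {
  stopifnot(inherits(eem, "eem"))
  mask <- scatter_mask(eem, bands)
  if (!any(mask)) return(eem)
  exg <- matrix(eem$ex_wavelengths, nrow = length(eem$em_wavelengths),
                ncol = length(eem$ex_wavelengths), byrow = TRUE)
  emg <- matrix(eem$em_wavelengths, nrow = length(eem$em_wavelengths),
                ncol = length(eem$ex_wavelengths))
  keep <- !mask
  if (sum(keep) < 3) abort("fewer than 3 unmasked cells; cannot interpolate")
  z <- eem$intensity
  z[mask] <- interp_delaunay(exg[keep], emg[keep], eem$intensity[keep],
                             exg[mask], emg[mask], fill = 0)
  new_eem(eem$ex_wavelengths, eem$em_wavelengths, z)
}

# spline evaluation is linear in the data values, so interpolation of many
# parallel series reduces to one weight matrix: column j holds the spline
# through the j-th indicator vector evaluated at `xout`
spline_weight_matrix <- function(x, xout, method = "natural") {
  n <- length(x)
  w <- matrix(0, nrow = length(xout), ncol = n)
  if (n < 4) {
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- 1
      w[, j] <- approx(x, e, xout, rule = 2)$y
    }
    attr(w, "fallback_linear") <- TRUE
    return(w)
  }
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    w[, j] <- splinefun(x, e, method = method)(xout)
  }
  w
}

#' Upsample an EEM by separable cubic splines
#'
#' Interpolates the raw EEM onto uniform `out_side x out_side` wavelength
#' grids spanning the raw ranges (emission axis first, then excitation).
#' Values at the original grid points are reproduced to interpolation
#' accuracy; negative interpolants are clipped to 0 (with a message). An
#' axis with fewer than 4 points falls back to linear interpolation with a
#' warning.
#'
#' @param eem A raw-grid `eem`.
#' @param out_side Side length of the upsampled grid (default 2217).
#' @return The upsampled `eem`.
#' @export
upsample_eem <- function(eem, out_side = 2217L) {
  stopifnot(inherits(eem, "eem"))
  ex_out <- seq(min(eem$ex_wavelengths), max(eem$ex_wavelengths),
                length.out = out_side)
  em_out <- seq(min(eem$em_wavelengths), max(eem$em_wavelengths),
                length.out = out_side)
  w_em <- spline_weight_matrix(eem$em_wavelengths, em_out)
  w_ex <- spline_weight_matrix(eem$ex_wavelengths, ex_out)
  if (isTRUE(attr(w_em, "fallback_linear")) || isTRUE(attr(w_ex, "fallback_linear"))) {
    warn("axis with fewer than 4 points: falling back to linear interpolation")
  }
  z <- w_em %*% eem$intensity %*% t(w_ex)
  n_neg <- sum(z < 0)
  if (n_neg > 0) {
    inform(paste0("clipped ", n_neg, " negative interpolants to 0"))
    z[z < 0] <- 0
  }
  new_eem(ex_out, em_out, z)
}

#' Augment an absorption dataset on a fine COD label grid
#'
#' For each wavelength channel, a cubic spline of absorbance versus COD
#' label is fit through the measured spectra (anchored by the blank at label
#' 0) and evaluated on the half-open label grid `(0, max label]` at the
#' given spacing. Measured spectra whose labels fall on the grid are
#' inserted bit-exactly. The total row count equals
#' `fill_count(0, max(label), step)`.
#'
#' @param measured List of `absorption_spectrum` objects (or a list as
#'   returned in `generate_design_dataset()$spectra`) with distinct
#'   `cod_label`s. If no blank (label 0) is present, an all-zero blank on
#'   the same grid is added as the anchor, with a message.
#' @param step Label spacing in mg/L (default 0.01).
#' @return An object of class `absorption_dataset`: list with
#'   `wavelengths`, `absorbance` (rows = labels), `cod_label`, `provenance`
#'   (`"measured"` or `"interpolated"`) and `step`.
#' @export
augment_absorption <- function(measured, step = 0.01) {
  if (length(measured) < 2) abort("need at least 2 measured spectra")
  labels <- vapply(measured, function(s) s$cod_label, numeric(1))
  if (anyNA(labels)) abort("all measured spectra must carry a COD label")
  if (anyDuplicated(labels)) abort("duplicate COD labels among measured spectra")
  wavelengths <- measured[[1]]$wavelengths
  for (s in measured) {
    if (!isTRUE(all.equal(s$wavelengths, wavelengths))) {
      abort("all spectra must share one wavelength grid")
    }
  }
  ord <- order(labels)
  labels <- labels[ord]
  knots <- do.call(rbind, lapply(measured[ord], function(s) s$absorbance))
  if (labels[1] != 0) {
    inform("no blank (label 0) among inputs; anchoring the grid with a zero spectrum")
    labels <- c(0, labels)
    knots <- rbind(0, knots)
  }
  grid <- label_grid(max(labels), step)
  w <- spline_weight_matrix(labels, grid)
  absorbance <- w %*% knots
  provenance <- rep("interpolated", length(grid))
  # measured knots on the grid are preserved bit-exactly
  knot_units <- round(labels / step)
  grid_units <- round(grid / step)
  hit <- match(knot_units, grid_units)
  for (i in which(!is.na(hit))) {
    absorbance[hit[i], ] <- knots[i, ]
    provenance[hit[i]] <- "measured"
  }
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 cod_label = grid, provenance = provenance, step = step),
            class = "absorption_dataset")
}

#' @export
print.absorption_dataset <- function(x, ...) {
  cat(sprintf("<absorption_dataset> %d spectra x %d wavelengths, labels (%g, %g] mg/L, step %g\n",
              nrow(x$absorbance), ncol(x$absorbance),
              0, max(x$cod_label), x$step))
  invisible(x)
}

#' Random train/test split of an augmented dataset
#'
#' Uniform sampling without replacement; the complement is the training
#' set. Reproducible given the seed.
#'
#' @param dataset An `absorption_dataset`.
#' @param n Test-set size (default 1000), must be smaller than the dataset.
#' @param seed Integer seed.
#' @return List with `train` and `test` (both `absorption_dataset`) and the
#'   `test_idx` used.
#' @export
split_test <- function(dataset, n = 1000L, seed = 1L) {
  stopifnot(inherits(dataset, "absorption_dataset"))
  size <- nrow(dataset$absorbance)
  if (n >= size) abort("test size must be smaller than the dataset")
  idx <- sort(with_seed(seed, sample.int(size, n)))
  subset_ds <- function(rows) {
    structure(list(wavelengths = dataset$wavelengths,
                   absorbance = dataset$absorbance[rows, , drop = FALSE],
                   cod_label = dataset$cod_label[rows],
                   provenance = dataset$provenance[rows],
                   step = dataset$step),
              class = "absorption_dataset")
  }
  list(train = subset_ds(setdiff(seq_len(size), idx)),
       test = subset_ds(idx), test_idx = idx)
}
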