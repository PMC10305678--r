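#' Photophysics parameters for the synthetic spectra generator
#'
#' Per-compound absorption bands (Gaussian in wavelength, peak height in
#' specific absorbance units L mg^-1 cm^-1) and a single Gaussian fluorophore
#' (excitation/emission centers and widths in nm, yield in arbitrary
#' intensity units per mg/L). Defaults approximate the aromatic amino acids:
#' phenylalanine absorbs near 257 nm (with a strong short-UV band near
#' 206 nm) and fluoresces at 258/282 nm; tyrosine absorbs near 274 nm
#' (strong band near 222 nm) and fluoresces at 275/303 nm; tryptophan
#' absorbs near 280 nm (strong band near 219 nm) and fluoresces at
#' 280/350 nm.
#'
#' @param compounds Optional named list to override or extend the defaults.
#'   Each entry is a list with elements `bands` (data frame with columns
#'   `center_nm`, `width_nm`, `peak`) and `fluor` (named numeric with
#'   `ex_nm`, `ex_width_nm`, `em_nm`, `em_width_nm`, `yield`).
#' @return An object of class `photophysics` (named list).
#' @export
photophysics_spec <- function(compounds = NULL) {
  defaults <- list(
    phenylalanine = list(
      bands = data.frame(center_nm = c(206, 257), width_nm = c(7, 9),
                         peak = c(0.057, 0.0012)),
      fluor = c(ex_nm = 258, ex_width_nm = 10, em_nm = 282, em_width_nm = 15,
                yield = 4)
    ),
    tyrosine = list(
      bands = data.frame(center_nm = c(222, 274), width_nm = c(8, 10),
                         peak = c(0.044, 0.0078)),
      fluor = c(ex_nm = 275, ex_width_nm = 12, em_nm = 303, em_width_nm = 18,
                yield = 40)
    ),
    tryptophan = list(
      bands = data.frame(center_nm = c(219, 280), width_nm = c(9, 12),
                         peak = c(0.23, 0.027)),
      fluor = c(ex_nm = 280, ex_width_nm = 14, em_nm = 350, em_width_nm = 28,
                yield = 120)
    )
  )
  spec <- modifyList(defaults, compounds %||% list())
  for (nm in names(spec)) {
    cp <- spec[[nm]]
    if (any(cp$bands$width_nm <= 0) || any(cp$bands$peak < 0)) {
      abort(paste0("invalid absorption bands for ", nm))
    }
    fl <- cp$fluor
    if (fl[["ex_width_nm"]] <= 0 || fl[["em_width_nm"]] <= 0 || fl[["yield"]] < 0) {
      abort(paste0("invalid fluorophore for ", nm))
    }
    if (fl[["em_nm"]] < fl[["ex_nm"]]) {
      abort(paste0("fluorophore for ", nm, " violates the Stokes shift (em < ex)"))
    }
  }
  structure(spec, class = "photophysics")
}

#' Measurement-noise settings
#'
#' @param gaussian_sd Standard deviation of additive Gaussian noise (AU for
#'   absorbance, intensity units for EEMs).
#' @param seed Integer seed; generators are pure functions of (inputs, seed).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 0, seed = 1L) {
  if (gaussian_sd < 0) abort("gaussian_sd must be >= 0")
  structure(list(gaussian_sd = gaussian_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

gaussian_profile <- function(x, center, width) {
  exp(-((x - center)^2) / (2 * width^2))
}

# specific absorbance curve epsilon(lambda) in L mg^-1 cm^-1 for one compound
specific_absorbance <- function(wavelengths, compound_photo) {
  bands <- compound_photo$bands
  eps <- numeric(length(wavelengths))
  for (b in seq_len(nrow(bands))) {
    eps <- eps + bands$peak[b] *
      gaussian_profile(wavelengths, bands$center_nm[b], bands$width_nm[b])
  }
  eps
}

check_mixture <- function(mixture, photo) {
  if (is.data.frame(mixture)) mixture <- setNames(mixture[[2]], mixture[[1]])
  missing <- setdiff(names(mixture), names(photo))
  if (length(missing) > 0) {
    abort(paste0("no photophysics entry for: ", paste(missing, collapse = ", ")))
  }
  if (any(mixture < 0)) abort("concentrations must be >= 0")
  mixture
}

#' Simulate a UV-Vis absorption spectrum of a mixture
#'
#' Beer-Lambert additive absorbance over a 1 cm path:
#' `A(lambda) = sum_i c_i * eps_i(lambda)` plus optional Gaussian noise.
#' Noiseless output is exactly additive over components and the generator is
#' deterministic given the noise seed.
#'
#' @param mixture Named concentrations in mg/L (or a `(name, conc)` data
#'   frame); an empty vector gives a blank.
#' @param photo A [photophysics_spec()].
#' @param noise A [noise_spec()].
#' @param wavelengths Wavelength grid in nm (default [absorption_grid()]).
#' @return An object of class `absorption_spectrum`: list with
#'   `wavelengths`, `absorbance`, `cod_label` (NA until labeled) and
#'   `provenance = "synthetic"`.
#' @export
simulate_absorption <- function(mixture = numeric(), photo = photophysics_spec(),
                                noise = noise_spec(),
                                wavelengths = absorption_grid()) {
  mixture <- check_mixture(mixture, photo)
  absorbance <- numeric(length(wavelengths))
  for (nm in names(mixture)) {
    absorbance <- absorbance + mixture[[nm]] * specific_absorbance(wavelengths, photo[[nm]])
  }
  if (noise$gaussian_sd > 0) {
    absorbance <- absorbance + with_seed(noise$seed,
      rnorm(length(wavelengths), sd = noise$gaussian_sd))
  }
  new_absorption_spectrum(wavelengths, absorbance, cod_label = NA_real_,
                          provenance = "synthetic")
}

new_absorption_spectrum <- function(wavelengths, absorbance, cod_label, provenance) {
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    abort("wavelength grid must be strictly increasing")
  }
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 cod_label = cod_label, provenance = provenance),
            class = "absorption_spectrum")
}

new_eem <- function(ex, em, intensity) {
  if (is.unsorted(ex, strictly = TRUE) || is.unsorted(em, strictly = TRUE)) {
    abort("EEM wavelength grids must be strictly increasing")
  }
  if (!all(dim(intensity) == c(length(em), length(ex)))) {
    abort("intensity must be an emission x excitation matrix")
  }
  structure(list(ex_wavelengths = ex, em_wavelengths = em,
                 intensity = intensity), class = "eem")
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d emission x %d excitation channels (%g-%g / %g-%g nm)\n",
              length(x$em_wavelengths), length(x$ex_wavelengths),
              min(x$em_wavelengths), max(x$em_wavelengths),
              min(x$ex_wavelengths), max(x$ex_wavelengths)))
  invisible(x)
}

#' @export
print.absorption_spectrum <- function(x, ...) {
  cat(sprintf("<absorption_spectrum> %d points, %g-%g nm, COD label %s (%s)\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              format(x$cod_label), x$provenance))
  invisible(x)
}

# scatter ridge intensities on an (em x ex) grid; Raman line at a fixed
# 3400 cm^-1 Stokes shift from the excitation line (water OH stretch)
scatter_field <- function(ex, em, first = 500, second = 150, raman = 50,
                          width_nm = 10) {
  exg <- matrix(ex, nrow = length(em), ncol = length(ex), byrow = TRUE)
  emg <- matrix(em, nrow = length(em), ncol = length(ex))
  f <- first * gaussian_profile(emg - exg, 0, width_nm) +
    second * gaussian_profile(emg - 2 * exg, 0, width_nm)
  raman_em <- 1 / (1 / exg - 3400e-7) # nm; 3400 cm^-1 = 3400e-7 nm^-1
  f + raman * gaussian_profile(emg - raman_em, 0, width_nm)
}

#' Simulate an excitation-emission matrix of a mixture
#'
#' The noiseless, undistorted EEM is additive over components:
#' `F(ex, em) = sum_i c_i * yield_i * G(ex; ex_i) * G(em; em_i)` with
#' Gaussian excitation and emission profiles. With `ife = TRUE` the field is
#' attenuated by the primary+secondary inner-filter factor
#' `10^(-(A(ex) + A(em))/2)` computed from the mixture's own synthetic
#' absorbance (1 cm path). With `scatter = TRUE`, first-order Rayleigh
#' (em = ex), second-order Rayleigh (em = 2 ex) and water Raman ridges are
#' added. Noise is added last.
#'
#' @inheritParams simulate_absorption
#' @param ife Apply inner-filter distortion.
#' @param scatter Add scatter ridges.
#' @param ex,em Excitation/emission grids in nm.
#' @return An object of class `eem`.
#' @export
simulate_eem <- function(mixture = numeric(), photo = photophysics_spec(),
                         ife = FALSE, scatter = FALSE, noise = noise_spec(),
                         ex = excitation_grid(), em = emission_grid()) {
  mixture <- check_mixture(mixture, photo)
  intensity <- matrix(0, nrow = length(em), ncol = length(ex))
  for (nm in names(mixture)) {
    fl <- photo[[nm]]$fluor
    gex <- gaussian_profile(ex, fl[["ex_nm"]], fl[["ex_width_nm"]])
    gem <- gaussian_profile(em, fl[["em_nm"]], fl[["em_width_nm"]])
    intensity <- intensity + mixture[[nm]] * fl[["yield"]] * outer(gem, gex)
  }
  if (ife) {
    a_of <- function(lambda) {
      a <- numeric(length(lambda))
      for (nm in names(mixture)) {
        a <- a + mixture[[nm]] * specific_absorbance(lambda, photo[[nm]])
      }
      a
    }
    atten <- 10^(-(outer(a_of(em), a_of(ex), "+")) / 2)
    intensity <- intensity * atten
  }
  if (scatter) {
    intensity <- intensity + scatter_field(ex, em)
  }
  if (noise$gaussian_sd > 0) {
    intensity <- intensity + with_seed(noise$seed,
      matrix(rnorm(length(intensity), sd = noise$gaussian_sd),
             nrow = nrow(intensity)))
  }
  new_eem(ex, em, intensity)
}

#' Simulate a deionized-water blank EEM
#'
#' A zero-fluorophore EEM containing only scatter ridges and noise; used to
#' locate the scatter bands before removing them from sample EEMs.
#'
#' @inheritParams simulate_eem
#' @return An object of class `eem`.
#' @export
simulate_blank <- function(scatter = TRUE, noise = noise_spec(),
                           ex = excitation_grid(), em = emission_grid()) {
  simulate_eem(mixture = numeric(), scatter = scatter, noise = noise,
               ex = ex, em = em)
}

#' Generate the full synthetic design dataset
#'
#' One absorption spectrum and one EEM per design row, labeled with the COD
#' computed from the conversion coefficients and sorted by ascending label.
#'
#' @param design A [mixture_design()] tibble (concentration columns named
#'   after registered compounds plus `cod_label`), or NULL for the packaged
#'   design.
#' @param photo A [photophysics_spec()].
#' @param noise A [noise_spec()] for the absorption spectra; per-row seeds
#'   are derived from `noise$seed` so rows are independent but reproducible.
#' @param eem_noise A [noise_spec()] for the EEMs (defaults to `noise`).
#' @param ife,scatter Passed to [simulate_eem()].
#' @return A list with `manifest` (tibble: id, concentrations, cod_label,
#'   seed), `spectra` (list of `absorption_spectrum`) and `eems` (list of
#'   `eem`), all in ascending label order.
#' @export
generate_design_dataset <- function(design = NULL, photo = photophysics_spec(),
                                    noise = noise_spec(), eem_noise = noise,
                                    ife = FALSE, scatter = FALSE) {
  design <- design %||% mixture_design()
  if (nrow(design) == 0) abort("design must be non-empty")
  conc_cols <- intersect(names(design), names(photo))
  if (length(conc_cols) == 0) abort("design has no concentration column matching photophysics")
  if (!"cod_label" %in% names(design)) abort("design must carry cod_label")
  ord <- order(design$cod_label)
  if (anyDuplicated(design$cod_label)) {
    warn("duplicate COD labels in design; ties broken by row order")
  }
  design <- design[ord, ]
  spectra <- vector("list", nrow(design))
  eems <- vector("list", nrow(design))
  seeds <- noise$seed + seq_len(nrow(design))
  for (i in seq_len(nrow(design))) {
    mix <- setNames(as.numeric(design[i, conc_cols]), conc_cols)
    mix <- mix[mix > 0]
    ns <- noise_spec(noise$gaussian_sd, seeds[i])
    sp <- simulate_absorption(mix, photo, ns)
    sp$cod_label <- design$cod_label[i]
    spectra[[i]] <- sp
    eems[[i]] <- simulate_eem(mix, photo, ife = ife, scatter = scatter,
                              noise = noise_spec(eem_noise$gaussian_sd,
                                                 seeds[i] + 10000L))
  }
  manifest <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(nrow(design))),
    tibble::as_tibble(design[c(conc_cols, "cod_label")]),
    tibble::tibble(seed = seeds)
  )
  list(manifest = manifest, spectra = spectra, eems = eems)
}
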