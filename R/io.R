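# CSV dialects: absorption spectra are two-column (wavelength_nm,
# absorbance); EEMs are matrix CSVs whose first row is the excitation nm
# header and first column the emission nm; manifests are plain CSVs with a
# path-validity check. Writes are atomic (temp file + rename).

atomic_write <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read and write absorption-spectrum CSVs
#'
#' @param spectrum An `absorption_spectrum`.
#' @param path File path.
#' @param cod_label,provenance Metadata attached on read (the CSV itself
#'   carries only the numeric payload).
#' @return `read_absorption_csv()` returns an `absorption_spectrum`;
#'   `write_absorption_csv()` returns the path invisibly.
#' @export
write_absorption_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "absorption_spectrum"))
  df <- data.frame(wavelength_nm = spectrum$wavelengths,
                   absorbance = spectrum$absorbance)
  atomic_write(function(tmp) readr::write_csv(df, tmp), path)
}

#' @rdname write_absorption_csv
#' @export
read_absorption_csv <- function(path, cod_label = NA_real_,
                                provenance = "measured") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(df))) {
    abort(paste0(path, ": expected columns wavelength_nm, absorbance"))
  }
  if (is.unsorted(df$wavelength_nm, strictly = TRUE)) {
    bad <- which(diff(df$wavelength_nm) <= 0)[1] + 1L
    abort(sprintf("%s: wavelength grid not strictly increasing at data line %d",
                  path, bad))
  }
  new_absorption_spectrum(df$wavelength_nm, df$absorbance, cod_label, provenance)
}

#' Read and write EEM matrix CSVs
#'
#' First row: excitation wavelengths (nm); first column: emission
#' wavelengths (nm); body: intensity.
#'
#' @param eem An `eem`.
#' @param path File path.
#' @return `read_eem_csv()` returns an `eem`; `write_eem_csv()` returns the
#'   path invisibly.
#' @export
write_eem_csv <- function(eem, path) {
  stopifnot(inherits(eem, "eem"))
  m <- cbind(eem$em_wavelengths, eem$intensity)
  header <- c("em_nm", format(eem$ex_wavelengths, trim = TRUE, digits = 15))
  atomic_write(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = ","), con)
    utils::write.table(m, con, sep = ",", row.names = FALSE, col.names = FALSE)
  }, path)
}

#' @rdname write_eem_csv
#' @export
read_eem_csv <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, colClasses = "numeric", skip = 1)
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  ex <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(ex)) abort(paste0(path, ": malformed excitation header (line 1)"))
  em <- raw[[1]]
  if (is.unsorted(em, strictly = TRUE)) {
    bad <- which(diff(em) <= 0)[1] + 1L
    abort(sprintf("%s: emission grid not strictly increasing at data line %d",
                  path, bad + 1L))
  }
  if (is.unsorted(ex, strictly = TRUE)) {
    abort(paste0(path, ": excitation header not strictly increasing (line 1)"))
  }
  new_eem(ex, em, as.matrix(raw[-1]))
}

#' Read and write dataset manifests
#'
#' A manifest records ids, per-compound concentrations, COD labels, seeds
#' and (optionally) artifact paths. Reading validates that every
#' referenced file exists.
#'
#' @param manifest A tibble.
#' @param path File path.
#' @param check_paths Validate columns ending in `_path` on read.
#' @return `read_manifest()` returns a tibble.
#' @export
write_manifest <- function(manifest, path) {
  atomic_write(function(tmp) readr::write_csv(manifest, tmp), path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  if (check_paths) {
    path_cols <- grep("_path$", names(m), value = TRUE)
    for (pc in path_cols) {
      missing <- m[[pc]][!file.exists(m[[pc]])]
      if (length(missing) > 0) {
        abort(paste0("manifest references missing file(s): ",
                     paste(missing, collapse = ", ")))
      }
    }
  }
  m
}
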