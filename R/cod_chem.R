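#' Compound registry for COD conversion chemistry
#'
#' Reads a registry of organic compounds with their elemental composition
#' (carbon, hydrogen and oxygen atom counts), relative molecular mass and,
#' where available, the COD conversion coefficient measured by dichromate
#' digestion. The packaged registry covers the three aromatic amino acids
#' (tyrosine, phenylalanine, tryptophan) commonly used as fluorescent
#' surrogates for dissolved organic matter.
#'
#' @param path Path to a registry CSV with columns `name, formula, m, nH, l,
#'   Mr, alpha_measured`. Defaults to the packaged amino-acid registry.
#' @return A tibble with one row per compound and a `alpha_theoretical`
#'   column computed from the stoichiometric formula.
#' @seealso [theoretical_cod_coefficient()], [mixture_cod()]
#' @export
#' @examples
#' compound_table()
compound_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "compounds.csv", package = "codfusion")
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("name", "m", "nH", "l", "Mr")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("compound registry is missing columns: ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tbl$name)) abort("compound names must be unique")
  tbl$alpha_theoretical <- theoretical_cod_coefficient(tbl$m, tbl$nH, tbl$l, tbl$Mr)
  tibble::as_tibble(tbl)
}

#' Theoretical COD conversion coefficient from stoichiometry
#'
#' Assuming complete oxidation of CmHnOl to carbon dioxide and water,
#' the oxidant demand per unit mass of compound is
#' \deqn{\alpha_{COD} = (2m + n/2 - l) \cdot M_r(O) / M_r(C_mH_nO_l)}
#' with the relative atomic mass of oxygen fixed at 16.00. Nitrogen and
#' sulfur are ignored, so for heteroatom-containing compounds this value is
#' informational; measured dichromate coefficients should be preferred for
#' labeling (see [compound_table()]).
#'
#' @param m,nH,l Carbon, hydrogen and oxygen atom counts (vectorized).
#' @param Mr Relative molecular mass in g/mol.
#' @return Coefficient in mg O2 per mg compound.
#' @export
#' @examples
#' theoretical_cod_coefficient(9, 11, 3, 181.189) # tyrosine, about 1.810
theoretical_cod_coefficient <- function(m, nH, l, Mr) {
  if (any(Mr <= 0)) abort("Mr must be positive")
  if (any(m < 1) || any(nH < 0) || any(l < 0)) {
    abort("atom counts must satisfy m >= 1, nH >= 0, l >= 0")
  }
  demand <- 2 * m + nH / 2 - l
  if (any(demand < 0)) {
    abort("invalid stoichiometry: computed oxidant demand is negative")
  }
  demand * MR_OXYGEN / Mr
}

#' COD of a mixture from component concentrations
#'
#' COD is additive over components: `sum(concentration * coefficient)`.
#'
#' @param mixture Named numeric vector of concentrations in mg/L, or a
#'   two-column data frame `(name, conc_mg_l)`. Names must be unique.
#' @param coefficients Named numeric vector of COD conversion coefficients
#'   (mg O2 / mg); by default the measured coefficients of the packaged
#'   registry.
#' @return COD in mg/L.
#' @export
#' @examples
#' mixture_cod(c(tyrosine = 15, phenylalanine = 80, tryptophan = 6)) # 146.57
mixture_cod <- function(mixture, coefficients = NULL) {
  if (is.data.frame(mixture)) {
    mixture <- setNames(mixture[[2]], mixture[[1]])
  }
  if (length(mixture) == 0) return(0)
  if (is.null(names(mixture)) || any(names(mixture) == "")) {
    abort("mixture components must be named")
  }
  if (anyDuplicated(names(mixture))) abort("compound names must be unique within a mixture")
  if (any(mixture < 0)) abort("concentrations must be >= 0")
  if (is.null(coefficients)) {
    reg <- compound_table()
    coefficients <- setNames(reg$alpha_measured, reg$name)
  }
  missing <- setdiff(names(mixture), names(coefficients))
  if (length(missing) > 0) {
    abort(paste0("no COD coefficient for: ", paste(missing, collapse = ", ")))
  }
  sum(mixture * coefficients[names(mixture)])
}

#' Number of augmentation labels in a half-open COD interval
#'
#' Counts the labels in `(label_low, label_high]` on a grid with the given
#' spacing. The arithmetic is done in integer multiples of `step` to avoid
#' floating-point drift, so `fill_count(9.34, 18.78)` is exactly 944 and
#' `fill_count(0, 146.57)` is exactly 14657.
#'
#' @param label_low,label_high COD labels in mg/L, `label_high >= label_low >= 0`.
#' @param step Grid spacing in mg/L (default 0.01).
#' @return Integer count.
#' @export
fill_count <- function(label_low, label_high, step = 0.01) {
  if (step <= 0) abort("step must be positive")
  if (label_low < 0 || label_high < label_low) {
    abort("labels must satisfy label_high >= label_low >= 0")
  }
  as.integer(round(label_high / step) - round(label_low / step))
}

#' Ordered augmentation label grid over (0, cod_max]
#'
#' @param cod_max Largest COD label in mg/L (> 0).
#' @param step Grid spacing in mg/L.
#' @return Strictly increasing numeric vector of length
#'   `fill_count(0, cod_max, step)`.
#' @export
label_grid <- function(cod_max, step = 0.01) {
  if (cod_max <= 0) abort("cod_max must be positive")
  n <- fill_count(0, cod_max, step)
  seq_len(n) * step
}

#' Mixture design table
#'
#' Reads a mixture design (one row per mixture, one concentration column per
#' compound) and computes COD labels from the given conversion coefficients.
#' If the design carries a `cod_printed` column, rows whose recorded label
#' disagrees with the recomputed one beyond half a label-grid step are
#' flagged in a `label_discrepancy` column (the recomputed label is always
#' the one used downstream).
#'
#' @param path Design CSV; defaults to the packaged ten-mixture amino-acid
#'   design.
#' @param coefficients Named coefficients as in [mixture_cod()].
#' @param step Label grid spacing used for the discrepancy tolerance.
#' @return A tibble with concentration columns, `cod_label` (recomputed),
#'   and, when a recorded label is present, `cod_printed` and
#'   `label_discrepancy`.
#' @export
mixture_design <- function(path = NULL, coefficients = NULL, step = 0.01) {
  path <- path %||% system.file("extdata", "mixture_design.csv", package = "codfusion")
  design <- readr::read_csv(path, show_col_types = FALSE)
  if (is.null(coefficients)) {
    reg <- compound_table()
    coefficients <- setNames(reg$alpha_measured, reg$name)
  }
  conc_cols <- intersect(names(design), names(coefficients))
  if (length(conc_cols) == 0) {
    abort("design has no concentration column matching a registered compound")
  }
  conc <- as.matrix(design[conc_cols])
  if (any(conc < 0)) abort("concentrations must be >= 0")
  design$cod_label <- as.numeric(conc %*% coefficients[conc_cols])
  if ("cod_printed" %in% names(design)) {
    design$label_discrepancy <- abs(design$cod_printed - design$cod_label) > step / 2
    if (any(design$label_discrepancy)) {
      inform(paste0(
        sum(design$label_discrepancy),
        " design row(s) carry a recorded COD label inconsistent with the",
        " conversion coefficients; recomputed labels are used"
      ))
    }
  }
  tibble::as_tibble(design)
}
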