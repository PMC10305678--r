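# Shared fixtures and independent oracles, built in code at test time.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# small EEM on arbitrary grids
make_eem <- function(intensity,
                     ex = seq(255, 380, length.out = ncol(intensity)),
                     em = seq(200, 700, length.out = nrow(intensity))) {
  codfusion:::new_eem(ex, em, intensity)
}

# brute-force oxidant-demand oracle: count oxygen atoms needed to burn
# CmHnOl to CO2 + H2O by explicit element bookkeeping
stoichiometry_oracle <- function(m, nH, l, Mr) {
  o_in_products <- 0
  for (i in seq_len(m)) o_in_products <- o_in_products + 2 # one CO2 each
  o_in_products <- o_in_products + nH / 2 # half an H2O per H atom pair
  o_needed <- o_in_products - l
  o_needed * 16.00 / Mr
}

# direct sliding-window complex Gabor correlation with reflect padding
direct_gabor_response <- function(img, kern) {
  k <- kern$K
  h <- (k - 1) / 2
  rp <- codfusion:::reflect_pad(img, h)
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      blk <- rp[i:(i + k - 1), j:(j + k - 1)]
      out[i, j] <- sqrt(sum(blk * kern$real)^2 + sum(blk * kern$imag)^2)
    }
  }
  out
}

# a tiny synthetic design (three mixtures) for fast cross-module tests
tiny_design <- function() {
  tibble::tibble(
    tyrosine = c(2, 5, 8), tryptophan = c(1, 2, 3),
    cod_label = c(2 * 1.31 + 1 * 1.42, 5 * 1.31 + 2 * 1.42, 8 * 1.31 + 3 * 1.42))
}

# a valid small fusion-net input length for the 7-pool plan
small_net <- function(seed = 1) {
  build_fusion_net(input_len = 300L, channels = c(2L, 3L, 4L, 5L),
                   fluor_dim = c(2L, 4L), hidden = 6L, seed = seed)
}
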