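# Independent oracles used against the package's closed forms.

# Allele-copy counting over an explicit integer population of cells:
# n_cells mixed as round(purity * n_cells) tumor cells with (c_b6, c_s129)
# copies and the rest normal diploid het cells.
counting_baf <- function(c_b6, c_s129, purity, n_cells = 10000) {
  n_tumor <- round(purity * n_cells)
  n_normal <- n_cells - n_tumor
  s129 <- n_tumor * c_s129 + n_normal * 1
  total <- n_tumor * (c_b6 + c_s129) + n_normal * 2
  s129 / total
}

counting_vaf <- function(multiplicity, cell_fraction, tumor_copy = 2,
                         background_copy = 2, n_cells = 10000) {
  n_mut <- round(cell_fraction * n_cells)
  n_other <- n_cells - n_mut
  mut <- n_mut * multiplicity
  total <- n_mut * tumor_copy + n_other * background_copy
  mut / total
}

# Brute-force two-sided Fisher p for the 2x2 table [[a, b], [c, d]]:
# enumerate the hypergeometric support with binomial coefficients and sum
# every outcome no more probable than the observed one.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  probs <- choose(m, x) * choose(n, k - x) / choose(m + n, k)
  obs <- probs[x == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
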