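#' Amino-acid alphabets and the embedded BLOSUM62 matrix
#'
#' `blosum62()` returns the standard 20x20 BLOSUM62 substitution matrix
#' extended with an `X` row/column scoring 0 against everything (neutral
#' masking of unknown residues). This is the default scoring table for
#' [sw_score()] and [reciprocal_best_hits()].
#'
#' @return Integer matrix with dimnames over `ACDEFGHIKLMNPQRSTVWYX`.
#' @export
blosum62 <- function() {
  .blosum62
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA21 <- c(AA20, "X")

.blosum62 <- local({
  v <- c(
    4, 0, -2, -1, -2, 0, -2, -1, -1, -1, -1, -2, -1, -1, -1, 1, 0, 0, -3, -2,
    0, 9, -3, -4, -2, -3, -3, -1, -3, -1, -1, -3, -3, -3, -3, -1, -1, -1, -2, -2,
    -2, -3, 6, 2, -3, -1, -1, -3, -1, -4, -3, 1, -1, 0, -2, 0, -1, -3, -4, -3,
    -1, -4, 2, 5, -3, -2, 0, -3, 1, -3, -2, 0, -1, 2, 0, 0, -1, -2, -3, -2,
    -2, -2, -3, -3, 6, -3, -1, 0, -3, 0, 0, -3, -4, -3, -3, -2, -2, -1, 1, 3,
    0, -3, -1, -2, -3, 6, -2, -4, -2, -4, -3, 0, -2, -2, -2, 0, -2, -3, -2, -3,
    -2, -3, -1, 0, -1, -2, 8, -3, -1, -3, -2, 1, -2, 0, 0, -1, -2, -3, -2, 2,
    -1, -1, -3, -3, 0, -4, -3, 4, -3, 2, 1, -3, -3, -3, -3, -2, -1, 3, -3, -1,
    -1, -3, -1, 1, -3, -2, -1, -3, 5, -2, -1, 0, -1, 1, 2, 0, -1, -2, -3, -2,
    -1, -1, -4, -3, 0, -4, -3, 2, -2, 4, 2, -3, -3, -2, -2, -2, -1, 1, -2, -1,
    -1, -1, -3, -2, 0, -3, -2, 1, -1, 2, 5, -2, -2, 0, -1, -1, -1, 1, -1, -1,
    -2, -3, 1, 0, -3, 0, 1, -3, 0, -3, -2, 6, -2, 0, 0, 1, 0, -3, -4, -2,
    -1, -3, -1, -1, -4, -2, -2, -3, -1, -3, -2, -2, 7, -1, -2, -1, -1, -2, -4, -3,
    -1, -3, 0, 2, -3, -2, 0, -3, 1, -2, 0, 0, -1, 5, 1, 0, -1, -2, -2, -1,
    -1, -3, -2, 0, -3, -2, 0, -3, 2, -2, -1, 0, -2, 1, 5, -1, -1, -3, -3, -2,
    1, -1, 0, 0, -2, 0, -1, -2, 0, -2, -1, 1, -1, 0, -1, 4, 1, -2, -3, -2,
    0, -1, -1, -1, -2, -2, -2, -1, -1, -1, -1, 0, -1, -1, -1, 1, 5, 0, -2, -2,
    0, -1, -3, -2, -1, -3, -3, 3, -2, 1, 1, -3, -2, -2, -3, -2, 0, 4, -3, -1,
    -3, -2, -4, -3, 1, -2, -2, -3, -3, -2, -1, -4, -4, -2, -3, -3, -2, -3, 11, 2,
    -2, -2, -3, -2, 3, -3, 2, -1, -2, -1, -1, -2, -3, -1, -2, -2, -2, -1, 2, 7
  )
  m <- matrix(0L, 21L, 21L, dimnames = list(AA21, AA21))
  m[1:20, 1:20] <- as.integer(v)  # X row/col stay 0: neutral masking
  m
})

#' Mean codon GC fraction per amino acid
#'
#' Computed from the standard genetic code with equal weight on each codon
#' (no codon-usage information). High-GC residues (G, A, R, P) and low-GC
#' residues (Y, F, I, N, K) anchor opposite ends of the scale, which is the
#' axis that composition PCA of GC-biased proteomes recovers.
#'
#' @return Named numeric vector over the 20 amino acids, values in `[0, 1]`.
#' @export
amino_acid_gc_table <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  gc_per_codon <- vapply(strsplit(names(code), ""), function(b) {
    sum(b %in% c("G", "C")) / 3
  }, numeric(1))
  out <- vapply(AA20, function(a) mean(gc_per_codon[code == a]), numeric(1))
  out
}
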