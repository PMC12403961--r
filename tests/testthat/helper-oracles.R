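# Independent oracles and small fixture builders used across the suite.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, letters = AA) {
  paste(sample(letters, len, replace = TRUE), collapse = "")
}

# Brute-force affine-gap Smith-Waterman score: full three-matrix dynamic
# programme written independently of the package's scorer. A gap of
# length L costs open + L * ext.
sw_oracle <- function(a, b, submat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + submat[av[i - 1], bv[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Step-up false-discovery-rate adjustment straight from the definition:
# adjusted p(i) = min over j >= i (in sorted order) of m * p(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * sorted[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Per-base-pair interval coverage of half-open [start, end) intervals
# within a window [wstart, wend).
coverage_oracle <- function(starts, ends, wstart, wend) {
  if (wend <= wstart) return(0)
  covered <- logical(wend - wstart)
  for (k in seq_along(starts)) {
    lo <- max(starts[k], wstart); hi <- min(ends[k], wend)
    if (hi > lo) covered[(lo - wstart + 1):(hi - wstart)] <- TRUE
  }
  sum(covered)
}

# Contamination rule applied literally to one query's hits.
contamination_oracle <- function(taxa, evalues, threshold = 1e-20) {
  sig <- evalues < threshold
  sum(sig & taxa == "Metazoa") == 0 && sum(sig & taxa == "Bacteria") >= 1
}

# Regex-based overlapping Gly-X-Y frame counter (independent of scan_gxy's
# positional walk): count positions i with G at i-3, i, i+3, i+6.
gxy_oracle <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  count <- 0; px <- 0; py <- 0
  for (i in seq_len(n)) {
    if (i - 3 >= 1 && i + 6 <= n &&
        all(res[c(i - 3, i, i + 3, i + 6)] == "G")) {
      count <- count + 1
      if (res[i + 1] == "P") px <- px + 1
      if (res[i + 2] == "P") py <- py + 1
    }
  }
  list(count = count,
       frac_x = if (count) px / count else 0,
       frac_y = if (count) py / count else 0)
}

# Small gene-position table builder (0-based half-open).
make_positions <- function(ids, chrom, start = NULL, width = 500L) {
  if (is.null(start)) start <- seq(0L, by = 1000L, length.out = length(ids))
  data.frame(gene_id = ids, chrom = chrom, start = start,
             end = start + width, strand = "+", stringsAsFactors = FALSE)
}
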