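#' Scan a protein for Gly-X-Y collagen repeats
#'
#' Counts central G-X-Y triplets embedded in a glycine frame: a triplet
#' starting at position i is counted iff the residues at i-3, i, i+3 and
#' i+6 are all glycine, i.e. the counted G-X-Y sits inside a run of four
#' G's at spacing 3 (Gxx.GXY.GxxG). Overlapping matches all count. The
#' proline fractions at the X and Y positions are computed over the counted
#' triplets only (the "proportion of repeats" convention). The flank
#' requirement (number of frame G's before/after the counted one) is
#' exposed as parameters.
#'
#' @param protein Protein sequence string (may be empty).
#' @param gene_id Optional id carried into the profile.
#' @param flank_before,flank_after Required G's at spacing 3 before / after
#'   the counted triplet's G (defaults 1 and 2, the Gxx.GXY.GxxG frame).
#' @return Object of class `repeat_profile`: list with `gene_id`,
#'   `repeat_count`, `frac_pro_X`, `frac_pro_Y`, `sequence_length`.
#' @export
scan_gxy <- function(protein, gene_id = NA_character_,
                     flank_before = 1L, flank_after = 2L) {
  stopifnot(is.character(protein), length(protein) == 1,
            flank_before >= 0, flank_after >= 0)
  res <- strsplit(toupper(protein), "")[[1]]
  n <- length(res)
  lo <- 1L + 3L * flank_before
  hi <- n - max(3L * flank_after, 2L)
  count <- 0L; pro_x <- 0L; pro_y <- 0L
  if (hi >= lo) {
    is_g <- res == "G"
    cand <- which(is_g[lo:hi]) + lo - 1L
    for (i in cand) {
      frame <- i + 3L * c(-(seq_len(flank_before)), seq_len(flank_after))
      if (all(is_g[frame])) {
        count <- count + 1L
        if (res[i + 1L] == "P") pro_x <- pro_x + 1L
        if (res[i + 2L] == "P") pro_y <- pro_y + 1L
      }
    }
  }
  structure(list(gene_id = gene_id,
                 repeat_count = count,
                 frac_pro_X = if (count > 0) pro_x / count else 0,
                 frac_pro_Y = if (count > 0) pro_y / count else 0,
                 sequence_length = n),
            class = "repeat_profile")
}

#' @exportS3Method base::print
print.repeat_profile <- function(x, ...) {
  cat(sprintf("<repeat_profile> %s: %d repeat(s), G-P-Y %.3f, G-X-P %.3f (length %d)\n",
              x$gene_id, x$repeat_count, x$frac_pro_X, x$frac_pro_Y,
              x$sequence_length))
  invisible(x)
}

#' Gly-X-Y repeat table for a whole proteome
#'
#' Runs [scan_gxy()] over every protein and keeps profiles with at least
#' `min_repeats` counted triplets, sorted by repeat count (descending,
#' ties by gene id).
#'
#' @param proteome A protein [sequence_set()].
#' @param min_repeats Minimum repeat count to report (default 0).
#' @param ... Passed to [scan_gxy()].
#' @return data.frame `gene_id, repeat_count, frac_pro_X, frac_pro_Y,
#'   sequence_length`.
#' @export
proteome_collagen_table <- function(proteome, min_repeats = 0L, ...) {
  stopifnot(inherits(proteome, "sequence_set"))
  profs <- lapply(names(proteome$seqs), function(id)
    scan_gxy(proteome$seqs[[id]], gene_id = id, ...))
  out <- data.frame(
    gene_id = vapply(profs, `[[`, character(1), "gene_id"),
    repeat_count = vapply(profs, `[[`, integer(1), "repeat_count"),
    frac_pro_X = vapply(profs, `[[`, numeric(1), "frac_pro_X"),
    frac_pro_Y = vapply(profs, `[[`, numeric(1), "frac_pro_Y"),
    sequence_length = vapply(profs, `[[`, integer(1), "sequence_length"),
    stringsAsFactors = FALSE)
  out <- out[out$repeat_count >= min_repeats, , drop = FALSE]
  out <- out[order(-out$repeat_count, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
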