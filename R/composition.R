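#' Amino-acid frequency vector of one protein
#'
#' Frequencies over the 20 standard residues; `X` residues are excluded
#' from the denominator.
#'
#' @param protein Non-empty protein sequence string.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_frequency_vector <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1, nzchar(protein))
  res <- strsplit(toupper(protein), "")[[1]]
  res <- res[res != "X"]
  if (length(res) == 0) stop("sequence contains only X residues")
  bad <- setdiff(unique(res), AA20)
  if (length(bad))
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  counts <- table(factor(res, levels = AA20))
  setNames(as.numeric(counts) / length(res), AA20)
}

# mean of per-protein frequency vectors for a character vector of sequences
mean_aa_frequencies <- function(seqs, pooled = FALSE) {
  if (pooled) return(aa_frequency_vector(paste(seqs, collapse = "")))
  mats <- vapply(seqs, aa_frequency_vector, numeric(20))
  rowMeans(mats)
}

#' Species-pair-averaged amino-acid composition matrix
#'
#' Implements the averaging-of-averages scheme: for each unordered species
#' pair, the per-species average amino-acid usage is the unweighted mean of
#' the per-protein frequency vectors of that species' members of the
#' ortholog pairs; each species' final row is then the unweighted mean of
#' its per-pair averages over all pairs it participates in. Length-pooled
#' counting is available as an option.
#'
#' @param proteomes Named list of protein [sequence_set()]s (names are the
#'   species labels).
#' @param pair_list List of `ortholog_pairs` covering every unordered
#'   species pair.
#' @param pooled If `TRUE`, pool residues across proteins instead of
#'   averaging per-protein vectors.
#' @return Matrix (species x 20 amino acids), rows summing to 1.
#' @export
species_composition_matrix <- function(proteomes, pair_list, pooled = FALSE) {
  labels <- names(proteomes)
  stopifnot(!is.null(labels), !anyDuplicated(labels))
  key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  pair_map <- list()
  for (op in pair_list) pair_map[[key(op$species_a, op$species_b)]] <- op
  n <- length(labels)
  per_pair_avg <- vector("list", n)
  names(per_pair_avg) <- labels
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- labels[i]; b <- labels[j]
    op <- pair_map[[key(a, b)]]
    if (is.null(op) || nrow(op$pairs) == 0)
      stop("no ortholog pairs for species pair ", a, " / ", b)
    genes_a <- if (op$species_a == a) op$pairs$gene_a else op$pairs$gene_b
    genes_b <- if (op$species_a == a) op$pairs$gene_b else op$pairs$gene_a
    per_pair_avg[[a]] <- c(per_pair_avg[[a]],
      list(mean_aa_frequencies(proteomes[[a]]$seqs[genes_a], pooled)))
    per_pair_avg[[b]] <- c(per_pair_avg[[b]],
      list(mean_aa_frequencies(proteomes[[b]]$seqs[genes_b], pooled)))
  }
  rows <- t(vapply(labels, function(s) {
    rowMeans(do.call(cbind, per_pair_avg[[s]]))
  }, numeric(20)))
  colnames(rows) <- AA20
  rows
}

#' Principal component analysis with a deterministic sign convention
#'
#' Centered (optionally scaled) PCA via the covariance eigendecomposition
#' that `prcomp` performs. Components are ordered by decreasing explained
#' variance and each loading vector is flipped, together with its scores,
#' so that its largest-magnitude entry is positive. A constant input matrix
#' yields zero scores and zero explained-variance fractions.
#'
#' @param x Numeric matrix, items in rows (>= 2 rows).
#' @param center,scale Passed to centering/scaling.
#' @return Object of class `pca_result`: list with `scores`, `loadings`,
#'   `explained` (variance fractions), `sdev`, `center`.
#' @export
pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  total_var <- sum(apply(x, 2, var))
  if (total_var <= .Machine$double.eps * max(1, sum(abs(x)))) {
    k <- min(dim(x))
    scores <- matrix(0, nrow(x), k, dimnames = list(rownames(x), paste0("PC", 1:k)))
    loadings <- matrix(0, ncol(x), k, dimnames = list(colnames(x), paste0("PC", 1:k)))
    return(structure(list(scores = scores, loadings = loadings,
                          explained = rep(0, k), sdev = rep(0, k),
                          center = colMeans(x)),
                     class = "pca_result"))
  }
  pr <- prcomp(x, center = center, scale. = scale)
  flip <- apply(pr$rotation, 2, function(v) {
    sign(v[which.max(abs(v))])
  })
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  expl <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = scores, loadings = loadings, explained = expl,
                 sdev = pr$sdev,
                 center = if (isTRUE(center)) pr$center else rep(0, ncol(x))),
            class = "pca_result")
}

#' @exportS3Method base::print
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$explained))
  cat(sprintf("<pca_result> %d item(s), %d variable(s); %s\n",
              nrow(x$scores), nrow(x$loadings),
              paste(sprintf("PC%d = %.2f%%", 1:k, 100 * x$explained[1:k]),
                    collapse = ", ")))
  invisible(x)
}

#' Tube-composition Euclidean distance screen
#'
#' Ranks every protein of a proteome by the Euclidean distance between its
#' amino-acid frequencies and a target composition over a subset of
#' residues. The default target is the reported tube composition of the
#' Pompeii worm: serine 25%, glycine 20.6%, alanine 11.8%.
#'
#' @param proteome A protein [sequence_set()].
#' @param target Named numeric vector of target fractions over a subset of
#'   amino acids (one-letter codes).
#' @return data.frame `gene_id, distance`, ascending distance, ties broken
#'   by gene id.
#' @export
target_distance_screen <- function(proteome,
                                   target = c(S = 0.25, G = 0.206, A = 0.118)) {
  stopifnot(inherits(proteome, "sequence_set"), length(proteome) > 0,
            !is.null(names(target)), all(names(target) %in% AA20),
            all(target >= 0 & target <= 1))
  d <- vapply(proteome$seqs, function(s) {
    f <- aa_frequency_vector(s)[names(target)]
    sqrt(sum((f - target)^2))
  }, numeric(1))
  out <- data.frame(gene_id = names(proteome$seqs), distance = unname(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-window GC content and gene coverage along a genome
#'
#' Splits every chromosome into consecutive non-overlapping windows (the
#' last window may be short) and reports the GC fraction (G+C over
#' A+C+G+T, N excluded) and the percentage of window bases covered by the
#' union of gene intervals.
#'
#' @param genome A DNA [sequence_set()] (one sequence per chromosome).
#' @param gene_positions Gene-position data.frame (0-based half-open), or
#'   `NULL` for GC only.
#' @param window_bp Window size in bp (default 100 kb).
#' @return data.frame `chrom, start, end, gc, gene_coverage_pct` (window
#'   coordinates 0-based half-open).
#' @export
genome_windows <- function(genome, gene_positions = NULL, window_bp = 100000L) {
  stopifnot(inherits(genome, "sequence_set"), genome$alphabet == "dna",
            window_bp > 0)
  if (!is.null(gene_positions)) validate_gene_positions(gene_positions)
  res <- lapply(names(genome$seqs), function(chrom) {
    s <- Biostrings::DNAString(genome$seqs[[chrom]])
    len <- length(s)
    starts <- seq.int(0L, len - 1L, by = window_bp)
    ends <- pmin(starts + window_bp, len)
    v <- Biostrings::Views(s, start = starts + 1L, end = ends)
    freq <- Biostrings::alphabetFrequency(v, baseOnly = TRUE)
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(acgt > 0, rowSums(freq[, c("C", "G"), drop = FALSE]) / acgt, NA_real_)
    cov_pct <- rep(0, length(starts))
    if (!is.null(gene_positions)) {
      g <- gene_positions[gene_positions$chrom == chrom, , drop = FALSE]
      if (nrow(g)) {
        ir <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L, end = g$end))
        win <- IRanges::IRanges(start = starts + 1L, end = ends)
        ov <- IRanges::findOverlaps(win, ir)
        if (length(ov)) {
          inter <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                       ir[S4Vectors::subjectHits(ov)])
          covered <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
          cov_pct[as.integer(names(covered))] <- 100 * covered / (ends - starts)[as.integer(names(covered))]
        }
      }
    }
    data.frame(chrom = chrom, start = starts, end = ends, gc = gc,
               gene_coverage_pct = cov_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
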