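#' Oxford grid of shared-ortholog counts per chromosome pair
#'
#' Cross-tabulates reciprocal-best-hit pairs by the chromosomes their
#' members occupy in the two species. The matrix total equals the number
#' of positioned pairs.
#'
#' @param ortholog_pairs An `ortholog_pairs` object or a data.frame with
#'   `gene_a`, `gene_b`.
#' @param positions_a,positions_b Gene-position data.frames covering every
#'   paired gene.
#' @return Integer matrix, rows = species-A chromosomes, columns =
#'   species-B chromosomes.
#' @export
oxford_grid <- function(ortholog_pairs, positions_a, positions_b) {
  pairs <- if (inherits(ortholog_pairs, "ortholog_pairs"))
    ortholog_pairs$pairs else ortholog_pairs
  validate_gene_positions(positions_a)
  validate_gene_positions(positions_b)
  chr_a <- setNames(positions_a$chrom, positions_a$gene_id)
  chr_b <- setNames(positions_b$chrom, positions_b$gene_id)
  missing <- c(setdiff(pairs$gene_a, names(chr_a)),
               setdiff(pairs$gene_b, names(chr_b)))
  if (length(missing))
    stop("unpositioned gene(s): ", paste(missing, collapse = ", "))
  tab <- table(chr_a[pairs$gene_a], chr_b[pairs$gene_b])
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  m
}

#' Ordinal gene ranks for synteny dot plots
#'
#' Ranks genes by midpoint position within each chromosome and returns the
#' dot coordinates of every ortholog pair.
#'
#' @inheritParams oxford_grid
#' @return data.frame `gene_a, gene_b, chrom_a, rank_a, chrom_b, rank_b`.
#' @export
synteny_dots <- function(ortholog_pairs, positions_a, positions_b) {
  pairs <- if (inherits(ortholog_pairs, "ortholog_pairs"))
    ortholog_pairs$pairs else ortholog_pairs
  rank_of <- function(pos) {
    mid <- (pos$start + pos$end) / 2
    r <- numeric(nrow(pos))
    for (ix in split(seq_len(nrow(pos)), pos$chrom))
      r[ix] <- rank(mid[ix], ties.method = "first") - 1
    setNames(r, pos$gene_id)
  }
  ra <- rank_of(positions_a); rb <- rank_of(positions_b)
  chr_a <- setNames(positions_a$chrom, positions_a$gene_id)
  chr_b <- setNames(positions_b$chrom, positions_b$gene_id)
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             chrom_a = unname(chr_a[pairs$gene_a]),
             rank_a = unname(ra[pairs$gene_a]),
             chrom_b = unname(chr_b[pairs$gene_b]),
             rank_b = unname(rb[pairs$gene_b]),
             stringsAsFactors = FALSE)
}

#' Significant chromosome associations in an Oxford grid
#'
#' For each cell, the one-sided hypergeometric probability of observing at
#' least the cell's shared-ortholog count given the row and column margins,
#' BH-adjusted over all cells.
#'
#' @param grid Count matrix from [oxford_grid()].
#' @param alpha BH-FDR level (default 0.05).
#' @return data.frame `chrom_a, chrom_b, count, p_raw, p_adj, significant`.
#' @export
significant_associations <- function(grid, alpha = 0.05) {
  N <- sum(grid)
  stopifnot(N > 0)
  rs <- rowSums(grid); cs <- colSums(grid)
  cells <- expand.grid(chrom_a = rownames(grid), chrom_b = colnames(grid),
                       stringsAsFactors = FALSE)
  k <- as.vector(grid)
  m <- rs[cells$chrom_a]; n <- cs[cells$chrom_b]
  p <- phyper(k - 1, m, N - m, n, lower.tail = FALSE)
  adj <- bh_adjust(p, alpha)
  out <- data.frame(cells, count = k, p_raw = unname(p),
                    p_adj = unname(adj$p_adj),
                    significant = unname(adj$significant),
                    stringsAsFactors = FALSE)
  out[order(out$p_adj, out$p_raw, out$chrom_a, out$chrom_b), , drop = FALSE]
}

#' Paint chromosomes by ancestral linkage group and call fusions
#'
#' Transfers ALG labels from a labelled reference through an ortholog map
#' onto the chromosomes of the query species, reports per-chromosome ALG
#' composition fractions, and calls a fusion on every chromosome carrying
#' at least two ALGs with at least `min_genes` genes each.
#'
#' @param ortholog_pairs Pairs between the query (`gene_a`) and the
#'   ALG-labelled reference (`gene_b`); an `ortholog_pairs` object or
#'   data.frame.
#' @param positions Query gene positions.
#' @param alg_map Named character vector reference gene id -> ALG label,
#'   or 2-column data.frame / TSV path.
#' @param min_genes Minimum genes per ALG for a fusion call (default 10).
#' @return List with `composition` (data.frame `chrom, alg, n_genes,
#'   fraction`) and `fusions` (data.frame `chrom, algs`).
#' @export
alg_paint <- function(ortholog_pairs, positions, alg_map, min_genes = 10L) {
  pairs <- if (inherits(ortholog_pairs, "ortholog_pairs"))
    ortholog_pairs$pairs else ortholog_pairs
  if (is.character(alg_map) && length(alg_map) == 1 && file.exists(alg_map)) {
    tab <- read_annotation_tsv(alg_map, c("gene_id", "alg"))
    alg_map <- setNames(tab$alg, tab$gene_id)
  }
  if (is.data.frame(alg_map))
    alg_map <- setNames(as.character(alg_map[[2]]), as.character(alg_map[[1]]))
  stopifnot(all(nzchar(alg_map)))
  validate_gene_positions(positions)
  chr <- setNames(positions$chrom, positions$gene_id)
  alg <- unname(alg_map[pairs$gene_b])
  keep <- !is.na(alg) & pairs$gene_a %in% names(chr)
  if (!any(keep)) stop("no overlap between ortholog pairs and the ALG map")
  tab <- table(chrom = unname(chr[pairs$gene_a[keep]]), alg = alg[keep])
  comp <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(comp) <- c("chrom", "alg", "n_genes")
  comp <- comp[comp$n_genes > 0, , drop = FALSE]
  totals <- tapply(comp$n_genes, comp$chrom, sum)
  comp$fraction <- comp$n_genes / as.numeric(totals[comp$chrom])
  comp <- comp[order(comp$chrom, -comp$n_genes), , drop = FALSE]
  rownames(comp) <- NULL
  fus <- lapply(split(comp, comp$chrom), function(cc) {
    big <- cc$alg[cc$n_genes >= min_genes]
    if (length(big) >= 2)
      data.frame(chrom = cc$chrom[1],
                 algs = paste(sort(big), collapse = "+"),
                 stringsAsFactors = FALSE)
    else NULL
  })
  fus <- do.call(rbind, fus[!vapply(fus, is.null, logical(1))])
  if (is.null(fus))
    fus <- data.frame(chrom = character(), algs = character(),
                      stringsAsFactors = FALSE)
  rownames(fus) <- NULL
  list(composition = comp, fusions = fus)
}

#' Candidate artefactual chromosome splits
#'
#' Flags ALGs whose genes dominate two or more chromosomes (each ALG
#' contributing at least `min_genes` there and being the chromosome's
#' majority label): the signature of one ancestral chromosome split across
#' assembly pieces.
#'
#' @param paint Output of [alg_paint()].
#' @param min_genes Minimum genes for a chromosome to count (default 10).
#' @return data.frame `alg, chroms, n_chromosomes`.
#' @export
split_candidates <- function(paint, min_genes = 10L) {
  comp <- paint$composition
  major <- do.call(rbind, lapply(split(comp, comp$chrom), function(cc) {
    cc[which.max(cc$n_genes), , drop = FALSE]
  }))
  major <- major[major$n_genes >= min_genes, , drop = FALSE]
  out <- lapply(split(major, major$alg), function(mm) {
    if (nrow(mm) >= 2)
      data.frame(alg = mm$alg[1],
                 chroms = paste(sort(mm$chrom), collapse = "+"),
                 n_chromosomes = nrow(mm), stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(alg = character(), chroms = character(),
                      n_chromosomes = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
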