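#' Variant filter configuration
#'
#' Defaults follow standard resequencing practice for moderate-coverage
#' data: site QUAL at least 30, every genotype depth in `[5, 50]`, no
#' missing genotypes, and SNPs within 5 bp of an indel excluded.
#'
#' @param min_qual Minimum phred site quality.
#' @param min_depth,max_depth Per-genotype depth bounds.
#' @param indel_flank_bp SNPs within this distance of an indel are dropped.
#' @param require_complete Drop sites with any missing genotype.
#' @return Object of class `variant_filter_config`.
#' @export
variant_filter_config <- function(min_qual = 30, min_depth = 5,
                                  max_depth = 50, indel_flank_bp = 5,
                                  require_complete = TRUE) {
  stopifnot(min_depth <= max_depth, indel_flank_bp >= 0)
  structure(list(min_qual = min_qual, min_depth = min_depth,
                 max_depth = max_depth, indel_flank_bp = indel_flank_bp,
                 require_complete = require_complete),
            class = "variant_filter_config")
}

#' Filter raw VCF records down to an analysis-ready genotype matrix
#'
#' Retains biallelic SNPs passing all of: site QUAL at least `min_qual`,
#' every genotype depth within `[min_depth, max_depth]` (sites without
#' depth information pass this filter), no missing genotypes (when
#' `require_complete`), and distance greater than `indel_flank_bp` from
#' the reference span of every indel record on the same chromosome.
#' A per-filter drop-count log is attached as the `"filter_log"`
#' attribute; filters are applied independently so the log counts each
#' site once per violated rule.
#'
#' @param records A `vcf_records` object from [read_vcf_biallelic()].
#' @param config A [variant_filter_config()].
#' @return A [genotype_matrix()] with attribute `filter_log`.
#' @export
apply_variant_filters <- function(records, config = variant_filter_config()) {
  stopifnot(inherits(records, "vcf_records"),
            inherits(config, "variant_filter_config"))
  sites <- records$sites
  is_snp <- !sites$is_indel
  qual_ok <- !is.na(sites$qual) & sites$qual >= config$min_qual
  depth_ok <- rep(TRUE, nrow(sites))
  if (!all(is.na(records$depth))) {
    d <- records$depth
    depth_ok <- apply(d >= config$min_depth & d <= config$max_depth, 2,
                      function(x) all(x %in% TRUE))
  }
  complete_ok <- if (config$require_complete)
    colSums(is.na(records$geno)) == 0 else rep(TRUE, nrow(sites))
  flank_ok <- rep(TRUE, nrow(sites))
  indels <- sites[sites$is_indel, , drop = FALSE]
  if (nrow(indels) > 0 && config$indel_flank_bp >= 0) {
    for (chrom in unique(indels$chrom)) {
      ind <- indels[indels$chrom == chrom, , drop = FALSE]
      # indel reference span [pos, pos + nchar(ref) - 1], widened by the flank
      iv <- IRanges::reduce(IRanges::IRanges(
        start = ind$pos - config$indel_flank_bp,
        end = ind$pos + nchar(ind$ref) - 1L + config$indel_flank_bp))
      on_chrom <- which(sites$chrom == chrom & is_snp)
      if (length(on_chrom)) {
        hit <- IRanges::overlapsAny(
          IRanges::IRanges(start = sites$pos[on_chrom], width = 1L), iv)
        flank_ok[on_chrom[hit]] <- FALSE
      }
    }
  }
  keep <- is_snp & qual_ok & depth_ok & complete_ok & flank_ok
  log <- c(not_biallelic_snp = sum(!is_snp),
           low_qual = sum(is_snp & !qual_ok),
           depth_out_of_range = sum(is_snp & !depth_ok),
           missing_genotype = sum(is_snp & !complete_ok),
           near_indel = sum(is_snp & !flank_ok),
           multiallelic_skipped_on_read = unname(records$skip_log["multiallelic_snp"]),
           retained = sum(keep))
  gm <- genotype_matrix(records$geno[, keep, drop = FALSE],
                        sites[keep, c("chrom", "pos", "ref", "alt")],
                        sample_ids = records$sample_ids)
  ord <- order(gm$sites$chrom, gm$sites$pos)
  gm$sites <- gm$sites[ord, , drop = FALSE]
  rownames(gm$sites) <- NULL
  gm$geno <- gm$geno[, ord, drop = FALSE]
  attr(gm, "filter_log") <- log
  gm
}

#' Global PCA of genotype dosages over samples
#'
#' Sites are mean-centred on the dosage scale and samples projected onto
#' the principal components, with the deterministic sign convention of
#' [pca()].
#'
#' @param gm A [genotype_matrix()] (>= 2 samples, >= 1 site).
#' @return A `pca_result` whose scores rows are samples.
#' @export
global_pca <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(gm$sample_ids) >= 2, ncol(gm$geno) >= 1)
  pca(gm$geno, center = TRUE, scale = FALSE)
}

#' Window specification for local analyses
#'
#' @param size_bp Window size (default 100 kb).
#' @param step_bp Step between window starts; default equal to the size
#'   (non-overlapping windows).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(size_bp = 100000L, step_bp = size_bp) {
  stopifnot(step_bp > 0, step_bp <= size_bp)
  structure(list(size_bp = as.integer(size_bp), step_bp = as.integer(step_bp)),
            class = "window_spec")
}

#' Local PCA along the genome in sliding windows
#'
#' Per-window genotype PCA as in [global_pca()]. Each window's PC1 is
#' sign-polarised so that its correlation with the global PC1 sample
#' scores is non-negative. Windows with fewer than `min_sites` SNPs are
#' flagged `skipped` and carry `NA` scores.
#'
#' @param gm A [genotype_matrix()] with positions sorted per chromosome.
#' @param windows A [window_spec()].
#' @param min_sites Minimum SNPs per analysable window (default 10).
#' @return Object of class `window_score_track`: data.frame with `chrom`,
#'   `start`, `end` (0-based half-open), `n_sites`, `skipped`, one
#'   `score.<sample>` column per sample, and attribute `global_pc1`.
#' @export
local_pca <- function(gm, windows = window_spec(), min_sites = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(windows, "window_spec"))
  gscore <- global_pca(gm)$scores[, 1]
  rows <- list()
  for (chrom in unique(gm$sites$chrom)) {
    on_chrom <- which(gm$sites$chrom == chrom)
    pos <- gm$sites$pos[on_chrom]          # 1-based bp
    max_pos <- max(pos)
    starts <- seq.int(0L, max(0L, max_pos - 1L), by = windows$step_bp)
    for (s in starts) {
      e <- s + windows$size_bp
      in_win <- on_chrom[pos > s & pos <= e]
      n <- length(in_win)
      if (n < min_sites) {
        sc <- rep(NA_real_, length(gm$sample_ids))
        skipped <- TRUE
      } else {
        wp <- pca(gm$geno[, in_win, drop = FALSE], center = TRUE)
        sc <- wp$scores[, 1]
        r <- suppressWarnings(cor(sc, gscore))
        if (!is.na(r) && r < 0) sc <- -sc
        skipped <- FALSE
      }
      rows[[length(rows) + 1L]] <- c(list(chrom = chrom, start = s, end = e,
                                          n_sites = n, skipped = skipped),
                                     as.list(setNames(sc, paste0("score.", gm$sample_ids))))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  attr(out, "global_pc1") <- gscore
  class(out) <- c("window_score_track", "data.frame")
  out
}

track_score_matrix <- function(track) {
  cols <- grep("^score\\.", names(track), value = TRUE)
  m <- as.matrix(track[, cols, drop = FALSE])
  colnames(m) <- sub("^score\\.", "", cols)
  m
}

#' Per-window hybrid index of a focal sample
#'
#' Places the focal sample's window PC1 score on the segment between the
#' two population centroids (computed from non-focal samples): 0 = home
#' centroid, 1 = other-population centroid, clipped to `[0, 1]`. Windows
#' with degenerate (equal) centroids or skipped windows yield `NA`.
#'
#' @param track A `window_score_track` from [local_pca()].
#' @param populations Named character/factor vector: sample -> population
#'   label (exactly two levels).
#' @param focal_sample Sample id to score.
#' @return The track data.frame with an added `hybrid_index` column.
#' @export
window_assignment_score <- function(track, populations, focal_sample) {
  m <- track_score_matrix(track)
  stopifnot(focal_sample %in% colnames(m),
            focal_sample %in% names(populations))
  populations <- populations[colnames(m)]
  home <- populations[[focal_sample]]
  lv <- unique(as.character(populations))
  stopifnot(length(lv) == 2)
  other <- setdiff(lv, home)
  home_samples <- setdiff(colnames(m)[populations == home], focal_sample)
  other_samples <- setdiff(colnames(m)[populations == other], focal_sample)
  stopifnot(length(home_samples) >= 1, length(other_samples) >= 1)
  c_home <- rowMeans(m[, home_samples, drop = FALSE])
  c_other <- rowMeans(m[, other_samples, drop = FALSE])
  denom <- c_other - c_home
  idx <- (m[, focal_sample] - c_home) / denom
  idx[abs(denom) < sqrt(.Machine$double.eps)] <- NA_real_
  idx <- pmin(pmax(idx, 0), 1)
  track$hybrid_index <- idx
  track
}

#' Observed heterozygosity
#'
#' Pooled fraction of genotype calls equal to dosage 1 over the selected
#' sites, overall and per chromosome.
#'
#' @param gm A [genotype_matrix()] with no missing genotypes.
#' @param chrom Optional chromosome id(s) restricting the site subset.
#' @return List with `overall` and `per_chromosome` (named vector).
#' @export
observed_heterozygosity <- function(gm, chrom = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sel <- if (is.null(chrom)) seq_len(ncol(gm$geno)) else
    which(gm$sites$chrom %in% chrom)
  if (length(sel) == 0) stop("empty site subset")
  g <- gm$geno[, sel, drop = FALSE]
  if (anyNA(g)) stop("missing genotypes present; filter first")
  per <- vapply(split(sel, gm$sites$chrom[sel]), function(ix) {
    mean(gm$geno[, ix, drop = FALSE] == 1L)
  }, numeric(1))
  list(overall = mean(g == 1L), per_chromosome = per)
}

#' Allele-sharing distance matrix between samples
#'
#' Pairwise distance = mean per-site absolute dosage difference divided
#' by 2, so that opposite homozygotes at every site give distance 1.
#'
#' @param gm A [genotype_matrix()].
#' @param sites Optional site index subset.
#' @return A `dist` object over samples.
#' @export
allele_sharing_dist <- function(gm, sites = NULL) {
  g <- if (is.null(sites)) gm$geno else gm$geno[, sites, drop = FALSE]
  stopifnot(ncol(g) >= 1)
  d <- as.matrix(dist(g, method = "manhattan")) / (2 * ncol(g))
  as.dist(d)
}

#' Neighbor-joining tree of samples in a genomic region
#'
#' Builds the allele-sharing distance matrix over the sites of a region
#' and reconstructs an unrooted neighbor-joining tree; negative branch
#' lengths are clamped to 0.
#'
#' @param gm A [genotype_matrix()] with >= 3 samples.
#' @param chrom Chromosome id; `NULL` uses all sites.
#' @param start_bp,end_bp Optional half-open bp bounds (`pos` in
#'   `(start_bp, end_bp]`).
#' @return An [ape::phylo] tree (use [ape::write.tree()] for newick).
#' @export
window_tree <- function(gm, chrom = NULL, start_bp = NULL, end_bp = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), length(gm$sample_ids) >= 3)
  sel <- seq_len(ncol(gm$geno))
  if (!is.null(chrom)) sel <- sel[gm$sites$chrom[sel] %in% chrom]
  if (!is.null(start_bp)) sel <- sel[gm$sites$pos[sel] > start_bp]
  if (!is.null(end_bp)) sel <- sel[gm$sites$pos[sel] <= end_bp]
  if (length(sel) == 0) stop("region contains no sites")
  tr <- ape::nj(allele_sharing_dist(gm, sel))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
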