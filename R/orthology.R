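#' Alignment scoring parameters
#'
#' Substitution matrix plus affine gap penalties for the local-alignment
#' scorer. A gap of length L costs `gap_open + L * gap_extend`. The default
#' 11/1 penalties are the common protein-search defaults; `X` scores 0
#' against every residue (neutral masking).
#'
#' @param matrix Substitution matrix with residue dimnames; default the
#'   embedded [blosum62()].
#' @param gap_open,gap_extend Positive gap penalties.
#' @return Object of class `align_params`.
#' @export
align_params <- function(matrix = blosum62(), gap_open = 11L, gap_extend = 1L) {
  stopifnot(gap_open > 0, gap_extend > 0,
            is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "align_params")
}

#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment score between two protein sequences over the
#' 20-letter alphabet plus `X`. The score is symmetric in its arguments and
#' floored at zero (the empty local alignment).
#'
#' @param seq_a,seq_b Non-empty protein sequence strings.
#' @param params An [align_params()].
#' @return Integer score, `>= 0`.
#' @export
sw_score <- function(seq_a, seq_b, params = align_params()) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            nzchar(seq_a), nzchar(seq_b))
  .sw_score_cpp(toupper(seq_a), toupper(seq_b), params$matrix,
                params$gap_open, params$gap_extend)
}

#' All-vs-all Smith-Waterman score matrix between two proteomes
#'
#' @param set_a,set_b [sequence_set()]s (protein).
#' @param params An [align_params()].
#' @return Integer matrix with dimnames from the gene ids.
#' @export
sw_score_matrix <- function(set_a, set_b, params = align_params()) {
  stopifnot(inherits(set_a, "sequence_set"), inherits(set_b, "sequence_set"))
  m <- .sw_score_matrix_cpp(unname(set_a$seqs), unname(set_b$seqs),
                            params$matrix, params$gap_open, params$gap_extend)
  dimnames(m) <- list(names(set_a$seqs), names(set_b$seqs))
  m
}

best_hits_from_scores <- function(scores) {
  # unique row-wise best partner; ties (two partners at the best score)
  # drop the gene -- conservative, deterministic RBH practice
  best <- apply(scores, 1, max)
  idx <- vapply(seq_len(nrow(scores)), function(i) {
    w <- which(scores[i, ] == best[i])
    if (length(w) == 1L) w else NA_integer_
  }, integer(1))
  idx
}

#' Reciprocal best hits between two proteomes
#'
#' A pair (a, b) is emitted iff b is a's unique best-scoring partner in set
#' B and a is b's unique best-scoring partner in set A. Equal-best-score
#' ties drop the gene.
#'
#' @param set_a,set_b Non-empty protein [sequence_set()]s.
#' @param params An [align_params()].
#' @param scores Optional precomputed score matrix (rows = A, cols = B),
#'   e.g. bitscores imported from an external search tool via
#'   [scores_from_hit_table()]; when supplied no alignment is run.
#' @return Object of class `ortholog_pairs`: list with `species_a`,
#'   `species_b` and `pairs` (data.frame `gene_a, gene_b, score`).
#' @export
reciprocal_best_hits <- function(set_a, set_b, params = align_params(),
                                 scores = NULL) {
  if (is.null(scores)) {
    stopifnot(length(set_a) > 0, length(set_b) > 0)
    scores <- sw_score_matrix(set_a, set_b, params)
  }
  fwd <- best_hits_from_scores(scores)
  rev <- best_hits_from_scores(t(scores))
  ia <- which(!is.na(fwd))
  keep <- ia[!is.na(rev[fwd[ia]]) & rev[fwd[ia]] == ia]
  pairs <- data.frame(
    gene_a = rownames(scores)[keep],
    gene_b = colnames(scores)[fwd[keep]],
    score = scores[cbind(keep, fwd[keep])],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(species_a = if (inherits(set_a, "sequence_set")) set_a$species_label else "A",
                 species_b = if (inherits(set_b, "sequence_set")) set_b$species_label else "B",
                 pairs = pairs),
            class = "ortholog_pairs")
}

#' @exportS3Method base::print
print.ortholog_pairs <- function(x, ...) {
  cat(sprintf("<ortholog_pairs> %s vs %s: %d pair(s)\n",
              x$species_a, x$species_b, nrow(x$pairs)))
  invisible(x)
}

#' Import an all-vs-all score matrix from a 12-column hit table
#'
#' Lets external search tools (DIAMOND, ssearch) stand in for the built-in
#' scorer at scale: the bitscore column becomes the score; multiple hits for
#' a (query, subject) pair keep the maximum.
#'
#' @param hits Hit data.frame from [read_hit_table()].
#' @param query_ids,subject_ids Full id universes (genes without hits score 0).
#' @return Numeric score matrix.
#' @export
scores_from_hit_table <- function(hits, query_ids = NULL, subject_ids = NULL) {
  if (is.null(query_ids)) query_ids <- unique(hits$query_id)
  if (is.null(subject_ids)) subject_ids <- unique(hits$subject_id)
  m <- matrix(0, length(query_ids), length(subject_ids),
              dimnames = list(query_ids, subject_ids))
  for (k in seq_len(nrow(hits))) {
    q <- hits$query_id[k]; s <- hits$subject_id[k]
    if (q %in% query_ids && s %in% subject_ids)
      m[q, s] <- max(m[q, s], hits$bitscore[k])
  }
  m
}

#' Cross-species consistent reciprocal-best-hit groups
#'
#' Computes pairwise RBH for every unordered species pair and emits one
#' ortholog group per clique: a set with exactly one gene per species in
#' which every pairwise RBH relation holds. With two species this reduces
#' to [reciprocal_best_hits()].
#'
#' @param sets List of >= 2 protein [sequence_set()]s with distinct labels.
#' @param params An [align_params()].
#' @return data.frame with one column per species label, one row per group.
#' @export
consistent_rbh <- function(sets, params = align_params()) {
  stopifnot(length(sets) >= 2)
  labels <- vapply(sets, function(s) s$species_label, character(1))
  if (anyDuplicated(labels)) stop("species labels must be distinct")
  n <- length(sets)
  # maps[[i]][[j]]: named vector gene_i -> gene_j for i < j, plus reverse
  maps <- vector("list", n)
  for (i in seq_len(n)) maps[[i]] <- vector("list", n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rb <- reciprocal_best_hits(sets[[i]], sets[[j]], params)
    maps[[i]][[j]] <- setNames(rb$pairs$gene_b, rb$pairs$gene_a)
    maps[[j]][[i]] <- setNames(rb$pairs$gene_a, rb$pairs$gene_b)
  }
  anchor <- maps[[1]]
  candidates <- if (n == 2) names(anchor[[2]]) else
    Reduce(intersect, lapply(2:n, function(j) names(anchor[[j]])))
  rows <- lapply(candidates, function(g1) {
    members <- c(g1, vapply(2:n, function(j) unname(anchor[[j]][g1]),
                            character(1)))
    if (n >= 3) for (i in 2:(n - 1)) for (j in (i + 1):n) {
      mp <- maps[[i]][[j]]
      partner <- mp[members[i]]
      if (is.na(partner) || partner != members[j]) return(NULL)
    }
    members
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- as.data.frame(do.call(rbind, c(rows, list(matrix(character(), 0, n)))),
                       stringsAsFactors = FALSE)
  names(out) <- labels
  rownames(out) <- NULL
  out
}
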