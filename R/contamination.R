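#' Configuration of the bacterial-contamination decision rule
#'
#' @param evalue_threshold Significance threshold; hits with
#'   `evalue < evalue_threshold` (strict) are significant. Default 1e-20.
#' @param excluded_species Species labels removed from the subjects before
#'   classification (e.g. the query species already present in the
#'   database, which would mask contaminants by self-hits).
#' @return Object of class `contamination_config`.
#' @export
contamination_config <- function(evalue_threshold = 1e-20,
                                 excluded_species = character()) {
  stopifnot(is.numeric(evalue_threshold), evalue_threshold > 0)
  structure(list(evalue_threshold = evalue_threshold,
                 excluded_species = as.character(excluded_species)),
            class = "contamination_config")
}

#' Classify queries as putative bacterial contaminants
#'
#' Applies the decision rule: after removing hits to excluded species, a
#' query is a contaminant iff it has no significant Metazoa hit and at
#' least one significant Bacteria hit (significant = e-value strictly
#' below the threshold). Hits to the `Other` taxon group neither rescue
#' nor condemn. Queries with no hits at all are non-contaminant.
#'
#' @param hits Hit data.frame from [read_hit_table()] (needs `query_id`,
#'   `evalue`, `subject_taxon_group`, optionally `subject_species`).
#' @param config A [contamination_config()].
#' @param queries Optional full query universe; queries without hits are
#'   reported as non-contaminant.
#' @param best_hit_only If `TRUE`, classify on each query's single best
#'   (lowest e-value) significant hit instead of all hits.
#' @return data.frame `query_id, is_contaminant, n_significant_bacterial,
#'   n_significant_metazoan`, one row per distinct query.
#' @export
classify_contaminants <- function(hits, config = contamination_config(),
                                  queries = NULL, best_hit_only = FALSE) {
  stopifnot(inherits(config, "contamination_config"))
  if (length(config$excluded_species) && nrow(hits) > 0)
    hits <- hits[!hits$subject_species %in% config$excluded_species, ,
                 drop = FALSE]
  if (is.null(queries)) queries <- unique(hits$query_id)
  sig <- hits[hits$evalue < config$evalue_threshold, , drop = FALSE]
  if (best_hit_only && nrow(sig) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(sig)), sig$query_id), function(ix) {
      ix[which.min(sig$evalue[ix])]
    }), use.names = FALSE)
    sig <- sig[keep, , drop = FALSE]
  }
  n_bac <- table(factor(sig$query_id[sig$subject_taxon_group == "Bacteria"],
                        levels = queries))
  n_met <- table(factor(sig$query_id[sig$subject_taxon_group == "Metazoa"],
                        levels = queries))
  out <- data.frame(
    query_id = queries,
    is_contaminant = as.integer(n_met) == 0L & as.integer(n_bac) >= 1L,
    n_significant_bacterial = as.integer(n_bac),
    n_significant_metazoan = as.integer(n_met),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Partition contaminant calls by pseudo-chromosome membership
#'
#' Splits calls into genes located on the pseudo-chromosomes versus genes
#' on the remaining (unplaced) sequences and counts contaminants and
#' totals in each partition.
#'
#' @param calls Output of [classify_contaminants()].
#' @param gene_positions Gene-position data.frame covering every called
#'   query.
#' @param pseudo_chromosome_ids Character vector of pseudo-chromosome ids.
#' @return List with `on` and `off`, each `c(contaminants =, total =)`.
#' @export
partition_by_scaffold <- function(calls, gene_positions,
                                  pseudo_chromosome_ids) {
  validate_gene_positions(gene_positions)
  chrom <- setNames(gene_positions$chrom, gene_positions$gene_id)
  missing <- setdiff(calls$query_id, names(chrom))
  if (length(missing))
    stop("gene(s) without position: ", paste(missing, collapse = ", "))
  on_chr <- chrom[calls$query_id] %in% pseudo_chromosome_ids
  list(
    on = c(contaminants = sum(calls$is_contaminant[on_chr]),
           total = sum(on_chr)),
    off = c(contaminants = sum(calls$is_contaminant[!on_chr]),
            total = sum(!on_chr)))
}
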