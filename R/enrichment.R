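#' Pearson chi-squared test on a 2x2 count table
#'
#' Tests whether a family's proportion differs between a focal gene set
#' (`k_focal` of `n_focal`) and a pooled comparator (`k_pool` of
#' `n_pool`): Pearson chi-squared on the 2x2 table, 1 df, no continuity
#' correction, two-sided p from the chi-squared(1) survival function.
#' Zero-margin tables return statistic 0, p 1. All arguments are
#' vectorised.
#'
#' @param k_focal,n_focal,k_pool,n_pool Counts, `k <= n`, `n > 0`.
#' @return List with `statistic` and `p`.
#' @export
chi2_family_test <- function(k_focal, n_focal, k_pool, n_pool) {
  stopifnot(all(n_focal > 0), all(n_pool > 0),
            all(k_focal >= 0), all(k_pool >= 0),
            all(k_focal <= n_focal), all(k_pool <= n_pool))
  a <- as.numeric(k_focal); b <- as.numeric(n_focal) - a
  c_ <- as.numeric(k_pool); d <- as.numeric(n_pool) - c_
  n <- a + b + c_ + d
  stat <- rep(0, length(a))
  margin_ok <- (a + c_) > 0 & (b + d) > 0
  stat[margin_ok] <- (n * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d)))[margin_ok]
  p <- ifelse(margin_ok, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  p[!margin_ok] <- 1
  list(statistic = stat, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values with enforced monotonicity, capped at 1, plus the
#' significance mask at level `alpha` (adjusted p strictly below alpha).
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param alpha FDR level (default 0.01).
#' @return List with `p_adj` and `significant`.
#' @export
bh_adjust <- function(p_values, alpha = 0.01) {
  stopifnot(all(p_values >= 0 & p_values <= 1), alpha > 0, alpha < 1)
  p_adj <- p.adjust(p_values, method = "BH")
  list(p_adj = p_adj, significant = p_adj < alpha)
}

#' Family counts for one labelled gene set
#'
#' @param annotations 2-column data.frame (`gene_id`, `family_id`) or the
#'   path of a 2-column TSV; one family per gene.
#' @param label Set label.
#' @param total_genes Total genes in the set; default the number of
#'   distinct annotated genes.
#' @return Object of class `family_counts`.
#' @export
family_counts <- function(annotations, label = "set", total_genes = NULL) {
  if (is.character(annotations) && length(annotations) == 1)
    annotations <- read_annotation_tsv(annotations, c("gene_id", "family_id"))
  stopifnot(is.data.frame(annotations), ncol(annotations) >= 2)
  counts <- table(annotations[[2]])
  if (is.null(total_genes)) total_genes <- length(unique(annotations[[1]]))
  stopifnot(all(counts <= total_genes))
  structure(list(label = label,
                 counts = setNames(as.integer(counts), names(counts)),
                 total_genes = as.integer(total_genes)),
            class = "family_counts")
}

#' Family-level enrichment scan with BH-FDR
#'
#' One chi-squared test per family present in either gene set, BH-adjusted
#' across all tested families. Significant means adjusted p below `alpha`;
#' when `overrepresented_only` is set, families whose focal proportion does
#' not exceed the pool proportion are additionally excluded from the
#' significant set (the "overrepresented families" framing).
#'
#' @param focal,pool [family_counts()] objects.
#' @param alpha BH-FDR level (default 0.01).
#' @param overrepresented_only Keep only focal-enriched families in the
#'   significant set (default `TRUE`).
#' @param min_total Families with fewer than this many genes overall are
#'   not tested (default 0).
#' @return data.frame `family_id, count_focal, count_pool, chi2_stat,
#'   p_raw, p_adj, significant`, sorted by adjusted then raw p.
#' @export
family_enrichment_scan <- function(focal, pool, alpha = 0.01,
                                   overrepresented_only = TRUE,
                                   min_total = 0L) {
  stopifnot(inherits(focal, "family_counts"), inherits(pool, "family_counts"))
  fams <- sort(union(names(focal$counts), names(pool$counts)))
  k_f <- ifelse(is.na(focal$counts[fams]), 0L, focal$counts[fams])
  k_p <- ifelse(is.na(pool$counts[fams]), 0L, pool$counts[fams])
  keep <- (k_f + k_p) >= min_total
  fams <- fams[keep]; k_f <- k_f[keep]; k_p <- k_p[keep]
  ct <- chi2_family_test(k_f, focal$total_genes, k_p, pool$total_genes)
  adj <- bh_adjust(ct$p, alpha)
  sig <- adj$significant
  if (overrepresented_only)
    sig <- sig & (k_f / focal$total_genes > k_p / pool$total_genes)
  out <- data.frame(family_id = fams, count_focal = unname(k_f),
                    count_pool = unname(k_p), chi2_stat = ct$statistic,
                    p_raw = ct$p, p_adj = adj$p_adj, significant = sig,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO term enrichment of a study set against a population
#'
#' One-sided hypergeometric overrepresentation test per GO term, with
#' optional propagation of annotations to ancestor terms along
#' child-parent ontology edges before testing, and BH adjustment across
#' terms.
#'
#' @param study Character vector of study gene ids (subset of `population`).
#' @param population Character vector of population gene ids.
#' @param gene2go 2-column data.frame (`gene_id`, `term`) or TSV path.
#' @param ontology_edges Optional 2-column data.frame (`child`, `parent`)
#'   of ontology edges used for annotation propagation.
#' @param alpha BH-FDR level (default 0.01).
#' @return data.frame `term, k_study, k_pop, p_raw, p_adj, significant`,
#'   sorted by adjusted then raw p.
#' @export
go_enrichment <- function(study, population, gene2go, ontology_edges = NULL,
                          alpha = 0.01) {
  if (is.character(gene2go) && length(gene2go) == 1)
    gene2go <- read_annotation_tsv(gene2go, c("gene_id", "term"))
  missing <- setdiff(study, population)
  if (length(missing))
    stop("study gene(s) missing from population: ",
         paste(missing, collapse = ", "))
  gene2go <- unique(gene2go[gene2go[[1]] %in% population, 1:2, drop = FALSE])
  names(gene2go) <- c("gene_id", "term")
  if (!is.null(ontology_edges))
    gene2go <- propagate_annotations(gene2go, ontology_edges)
  N <- length(unique(population))
  n <- length(unique(study))
  by_term <- split(gene2go$gene_id, gene2go$term)
  terms <- names(by_term)
  k_pop <- lengths(by_term)
  k_study <- vapply(by_term, function(g) sum(g %in% study), integer(1))
  p <- phyper(k_study - 1, k_pop, N - k_pop, n, lower.tail = FALSE)
  adj <- bh_adjust(p, alpha)
  out <- data.frame(term = terms, k_study = unname(k_study),
                    k_pop = unname(k_pop), p_raw = unname(p),
                    p_adj = unname(adj$p_adj),
                    significant = unname(adj$significant),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# annotate each gene with every ancestor of its terms (transitive closure
# over child -> parent edges; cycles are tolerated by fixpoint iteration)
propagate_annotations <- function(gene2go, ontology_edges) {
  stopifnot(ncol(ontology_edges) >= 2)
  parent_of <- split(as.character(ontology_edges[[2]]),
                     as.character(ontology_edges[[1]]))
  pairs <- unique(gene2go)
  repeat {
    add <- pairs[pairs$term %in% names(parent_of), , drop = FALSE]
    if (nrow(add) == 0) break
    new <- do.call(rbind, lapply(seq_len(nrow(add)), function(i) {
      data.frame(gene_id = add$gene_id[i], term = parent_of[[add$term[i]]],
                 stringsAsFactors = FALSE)
    }))
    new <- unique(new)
    before <- nrow(pairs)
    pairs <- unique(rbind(pairs, new))
    if (nrow(pairs) == before) break
  }
  pairs
}
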