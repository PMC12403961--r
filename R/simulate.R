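#' Simulate a family of diverged proteomes with known orthology
#'
#' Draws an ancestral proteome i.i.d. from a base composition, then derives
#' one proteome per species by per-site substitution at the given
#' divergence. A per-species GC bias tilts residue sampling (ancestral
#' draws use bias 0, substituted residues use the species' bias) toward
#' high-codon-GC amino acids, weighting residue `a` proportionally to
#' `exp(gc_bias * (gc_a - mean(gc)))` with `gc_a` from
#' [amino_acid_gc_table()]. The true ortholog map is positional: gene `i`
#' of every species descends from ancestral gene `i`.
#'
#' @param n_species Number of derived species.
#' @param n_genes Genes per species.
#' @param mean_len Mean protein length (lengths ~ 30 + Poisson).
#' @param divergence Per-species substitution probability per site
#'   (recycled).
#' @param gc_bias Per-species GC bias (recycled; 0 = no bias).
#' @param seed Random seed (required; generators are pure functions of
#'   their parameters and seed).
#' @param species_labels Optional labels; default `sp1, sp2, ...`.
#' @return List with `ancestor` ([sequence_set()]), `proteomes` (named
#'   list of [sequence_set()]s), `true_orthologs` (data.frame, one column
#'   per species), `gc_bias`, `divergence`, `seed`.
#' @export
simulate_proteome_family <- function(n_species = 2, n_genes = 50,
                                     mean_len = 150, divergence = 0.2,
                                     gc_bias = 0, seed,
                                     species_labels = NULL) {
  stopifnot(n_species >= 1, n_genes >= 1, mean_len > 30,
            all(divergence >= 0 & divergence <= 1))
  set.seed(seed)
  divergence <- rep_len(divergence, n_species)
  gc_bias <- rep_len(gc_bias, n_species)
  if (is.null(species_labels)) species_labels <- paste0("sp", seq_len(n_species))
  gc <- amino_acid_gc_table()
  aa_weights <- function(bias) {
    w <- exp(bias * (gc - mean(gc)))
    w / sum(w)
  }
  lens <- 30L + stats::rpois(n_genes, mean_len - 30)
  w0 <- aa_weights(0)
  ancestor <- vapply(lens, function(L)
    paste(sample(AA20, L, replace = TRUE, prob = w0), collapse = ""),
    character(1))
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  names(ancestor) <- gene_ids
  proteomes <- list()
  for (s in seq_len(n_species)) {
    ws <- aa_weights(gc_bias[s])
    seqs <- vapply(ancestor, function(a) {
      res <- strsplit(a, "")[[1]]
      hit <- runif(length(res)) < divergence[s]
      if (any(hit))
        res[hit] <- sample(AA20, sum(hit), replace = TRUE, prob = ws)
      paste(res, collapse = "")
    }, character(1))
    names(seqs) <- paste0(species_labels[s], "_", gene_ids)
    proteomes[[species_labels[s]]] <-
      sequence_set(seqs, species_label = species_labels[s])
  }
  true_orthologs <- as.data.frame(
    lapply(species_labels, function(sl) paste0(sl, "_", gene_ids)),
    col.names = species_labels, stringsAsFactors = FALSE)
  list(ancestor = sequence_set(ancestor, species_label = "ancestor"),
       proteomes = proteomes, true_orthologs = true_orthologs,
       gc_bias = setNames(gc_bias, species_labels),
       divergence = setNames(divergence, species_labels), seed = seed)
}

#' Simulate a collagen-like protein with a known repeat count
#'
#' Constructs `flank + (G,X,Y) x (k_repeats + 3) + flank` where X is
#' proline with probability `pX_pro` (otherwise a non-G, non-P residue)
#' and Y likewise with `pY_pro`, and flanks contain no glycine, so that
#' [scan_gxy()] counts exactly `k_repeats` central triplets. The truth
#' profile records the realised proline fractions over the counted
#' triplets.
#'
#' @param k_repeats Number of counted central triplets (>= 1).
#' @param pX_pro,pY_pro Proline probabilities at X and Y.
#' @param flank_len Length of each non-G flank.
#' @param seed Random seed.
#' @param gene_id Id recorded in the truth profile.
#' @return List with `sequence` and `truth` (a `repeat_profile`).
#' @export
simulate_collagen_protein <- function(k_repeats, pX_pro = 0.3, pY_pro = 0.3,
                                      flank_len = 20L, seed,
                                      gene_id = "sim_collagen") {
  stopifnot(k_repeats >= 1, pX_pro >= 0, pX_pro <= 1, pY_pro >= 0,
            pY_pro <= 1, flank_len >= 0)
  set.seed(seed)
  non_g <- setdiff(AA20, "G")
  non_gp <- setdiff(AA20, c("G", "P"))
  m <- k_repeats + 3L
  x <- ifelse(runif(m) < pX_pro, "P", sample(non_gp, m, replace = TRUE))
  y <- ifelse(runif(m) < pY_pro, "P", sample(non_gp, m, replace = TRUE))
  triplets <- paste0("G", x, y, collapse = "")
  flank1 <- paste(sample(non_g, flank_len, replace = TRUE), collapse = "")
  flank2 <- paste(sample(non_g, flank_len, replace = TRUE), collapse = "")
  seq <- paste0(flank1, triplets, flank2)
  counted <- 2:(m - 2L)  # interior triplets of the G frame
  truth <- structure(list(
    gene_id = gene_id, repeat_count = k_repeats,
    frac_pro_X = mean(x[counted] == "P"),
    frac_pro_Y = mean(y[counted] == "P"),
    sequence_length = nchar(seq)), class = "repeat_profile")
  list(sequence = seq, truth = truth,
       params = list(k_repeats = k_repeats, pX_pro = pX_pro,
                     pY_pro = pY_pro, flank_len = flank_len, seed = seed))
}

#' Simulate two-population biallelic genotypes (Balding-Nichols model)
#'
#' Per site, an ancestral allele frequency `p ~ Uniform(0.05, 0.95)` and
#' population frequencies `~ Beta(p(1-F)/F, (1-p)(1-F)/F)` generate
#' genotypes `~ Binomial(2, freq)`. A designated barrier chromosome uses a
#' larger `F` and ancestral frequencies drawn near 0/1, depressing
#' heterozygosity. Within introgression blocks the focal sample draws its
#' genotypes from the donor population's frequencies instead of its own.
#'
#' @param n_per_pop Samples per population (>= 2); populations are `north`
#'   and `south`.
#' @param chromosomes Chromosome ids.
#' @param chrom_length_bp Chromosome length in bp (recycled).
#' @param sites_per_chromosome SNPs per chromosome (recycled).
#' @param F_st Divergence parameter per chromosome (recycled), in (0, 1).
#' @param barrier_chrom Optional chromosome id acting as the low-diversity
#'   barrier.
#' @param barrier_F Divergence parameter of the barrier chromosome.
#' @param introgression_blocks Optional data.frame `sample, chrom,
#'   start_bp, end_bp, donor` of planted introgression blocks.
#' @param seed Random seed.
#' @return List with `gm` (a [genotype_matrix()]) and `truth` (list:
#'   `populations` named vector, `blocks`, `barrier_chrom`, `F_st`,
#'   `seed`).
#' @export
simulate_two_pop_genotypes <- function(n_per_pop = 3,
                                       chromosomes = paste0("chr", 1:3),
                                       chrom_length_bp = 1e6,
                                       sites_per_chromosome = 500,
                                       F_st = 0.2,
                                       barrier_chrom = NULL,
                                       barrier_F = 0.6,
                                       introgression_blocks = NULL,
                                       seed) {
  stopifnot(n_per_pop >= 2, all(F_st > 0 & F_st < 1))
  set.seed(seed)
  n_chr <- length(chromosomes)
  chrom_length_bp <- rep_len(chrom_length_bp, n_chr)
  sites_per_chromosome <- rep_len(sites_per_chromosome, n_chr)
  F_st <- setNames(rep_len(F_st, n_chr), chromosomes)
  if (!is.null(barrier_chrom)) {
    stopifnot(barrier_chrom %in% chromosomes, barrier_F > 0, barrier_F < 1)
    F_st[barrier_chrom] <- barrier_F
  }
  samples <- c(paste0("north", seq_len(n_per_pop)),
               paste0("south", seq_len(n_per_pop)))
  populations <- setNames(rep(c("north", "south"), each = n_per_pop), samples)
  site_list <- list(); geno_list <- list()
  for (ci in seq_len(n_chr)) {
    chrom <- chromosomes[ci]
    n_sites <- sites_per_chromosome[ci]
    pos <- sort(sample.int(chrom_length_bp[ci], n_sites))
    if (!is.null(barrier_chrom) && chrom == barrier_chrom) {
      u <- runif(n_sites, 0.01, 0.1)
      p <- ifelse(runif(n_sites) < 0.5, u, 1 - u)
    } else {
      p <- runif(n_sites, 0.05, 0.95)
    }
    Fc <- F_st[chrom]
    shape_scale <- (1 - Fc) / Fc
    freq <- list(
      north = rbeta(n_sites, p * shape_scale, (1 - p) * shape_scale),
      south = rbeta(n_sites, p * shape_scale, (1 - p) * shape_scale))
    g <- matrix(NA_integer_, nrow = length(samples), ncol = n_sites,
                dimnames = list(samples, NULL))
    for (s in samples) {
      f <- freq[[populations[[s]]]]
      if (!is.null(introgression_blocks)) {
        blk <- introgression_blocks[
          introgression_blocks$sample == s &
            introgression_blocks$chrom == chrom, , drop = FALSE]
        for (b in seq_len(nrow(blk))) {
          in_blk <- pos > blk$start_bp[b] & pos <= blk$end_bp[b]
          f[in_blk] <- freq[[blk$donor[b]]][in_blk]
        }
      }
      g[s, ] <- rbinom(n_sites, 2L, f)
    }
    site_list[[ci]] <- data.frame(chrom = chrom, pos = pos,
                                  ref = "A", alt = "T",
                                  stringsAsFactors = FALSE)
    geno_list[[ci]] <- g
  }
  sites <- do.call(rbind, site_list)
  geno <- do.call(cbind, geno_list)
  gm <- genotype_matrix(geno, sites, sample_ids = samples)
  list(gm = gm,
       truth = list(populations = populations,
                    blocks = introgression_blocks,
                    barrier_chrom = barrier_chrom, F_st = F_st, seed = seed))
}

#' Simulate a taxon-labelled hit table with planted contaminants
#'
#' Planted contaminants receive only Bacteria hits with significant
#' e-values (below the threshold) and no Metazoa hits; clean queries
#' receive at least one significant Metazoa hit and, with probability
#' `p_clean_bacterial`, additional Bacteria hits. E-value ranges are
#' log10-uniform and configurable to create boundary cases.
#'
#' @param n_queries Number of queries.
#' @param contaminant_fraction Fraction of planted contaminants.
#' @param sig_evalue_range,nonsig_evalue_range Length-2 e-value ranges for
#'   significant / non-significant hits (log10-uniform draws).
#' @param p_clean_bacterial Probability that a clean query also has a
#'   Bacteria hit.
#' @param max_hits_per_query Maximum hits drawn per query per group.
#' @param seed Random seed.
#' @return List with `hits` (data.frame in [read_hit_table()] layout) and
#'   `truth` (named logical: query is a contaminant).
#' @export
simulate_hit_table <- function(n_queries = 100, contaminant_fraction = 0.2,
                               sig_evalue_range = c(1e-60, 1e-25),
                               nonsig_evalue_range = c(1e-15, 1e-3),
                               p_clean_bacterial = 0.3,
                               max_hits_per_query = 3L, seed) {
  stopifnot(contaminant_fraction >= 0, contaminant_fraction <= 1)
  set.seed(seed)
  r_ev <- function(n, range)
    10^runif(n, log10(range[1]), log10(range[2]))
  queries <- sprintf("q%04d", seq_len(n_queries))
  n_cont <- round(n_queries * contaminant_fraction)
  truth <- setNames(c(rep(TRUE, n_cont), rep(FALSE, n_queries - n_cont)),
                    queries)
  rows <- list()
  add <- function(q, grp, sp, ev)
    rows[[length(rows) + 1L]] <<- data.frame(
      query_id = q, subject_id = paste0(sp, "_", length(rows)),
      pident = round(runif(1, 30, 95), 1), length = sample(50:500, 1),
      evalue = ev, bitscore = round(-10 * log10(ev + 1e-300), 1),
      subject_species = sp, subject_taxon_group = grp,
      stringsAsFactors = FALSE)
  for (q in queries) {
    if (truth[[q]]) {
      for (k in seq_len(sample.int(max_hits_per_query, 1)))
        add(q, "Bacteria", "bact_sp", r_ev(1, sig_evalue_range))
      if (runif(1) < 0.3)  # non-significant metazoan noise is allowed
        add(q, "Metazoa", "meta_sp", r_ev(1, nonsig_evalue_range))
    } else {
      for (k in seq_len(sample.int(max_hits_per_query, 1)))
        add(q, "Metazoa", "meta_sp", r_ev(1, sig_evalue_range))
      if (runif(1) < p_clean_bacterial)
        add(q, "Bacteria", "bact_sp", r_ev(1, sig_evalue_range))
    }
  }
  hits <- do.call(rbind, rows)
  rownames(hits) <- NULL
  list(hits = hits, truth = truth)
}

#' Simulate gene-family annotation tables with planted enrichment
#'
#' Families are assigned multinomially with equal base probabilities; the
#' focal set multiplies the probabilities of the enriched families by
#' their fold effects and renormalises.
#'
#' @param n_genes_focal,n_genes_pool Genes in the focal / pool sets.
#' @param n_families Number of families.
#' @param enriched Named numeric vector family id -> fold (> 0); family
#'   ids are `fam0001, ...`. May be empty (null tables).
#' @param seed Random seed.
#' @return List with `focal` and `pool` annotation data.frames
#'   (`gene_id`, `family_id`) and `truth` (the `enriched` vector).
#' @export
simulate_family_annotations <- function(n_genes_focal = 2000,
                                        n_genes_pool = 2000,
                                        n_families = 100,
                                        enriched = numeric(), seed) {
  stopifnot(all(enriched > 0))
  set.seed(seed)
  fams <- sprintf("fam%04d", seq_len(n_families))
  stopifnot(all(names(enriched) %in% fams))
  base <- rep(1 / n_families, n_families)
  names(base) <- fams
  focal_p <- base
  focal_p[names(enriched)] <- focal_p[names(enriched)] * enriched
  focal_p <- focal_p / sum(focal_p)
  focal <- data.frame(
    gene_id = sprintf("focal_g%05d", seq_len(n_genes_focal)),
    family_id = sample(fams, n_genes_focal, replace = TRUE, prob = focal_p),
    stringsAsFactors = FALSE)
  pool <- data.frame(
    gene_id = sprintf("pool_g%05d", seq_len(n_genes_pool)),
    family_id = sample(fams, n_genes_pool, replace = TRUE, prob = base),
    stringsAsFactors = FALSE)
  list(focal = focal, pool = pool, truth = enriched)
}
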