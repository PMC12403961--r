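#' Validate a workflow run configuration
#'
#' A run configuration is a YAML file or an R list with the keys
#' `workflow` (one of `composition`, `popgen`, `screen`, `families`),
#' `inputs` (named paths), `params` (stage parameters) and `out_dir`.
#' Unknown top-level keys are rejected and every referenced input path
#' must exist at validation time.
#'
#' @param config YAML path or list.
#' @return The validated configuration list, invisibly classed
#'   `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed <- c("workflow", "inputs", "params", "out_dir", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$workflow) ||
      !config$workflow %in% c("composition", "popgen", "screen", "families"))
    stop("workflow must be one of composition, popgen, screen, families")
  if (is.null(config$out_dir)) stop("out_dir is required")
  config$params <- config$params %||% list()
  config$inputs <- config$inputs %||% list()
  for (nm in names(config$inputs)) {
    p <- config$inputs[[nm]]
    if (is.character(p) && length(p) == 1 && !file.exists(p))
      stop("input path does not exist: ", nm, " = ", p)
  }
  class(config) <- c("run_config", "list")
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run one of the four headline workflows
#'
#' * `composition`: proteome FASTAs -> pairwise RBH -> species-pair-
#'   averaged composition matrix -> PCA (matrix, scores, loadings TSVs).
#' * `popgen`: VCF -> variant filters -> global + local PCA ->
#'   per-chromosome observed heterozygosity (and an optional window tree).
#' * `screen`: hit table + taxon map -> contamination calls -> optional
#'   pseudo-chromosome partition summary.
#' * `families`: annotation TSVs -> family enrichment scan -> optional GO
#'   enrichment of the significant families' genes.
#'
#' Outputs are confined to `out_dir`; a JSON run manifest records the
#' workflow, parameters, seed, input checksums and package version. Any
#' stage error aborts with the stage name in the message.
#'
#' @param config A [run_config()], YAML path, or list.
#' @return Named list of output paths (including `manifest`), invisibly.
#' @export
run_workflow <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("workflow stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  out <- switch(cfg$workflow,
    composition = workflow_composition(cfg, stage),
    popgen = workflow_popgen(cfg, stage),
    screen = workflow_screen(cfg, stage),
    families = workflow_families(cfg, stage))
  manifest <- list(
    workflow = cfg$workflow,
    params = cfg$params,
    seed = cfg$seed,
    inputs = lapply(cfg$inputs, function(p)
      if (is.character(p) && length(p) == 1 && file.exists(p))
        list(path = p, md5 = unname(tools::md5sum(p))) else p),
    outputs = out,
    package_version = as.character(utils::packageVersion("ventcomp")),
    timestamp = format(Sys.time(), tz = "UTC"))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(out, list(manifest = manifest_path)))
}

workflow_composition <- function(cfg, stage) {
  fasta_paths <- cfg$inputs$proteomes
  stopifnot(!is.null(fasta_paths), !is.null(names(fasta_paths)))
  proteomes <- stage("read_proteomes", lapply(names(fasta_paths), function(sp)
    read_fasta(fasta_paths[[sp]], "protein", species_label = sp)))
  names(proteomes) <- names(fasta_paths)
  labels <- names(proteomes)
  pairs <- stage("reciprocal_best_hits", {
    out <- list()
    for (i in seq_len(length(labels) - 1)) for (j in (i + 1):length(labels))
      out[[length(out) + 1L]] <-
        reciprocal_best_hits(proteomes[[i]], proteomes[[j]])
    out
  })
  mat <- stage("composition_matrix",
               species_composition_matrix(proteomes, pairs,
                 pooled = isTRUE(cfg$params$pooled)))
  pc <- stage("pca", pca(mat, center = !isFALSE(cfg$params$center),
                         scale = isTRUE(cfg$params$scale)))
  list(
    composition_matrix = write_tsv(
      data.frame(species = rownames(mat), mat, check.names = FALSE),
      file.path(cfg$out_dir, "composition_matrix.tsv")),
    pca_scores = write_tsv(
      data.frame(species = rownames(pc$scores), pc$scores, check.names = FALSE),
      file.path(cfg$out_dir, "pca_scores.tsv")),
    pca_loadings = write_tsv(
      data.frame(amino_acid = rownames(pc$loadings), pc$loadings,
                 check.names = FALSE),
      file.path(cfg$out_dir, "pca_loadings.tsv")),
    explained = write_tsv(
      data.frame(component = seq_along(pc$explained),
                 explained_fraction = pc$explained),
      file.path(cfg$out_dir, "pca_explained.tsv")))
}

workflow_popgen <- function(cfg, stage) {
  stopifnot(!is.null(cfg$inputs$vcf))
  rec <- stage("read_vcf", read_vcf_biallelic(cfg$inputs$vcf))
  fc <- do.call(variant_filter_config,
                cfg$params[intersect(names(cfg$params),
                  names(formals(variant_filter_config)))])
  gm <- stage("apply_variant_filters", apply_variant_filters(rec, fc))
  gp <- stage("global_pca", global_pca(gm))
  ws <- window_spec(cfg$params$window_size %||% 100000L,
                    cfg$params$step %||% (cfg$params$window_size %||% 100000L))
  track <- stage("local_pca",
                 local_pca(gm, ws, min_sites = cfg$params$min_sites %||% 10L))
  het <- stage("observed_heterozygosity", observed_heterozygosity(gm))
  outs <- list(
    filter_log = write_tsv(
      data.frame(filter = names(attr(gm, "filter_log")),
                 n = as.integer(attr(gm, "filter_log"))),
      file.path(cfg$out_dir, "filter_log.tsv")),
    global_pca = write_tsv(
      data.frame(sample = rownames(gp$scores), gp$scores, check.names = FALSE),
      file.path(cfg$out_dir, "global_pca_scores.tsv")),
    local_pca = write_tsv(as.data.frame(track),
                          file.path(cfg$out_dir, "local_pca_track.tsv")),
    heterozygosity = write_tsv(
      data.frame(chromosome = c(names(het$per_chromosome), "overall"),
                 h_obs = c(het$per_chromosome, het$overall)),
      file.path(cfg$out_dir, "heterozygosity.tsv")))
  tr <- cfg$params$tree_region
  if (!is.null(tr)) {
    tree <- stage("window_tree",
                  window_tree(gm, tr$chrom, tr$start_bp, tr$end_bp))
    path <- file.path(cfg$out_dir, "window_tree.nwk")
    ape::write.tree(tree, path)
    outs$window_tree <- path
  }
  outs
}

workflow_screen <- function(cfg, stage) {
  stopifnot(!is.null(cfg$inputs$hits))
  taxon_map <- if (!is.null(cfg$inputs$taxon_map))
    read_taxon_map(cfg$inputs$taxon_map) else NULL
  hits <- stage("read_hit_table", read_hit_table(cfg$inputs$hits, taxon_map))
  cc <- contamination_config(
    evalue_threshold = cfg$params$evalue %||% 1e-20,
    excluded_species = cfg$params$exclude_species %||% character())
  calls <- stage("classify_contaminants",
                 classify_contaminants(hits, cc,
                   best_hit_only = isTRUE(cfg$params$best_hit_only)))
  outs <- list(calls = write_tsv(calls, file.path(cfg$out_dir, "contaminant_calls.tsv")))
  if (!is.null(cfg$inputs$gene_positions)) {
    pos <- read_gene_positions(cfg$inputs$gene_positions)
    part <- stage("partition_by_scaffold",
                  partition_by_scaffold(calls, pos,
                    cfg$params$pseudo_chromosomes %||% character()))
    outs$partition <- write_tsv(
      data.frame(partition = c("on", "off"),
                 contaminants = c(part$on["contaminants"], part$off["contaminants"]),
                 total = c(part$on["total"], part$off["total"])),
      file.path(cfg$out_dir, "partition_summary.tsv"))
  }
  outs
}

workflow_families <- function(cfg, stage) {
  stopifnot(!is.null(cfg$inputs$focal), !is.null(cfg$inputs$pool))
  focal <- stage("family_counts",
                 family_counts(cfg$inputs$focal, label = "focal"))
  pool <- stage("family_counts", family_counts(cfg$inputs$pool, label = "pool"))
  res <- stage("family_enrichment_scan",
               family_enrichment_scan(focal, pool,
                 alpha = cfg$params$alpha %||% 0.01))
  outs <- list(enrichment = write_tsv(
    res, file.path(cfg$out_dir, "family_enrichment.tsv")))
  if (!is.null(cfg$inputs$gene2go)) {
    ann <- read_annotation_tsv(cfg$inputs$focal, c("gene_id", "family_id"))
    sig_fams <- res$family_id[res$significant]
    study <- unique(ann$gene_id[ann$family_id %in% sig_fams])
    population <- unique(ann$gene_id)
    go <- stage("go_enrichment",
                go_enrichment(study, population, cfg$inputs$gene2go,
                  alpha = cfg$params$alpha %||% 0.01))
    outs$go <- write_tsv(go, file.path(cfg$out_dir, "go_enrichment.tsv"))
  }
  outs
}
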