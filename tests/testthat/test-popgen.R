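toy_records <- function() {
  # hand-built record set with planted filter violations
  sites <- data.frame(
    chrom = "chr1",
    pos = c(100L, 203L, 500L, 600L, 700L, 200L),
    ref = c("A", "C", "G", "T", "A", "AT"),
    alt = c("T", "G", "A", "C", "G", "A"),
    qual = c(50, 50, 10, 50, 50, 99),
    is_indel = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  geno <- rbind(s1 = c(1L, 0L, 1L, 0L, NA, NA),
                s2 = c(0L, 1L, 2L, 1L, 1L, NA))
  depth <- rbind(s1 = c(20, 20, 20, 4, 20, NA),
                 s2 = c(20, 20, 20, 20, 20, NA))
  structure(list(sample_ids = c("s1", "s2"), sites = sites, geno = geno,
                 depth = depth, skip_log = c(multiallelic_snp = 0L)),
            class = "vcf_records")
}

test_that("variant filters drop planted violations exactly", {
  rec <- toy_records()
  gm <- apply_variant_filters(rec)
  # survivors: pos 100 only. 203 is within 5 bp of the indel span
  # [200, 201]; 500 fails QUAL; 600 fails depth; 700 has a missing call.
  expect_equal(gm$sites$pos, 100L)
  log <- attr(gm, "filter_log")
  expect_equal(log[["near_indel"]], 1)
  expect_equal(log[["low_qual"]], 1)
  expect_equal(log[["depth_out_of_range"]], 1)
  expect_equal(log[["missing_genotype"]], 1)
  expect_equal(log[["retained"]], 1)
})

test_that("an indel-adjacent SNP survives outside the 5 bp flank", {
  rec <- toy_records()
  rec$sites$pos[2] <- 207L  # indel span [200,201] + 5 -> cutoff 206
  gm <- apply_variant_filters(rec)
  expect_true(207L %in% gm$sites$pos)
})

test_that("filtering is idempotent", {
  sim <- simulate_two_pop_genotypes(n_per_pop = 2, sites_per_chromosome = 80,
                                    seed = 61)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(sim$gm, path, qual = 60,
            depth = matrix(20, nrow(sim$gm$geno), ncol(sim$gm$geno)))
  rec <- read_vcf_biallelic(path)
  once <- apply_variant_filters(rec)
  rec2 <- list(sample_ids = once$sample_ids,
               sites = cbind(once$sites, qual = 60, is_indel = FALSE),
               geno = once$geno,
               depth = matrix(20, nrow(once$geno), ncol(once$geno)),
               skip_log = c(multiallelic_snp = 0L))
  class(rec2) <- "vcf_records"
  twice <- apply_variant_filters(rec2)
  expect_equal(twice$geno, once$geno)
  expect_equal(twice$sites$pos, once$sites$pos)
})

test_that("global PCA separates simulated populations and sums to one", {
  sim <- simulate_two_pop_genotypes(n_per_pop = 3, chromosomes = "chr1",
                                    sites_per_chromosome = 3000,
                                    F_st = 0.2, seed = 62)
  p <- global_pca(sim$gm)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  pc1 <- p$scores[, 1]
  north <- pc1[sim$truth$populations == "north"]
  south <- pc1[sim$truth$populations == "south"]
  expect_true(max(north) < min(south) || max(south) < min(north))
  # identical samples land on the same score
  g2 <- sim$gm
  g2$geno[2, ] <- g2$geno[1, ]
  p2 <- global_pca(g2)
  expect_equal(p2$scores[1, 1], p2$scores[2, 1], tolerance = 1e-8)
})

test_that("local PCA flags thin windows and polarises against global PC1", {
  sim <- simulate_two_pop_genotypes(n_per_pop = 3, chromosomes = "chr1",
                                    chrom_length_bp = 1e6,
                                    sites_per_chromosome = 800, seed = 63)
  track <- local_pca(sim$gm, window_spec(100000L), min_sites = 10)
  expect_false(any(track$skipped))
  m <- track_scores <- as.matrix(
    track[, grep("^score\\.", names(track))])
  gl <- attr(track, "global_pc1")
  cors <- apply(m, 1, function(sc) suppressWarnings(cor(sc, gl)))
  expect_true(all(cors >= 0 | is.na(cors)))

  # a window beyond the last site is absent; a sparse matrix gets flags
  sparse <- simulate_two_pop_genotypes(n_per_pop = 3, chromosomes = "chr1",
                                       chrom_length_bp = 1e6,
                                       sites_per_chromosome = 30, seed = 64)
  tr2 <- local_pca(sparse$gm, window_spec(100000L), min_sites = 10)
  expect_true(any(tr2$skipped))
  expect_true(all(is.na(as.matrix(
    tr2[tr2$skipped, grep("^score\\.", names(tr2))]))))
})

test_that("hybrid index is 0 at the home centroid and 0.5 at the midpoint", {
  samples <- c("n1", "n2", "s1", "s2", "focal")
  track <- data.frame(chrom = "chr1", start = c(0, 1e5), end = c(1e5, 2e5),
                      n_sites = 50, skipped = FALSE)
  # home (south) centroid at 4, north centroid at -4
  track$score.n1 <- c(-5, -5); track$score.n2 <- c(-3, -3)
  track$score.s1 <- c(5, 5); track$score.s2 <- c(3, 3)
  track$score.focal <- c(4, 0)   # home centroid, then midpoint
  class(track) <- c("window_score_track", "data.frame")
  pops <- setNames(c("north", "north", "south", "south", "south"), samples)
  res <- window_assignment_score(track, pops, "focal")
  expect_equal(res$hybrid_index, c(0, 0.5))
})

test_that("planted introgression blocks shift the focal hybrid index", {
  blocks <- data.frame(sample = "south1", chrom = "chr1",
                       start_bp = 1e6, end_bp = 2e6, donor = "north",
                       stringsAsFactors = FALSE)
  sim <- simulate_two_pop_genotypes(n_per_pop = 3, chromosomes = "chr1",
                                    chrom_length_bp = 4e6,
                                    sites_per_chromosome = 4000,
                                    F_st = 0.2,
                                    introgression_blocks = blocks, seed = 65)
  track <- local_pca(sim$gm, window_spec(100000L), min_sites = 10)
  res <- window_assignment_score(track, sim$truth$populations, "south1")
  in_block <- res$start >= 1e6 & res$end <= 2e6
  covered <- !res$skipped & !is.na(res$hybrid_index)
  sens <- mean(res$hybrid_index[in_block & covered] >= 0.5)
  fpr <- mean(res$hybrid_index[!in_block & covered] >= 0.5)
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("observed heterozygosity covers the degenerate and invariance cases", {
  sites <- data.frame(chrom = rep(c("c1", "c2"), each = 3),
                      pos = rep(1:3, 2) * 10L, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  het <- genotype_matrix(matrix(1L, 4, 6), sites)
  expect_equal(observed_heterozygosity(het)$overall, 1)
  mono <- genotype_matrix(matrix(0L, 4, 6), sites)
  expect_equal(observed_heterozygosity(mono)$overall, 0)

  set.seed(66)
  g <- matrix(sample(0:2, 24, replace = TRUE), 4, 6)
  gm <- genotype_matrix(g, sites)
  shuffled <- genotype_matrix(g[c(3, 1, 4, 2), c(5, 3, 1, 6, 2, 4)],
                              sites[c(5, 3, 1, 6, 2, 4), ])
  expect_equal(observed_heterozygosity(gm)$overall,
               observed_heterozygosity(shuffled)$overall)
  expect_error(observed_heterozygosity(gm, chrom = "nope"), "empty")
})

test_that("pooled heterozygosity matches a direct-sampling Monte-Carlo oracle", {
  # Balding-Nichols draw: E[H_obs] estimated two independent ways
  set.seed(67)
  F <- 0.2; reps <- 30
  sim_means <- vapply(seq_len(reps), function(r) {
    s <- simulate_two_pop_genotypes(n_per_pop = 3, chromosomes = "c1",
                                    sites_per_chromosome = 400,
                                    F_st = F, seed = 6700 + r)
    observed_heterozygosity(s$gm)$overall
  }, numeric(1))
  # direct sampling from the same hierarchical model, no genotype matrix
  n_draw <- 60000
  p <- runif(n_draw, 0.05, 0.95)
  q <- rbeta(n_draw, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  direct <- mean(2 * q * (1 - q))
  se <- sd(sim_means) / sqrt(reps)
  expect_lt(abs(mean(sim_means) - direct), 3 * se + 0.01)
})

test_that("neighbor-joining window trees behave on degenerate and additive cases", {
  sites <- data.frame(chrom = "c1", pos = (1:10) * 100L, ref = "A", alt = "T",
                      stringsAsFactors = FALSE)
  same <- genotype_matrix(matrix(rep(c(0L, 1L), 5 * 4), 4, 10, byrow = TRUE),
                          sites, sample_ids = paste0("t", 1:4))
  tr <- window_tree(same)
  expect_s3_class(tr, "phylo")
  expect_equal(sum(tr$edge.length), 0)

  # additive 4-taxon matrix built from split-supporting sites:
  # nA=4, nB=2, nC=6, nD=8 private sites, nAB=10 sites splitting AB|CD
  blocks <- c(A = 4, B = 2, C = 6, D = 8, AB = 10)
  cols <- list()
  put <- function(rows, times) {
    for (i in seq_len(times)) {
      v <- rep(0L, 4); v[rows] <- 2L
      cols[[length(cols) + 1L]] <<- v
    }
  }
  put(1, blocks["A"]); put(2, blocks["B"]); put(3, blocks["C"])
  put(4, blocks["D"]); put(1:2, blocks["AB"])
  g <- do.call(cbind, cols)
  M <- ncol(g)
  sites2 <- data.frame(chrom = "c1", pos = seq_len(M) * 10L, ref = "A",
                       alt = "T", stringsAsFactors = FALSE)
  gm <- genotype_matrix(g, sites2, sample_ids = c("A", "B", "C", "D"))
  tr2 <- window_tree(gm)
  # topology: AB|CD split present
  split_ok <- ape::is.monophyletic(ape::unroot(tr2), c("A", "B"))
  expect_true(split_ok)
  # branch lengths recovered exactly (allele-sharing distance = n_i / M)
  tip_len <- setNames(tr2$edge.length[tr2$edge[, 2] <= 4],
                      tr2$tip.label[tr2$edge[tr2$edge[, 2] <= 4, 2]])
  expect_equal(tip_len[c("A", "B", "C", "D")],
               c(A = 4, B = 2, C = 6, D = 8) / M, tolerance = 1e-9)
  internal <- tr2$edge.length[tr2$edge[, 2] > 4]
  expect_equal(internal, blocks[["AB"]] / M, tolerance = 1e-9)
})

test_that("diverged populations come out monophyletic in window trees", {
  sim <- simulate_two_pop_genotypes(n_per_pop = 3, chromosomes = "c1",
                                    sites_per_chromosome = 2000,
                                    F_st = 0.3, seed = 68)
  tr <- window_tree(sim$gm, "c1")
  north <- names(sim$truth$populations)[sim$truth$populations == "north"]
  expect_true(ape::is.monophyletic(tr, north))
})

test_that("the barrier chromosome depresses heterozygosity", {
  low <- 0
  for (r in 1:20) {
    sim <- simulate_two_pop_genotypes(
      n_per_pop = 3, chromosomes = paste0("chr", 1:4),
      sites_per_chromosome = 300, F_st = 0.2,
      barrier_chrom = "chr4", barrier_F = 0.6, seed = 6900 + r)
    het <- observed_heterozygosity(sim$gm)$per_chromosome
    if (names(which.min(het)) == "chr4") low <- low + 1
  }
  expect_gte(low / 20, 0.95)
})
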