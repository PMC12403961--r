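test_that("amino-acid frequencies are normalised and X-masked", {
  f <- aa_frequency_vector("AAAA")
  expect_equal(unname(f["A"]), 1)
  expect_equal(sum(f), 1)
  expect_equal(unname(aa_frequency_vector("ACDEFGHIKLMNPQRSTVWY")),
               rep(0.05, 20))
  # X is excluded from the denominator
  expect_equal(unname(aa_frequency_vector("AXAX")["A"]), 1)
  expect_error(aa_frequency_vector("XXX"), "only X")
})

test_that("frequency of a concatenation is the length-weighted mean", {
  set.seed(31)
  for (rep in 1:10) {
    s <- random_protein(sample(10:50, 1))
    t <- random_protein(sample(10:50, 1))
    lhs <- aa_frequency_vector(paste0(s, t))
    rhs <- (nchar(s) * aa_frequency_vector(s) +
            nchar(t) * aa_frequency_vector(t)) / (nchar(s) + nchar(t))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("composition matrix equals plain per-protein mean for identical proteomes", {
  set.seed(32)
  seqs <- setNames(vapply(rep(60, 8), random_protein, character(1)),
                   sprintf("g%02d", 1:8))
  a <- sequence_set(seqs, "spA")
  b <- sequence_set(setNames(seqs, paste0("b_", names(seqs))), "spB")
  rb <- reciprocal_best_hits(a, b)
  mat <- species_composition_matrix(list(spA = a, spB = b), list(rb))
  plain <- rowMeans(vapply(seqs, aa_frequency_vector, numeric(20)))
  expect_equal(unname(mat["spA", ]), unname(plain), tolerance = 1e-12)
  expect_equal(unname(mat["spB", ]), unname(plain), tolerance = 1e-12)
  expect_equal(unname(rowSums(mat)), c(1, 1), tolerance = 1e-9)
})

test_that("species order only permutes composition rows", {
  sim <- simulate_proteome_family(n_species = 3, n_genes = 12, mean_len = 80,
                                  divergence = 0.1, seed = 33)
  pr <- sim$proteomes
  pairs <- list(reciprocal_best_hits(pr[[1]], pr[[2]]),
                reciprocal_best_hits(pr[[1]], pr[[3]]),
                reciprocal_best_hits(pr[[2]], pr[[3]]))
  m1 <- species_composition_matrix(pr, pairs)
  m2 <- species_composition_matrix(pr[c(3, 1, 2)], pairs)
  expect_equal(m1[rownames(m2), ], m2, tolerance = 1e-12)
  expect_equal(as.numeric(dist(m1)), as.numeric(dist(m2[rownames(m1), ])),
               tolerance = 1e-12)
})

test_that("a planted GC-bias gradient shifts GARP up and YFINK down", {
  biases <- c(-2, -1, 0, 1, 2)
  sim <- simulate_proteome_family(n_species = 5, n_genes = 30, mean_len = 120,
                                  divergence = 0.4, gc_bias = biases,
                                  seed = 34)
  pr <- sim$proteomes
  pairs <- list()
  for (i in 1:4) for (j in (i + 1):5)
    pairs[[length(pairs) + 1]] <- reciprocal_best_hits(pr[[i]], pr[[j]])
  mat <- species_composition_matrix(pr, pairs)
  garp <- rowSums(mat[, c("G", "A", "R", "P")])
  yfink <- rowSums(mat[, c("Y", "F", "I", "N", "K")])
  expect_true(all(diff(garp) > 0))
  expect_true(all(diff(yfink) < 0))
})

test_that("PCA handles the textbook cases with a fixed sign convention", {
  # two points: PC1 explains everything
  two <- pca(rbind(c(0, 0), c(1, 2)))
  expect_equal(two$explained[1], 1)
  # duplicated rows: defined zero result
  const <- pca(rbind(c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(const$scores == 0))
  expect_true(all(const$explained == 0))
  # sign convention: largest-magnitude loading entry positive
  set.seed(35)
  x <- matrix(rnorm(60), 10, 6)
  p <- pca(x)
  for (k in seq_along(p$explained))
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  expect_true(all(diff(p$explained) <= 1e-12))
})

test_that("all components reconstruct the centered matrix", {
  set.seed(36)
  x <- matrix(rnorm(48), 8, 6)
  p <- pca(x)
  recon <- p$scores %*% t(p$loadings)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(recon, centered, tolerance = 1e-9, ignore_attr = TRUE)
  # scores are mutually orthogonal
  cross <- crossprod(p$scores)
  expect_equal(cross[upper.tri(cross)], rep(0, sum(upper.tri(cross))),
               tolerance = 1e-9)
})

test_that("tube-composition screen ranks by Euclidean distance on S/G/A", {
  set.seed(37)
  # a protein hitting the tube target exactly: 250 S, 206 G, 118 A, rest V
  exact <- paste(c(rep("S", 250), rep("G", 206), rep("A", 118),
                   rep("V", 426)), collapse = "")
  seqs <- c(hit = exact,
            setNames(vapply(rep(200, 199), random_protein, character(1)),
                     sprintf("r%03d", 1:199)))
  prot <- sequence_set(seqs, "screen")
  ranked <- target_distance_screen(prot)
  expect_equal(ranked$gene_id[1], "hit")
  expect_equal(ranked$distance[1], 0, tolerance = 1e-12)
  # brute-force recomputation of every distance and of the ordering
  target <- c(S = 0.25, G = 0.206, A = 0.118)
  brute <- vapply(seqs, function(s) {
    f <- aa_frequency_vector(s)
    sqrt(sum((f[names(target)] - target)^2))
  }, numeric(1))
  brute <- brute[order(brute, names(brute))]
  expect_equal(ranked$gene_id, names(brute))
  expect_equal(ranked$distance, unname(brute), tolerance = 1e-12)
})

test_that("genome windows report GC and per-bp gene coverage", {
  genome <- sequence_set(
    c(chrA = strrep("GC", 500), chrB = strrep("AT", 500)),
    species_label = "toy", alphabet = "dna")
  pos <- data.frame(gene_id = c("g1", "g2"), chrom = c("chrA", "chrB"),
                    start = c(0L, 100L), end = c(200L, 300L), strand = "+",
                    stringsAsFactors = FALSE)
  win <- genome_windows(genome, pos, window_bp = 200L)
  a1 <- win[win$chrom == "chrA" & win$start == 0, ]
  expect_equal(a1$gc, 1.0)
  expect_equal(a1$gene_coverage_pct, 100)
  expect_equal(win$gc[win$chrom == "chrB"], rep(0, 5))

  # random interval sets against the per-bp marking oracle
  set.seed(38)
  starts <- sort(sample(0:900, 12))
  ends <- pmin(starts + sample(10:120, 12, replace = TRUE), 1000L)
  rpos <- data.frame(gene_id = sprintf("g%02d", 1:12), chrom = "chrA",
                     start = starts, end = ends, strand = "+",
                     stringsAsFactors = FALSE)
  win2 <- genome_windows(genome, rpos, window_bp = 300L)
  for (r in which(win2$chrom == "chrA")) {
    expected <- 100 * coverage_oracle(starts, ends, win2$start[r],
                                      win2$end[r]) /
      (win2$end[r] - win2$start[r])
    expect_equal(win2$gene_coverage_pct[r], expected, tolerance = 1e-9)
  }
})

test_that("codon GC table puts YFINK lowest and GARP highest", {
  gc <- amino_acid_gc_table()
  expect_true(all(gc >= 0 & gc <= 1))
  low5 <- names(sort(gc))[1:5]
  expect_setequal(low5, c("Y", "F", "I", "N", "K"))
  high4 <- names(sort(gc, decreasing = TRUE))[1:4]
  expect_setequal(high4, c("G", "A", "R", "P"))
})

test_that("PC1 loadings track codon GC on a GC-gradient proteome set", {
  biases <- seq(-2, 2, length.out = 6)
  sim <- simulate_proteome_family(n_species = 6, n_genes = 30, mean_len = 150,
                                  divergence = 0.5, gc_bias = biases,
                                  seed = 39)
  pr <- sim$proteomes
  pairs <- list()
  for (i in 1:5) for (j in (i + 1):6)
    pairs[[length(pairs) + 1]] <- reciprocal_best_hits(pr[[i]], pr[[j]])
  mat <- species_composition_matrix(pr, pairs)
  p <- pca(mat)
  r <- cor(p$loadings[, 1], amino_acid_gc_table()[rownames(p$loadings)])
  expect_gte(abs(r), 0.8)
})
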