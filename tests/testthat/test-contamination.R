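make_hits <- function(query, taxa, evalues, species = NULL) {
  if (length(taxa) == 0)
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      subject_species = character(),
                      subject_taxon_group = character(),
                      stringsAsFactors = FALSE))
  data.frame(query_id = query, subject_id = paste0("s", seq_along(taxa)),
             evalue = evalues, bitscore = 100,
             subject_species = species %||% paste0("sp", seq_along(taxa)),
             subject_taxon_group = taxa, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the decision rule is forced on the canonical cases", {
  # one significant Bacteria hit, no Metazoa -> contaminant
  h <- make_hits("q", "Bacteria", 1e-30)
  expect_true(classify_contaminants(h)$is_contaminant)
  # a significant Metazoa hit rescues
  h <- make_hits(c("q", "q"), c("Bacteria", "Metazoa"), c(1e-30, 1e-25))
  expect_false(classify_contaminants(h)$is_contaminant)
  # Bacteria hit above the threshold is not significant
  h <- make_hits("q", "Bacteria", 1e-15)
  expect_false(classify_contaminants(h)$is_contaminant)
  # boundary: e-value exactly 1e-20 is NOT significant (strict inequality)
  h <- make_hits("q", "Bacteria", 1e-20)
  expect_false(classify_contaminants(h)$is_contaminant)
  # no hits at all -> non-contaminant
  calls <- classify_contaminants(make_hits(character(), character(),
                                           numeric()),
                                 queries = "lonely")
  expect_false(calls$is_contaminant)
})

test_that("classifier equals exhaustive enumeration over hit patterns", {
  # all combinations of (taxon x significance) states for k = 1..3 hits
  states <- expand.grid(taxon = c("Metazoa", "Bacteria", "Other"),
                        sig = c(TRUE, FALSE), stringsAsFactors = FALSE)
  ev <- function(sig) ifelse(sig, 1e-40, 1e-10)
  rows <- list(); truth <- logical(); qid <- 0
  for (k in 1:3) {
    combos <- do.call(expand.grid, rep(list(seq_len(nrow(states))), k))
    for (r in seq_len(nrow(combos))) {
      qid <- qid + 1
      q <- sprintf("q%04d", qid)
      st <- states[as.integer(combos[r, ]), , drop = FALSE]
      rows[[qid]] <- make_hits(rep(q, k), st$taxon, ev(st$sig))
      truth[q] <- contamination_oracle(st$taxon, ev(st$sig))
    }
  }
  hits <- do.call(rbind, rows)
  calls <- classify_contaminants(hits, queries = names(truth))
  expect_equal(setNames(calls$is_contaminant, calls$query_id), truth)
  # invariant recorded in the calls themselves
  expect_true(all(!calls$is_contaminant |
                  (calls$n_significant_metazoan == 0 &
                   calls$n_significant_bacterial >= 1)))
})

test_that("adding hits moves calls monotonically", {
  base <- make_hits("q", "Bacteria", 1e-30)
  expect_true(classify_contaminants(base)$is_contaminant)
  # adding a significant Metazoa hit can only flip contaminant -> clean
  more <- rbind(base, make_hits("q", "Metazoa", 1e-30))
  expect_false(classify_contaminants(more)$is_contaminant)
  # adding a significant Bacteria hit to a clean no-Metazoa query flips it
  clean <- make_hits("q", "Other", 1e-30)
  expect_false(classify_contaminants(clean)$is_contaminant)
  flipped <- rbind(clean, make_hits("q", "Bacteria", 1e-30))
  expect_true(classify_contaminants(flipped)$is_contaminant)
})

test_that("hits to excluded species are removed before classification", {
  h <- make_hits(c("q", "q"), c("Metazoa", "Bacteria"), c(1e-30, 1e-30),
                 species = c("self_species", "some_bact"))
  cfg <- contamination_config(excluded_species = "self_species")
  expect_true(classify_contaminants(h, cfg)$is_contaminant)
  expect_false(classify_contaminants(h)$is_contaminant)
})

test_that("planted contaminants are recovered exactly with separated e-values", {
  sim <- simulate_hit_table(n_queries = 120, contaminant_fraction = 0.3,
                            seed = 46)
  calls <- classify_contaminants(sim$hits, queries = names(sim$truth))
  expect_equal(setNames(calls$is_contaminant, calls$query_id), sim$truth)
  # best-hit-only mode agrees when e-values are well separated
  calls2 <- classify_contaminants(sim$hits, queries = names(sim$truth),
                                  best_hit_only = TRUE)
  sens <- mean(calls2$is_contaminant[sim$truth[calls2$query_id]])
  expect_equal(sens, 1)
})

test_that("scaffold partition counts conserve and match hand enumeration", {
  calls <- data.frame(
    query_id = sprintf("g%02d", 1:10),
    is_contaminant = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                       FALSE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  pos <- make_positions(calls$query_id,
                        chrom = c("c1", "c1", "c1", "scaf9", "scaf9",
                                  "c2", "scaf7", "c2", "c1", "scaf7"))
  part <- partition_by_scaffold(calls, pos, c("c1", "c2"))
  # hand check: on-chromosome genes 1,2,3,6,8,9 of which 1,2,9 contaminate
  expect_equal(part$on, c(contaminants = 3, total = 6))
  expect_equal(part$off, c(contaminants = 2, total = 4))
  expect_equal(part$on[["total"]] + part$off[["total"]], nrow(calls))

  # all genes on pseudo-chromosomes -> off partition empty
  all_on <- partition_by_scaffold(calls, pos,
                                  unique(pos$chrom))
  expect_equal(all_on$off, c(contaminants = 0, total = 0))

  expect_error(
    partition_by_scaffold(calls, pos[-1, ], "c1"),
    "g01")
})
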