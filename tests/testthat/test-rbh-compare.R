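test_that("best hits maximize bitscore with deterministic tie-breaks", {
  h <- function(q, s, bits, e) {
    data.frame(qseqid = q, sseqid = s, pident = 90, length = 100L,
               mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 100L,
               sstart = 1L, send = 100L, evalue = e, bitscore = bits,
               stringsAsFactors = FALSE)
  }
  expect_identical(best_hits(h("q1", "s1", 200, 1e-50))$subject, "s1")
  two <- rbind(h("q1", "s1", 200, 1e-50), h("q1", "s2", 150, 1e-60))
  expect_identical(best_hits(two)$subject, "s1")
  tie <- rbind(h("q1", "s1", 200, 1e-40), h("q1", "s2", 200, 1e-60))
  expect_identical(best_hits(tie)$subject, "s2")
  tie2 <- rbind(h("q1", "s2", 200, 1e-40), h("q1", "s1", 200, 1e-40))
  expect_identical(best_hits(tie2)$subject, "s1")
  # strict e-value cutoff; multiple HSPs collapse to the best one
  expect_identical(nrow(best_hits(h("q1", "s1", 200, 1e-15))), 0L)
  hsp <- rbind(h("q1", "s1", 90, 1e-20), h("q1", "s1", 210, 1e-45),
               h("q1", "s2", 200, 1e-50))
  bh <- best_hits(hsp)
  expect_identical(bh$subject, "s1")
  expect_equal(bh$bitscore, 210)
})

test_that("reciprocal pairs require mutual best hits", {
  bh <- function(q, s, bits = 100, e = 1e-30) {
    data.frame(query = q, subject = s, bitscore = bits, evalue = e,
               stringsAsFactors = FALSE)
  }
  expect_identical(nrow(reciprocal_pairs(bh("a1", "b1"), bh("b1", "a1"))),
                   1L)
  expect_identical(nrow(reciprocal_pairs(bh("a1", "b1"), bh("b1", "a2"))),
                   0L)
})

test_that("RBH pair sets equal the exhaustive oracle on random instances", {
  set.seed(2024)
  for (rep in 1:50) {
    n_q <- sample(3:30, 1); n_s <- sample(3:30, 1)
    ab <- random_hit_table(n_q, n_s, sample(5:60, 1), "a", "b")
    ba <- random_hit_table(n_s, n_q, sample(5:60, 1), "b", "a")
    got <- reciprocal_pairs(best_hits(ab), best_hits(ba), "A", "B")
    want <- oracle_rbh(ab, ba)
    expect_identical(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_identical(got$protein_a, unname(want[, 1L]))
      expect_identical(got$protein_b, unname(want[, 2L]))
    }
  }
})

test_that("RBH output is symmetric in genome order and bounded in size", {
  set.seed(99)
  ab <- random_hit_table(15, 15, 40, "a", "b")
  ba <- random_hit_table(15, 15, 40, "b", "a")
  bh_ab <- best_hits(ab); bh_ba <- best_hits(ba)
  p1 <- reciprocal_pairs(bh_ab, bh_ba, "VA", "VB")
  p2 <- reciprocal_pairs(bh_ba, bh_ab, "VB", "VA")
  expect_equal(p1, p2)
  expect_lte(nrow(p1), min(nrow(bh_ab), nrow(bh_ba)))
  kept <- packaged_rbh(p1, p1$protein_a[1], p1$protein_b[1])
  expect_lte(nrow(kept), nrow(p1))
})

test_that("planted orthologs are recovered with perfect recall and precision", {
  sim <- simulate_virus_proteomes(n_viruses = 5, seed = 31)
  tabs <- simulate_hit_tables(sim, noise_sd = 0, decoys_per_pair = 0,
                              seed = 31)
  pairs <- all_reciprocal_pairs(tabs, names(sim$proteomes))
  truth_pairs <- do.call(rbind, lapply(split(sim$truth,
                                             sim$truth$group_id),
    function(g) paste(g$protein_id[order(g$virus)], collapse = "+")))
  got_pairs <- paste(pairs$protein_a, pairs$protein_b, sep = "+")
  expect_setequal(got_pairs, as.vector(truth_pairs))

  # packaged restriction recovers exactly the planted packaged pairs
  kept <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    packaged_rbh(pairs[i, ], sim$packaged[[pairs$virus_a[i]]],
                 sim$packaged[[pairs$virus_b[i]]])
  }))
  truth_packaged <- vapply(split(sim$truth, sim$truth$group_id),
                           function(g) all(g$packaged), logical(1))
  expect_identical(nrow(kept), sum(truth_packaged))
})

test_that("decoy scores above the match mean degrade RBH recall", {
  sim <- simulate_virus_proteomes(n_viruses = 4, seed = 8)
  recall <- function(decoy_mean) {
    tabs <- simulate_hit_tables(sim, match_bits_per_aa = 2,
                                decoy_bits_mean = decoy_mean,
                                noise_sd = 0, decoys_per_pair = 25,
                                seed = 8)
    pairs <- all_reciprocal_pairs(tabs, names(sim$proteomes))
    n_truth <- length(unique(sim$truth$group_id))
    got <- paste(pairs$protein_a, pairs$protein_b, sep = "+")
    truth <- vapply(split(sim$truth, sim$truth$group_id), function(g) {
      paste(g$protein_id[order(g$virus)], collapse = "+")
    }, character(1))
    sum(truth %in% got) / n_truth
  }
  expect_identical(recall(60), 1)   # decoys far below match scores
  expect_lt(recall(5000), 1)        # decoys dominate -> recall degrades
})

test_that("within/between family tallies and shared fractions", {
  pairs <- data.frame(virus_a = c("A", "A", "B"),
                      virus_b = c("B", "C", "C"),
                      protein_a = c("a1", "a2", "b1"),
                      protein_b = c("b1", "c1", "c2"),
                      stringsAsFactors = FALSE)
  fam <- c(A = "F1", B = "F1", C = "F2")
  tally <- within_between_tally(pairs, fam)
  expect_identical(tally$within, 1L)
  expect_identical(tally$between, 2L)
  expect_error(within_between_tally(pairs, fam[-3]), "family")

  counts <- matrix(c(0, 5, 5, 0), 2, 2,
                   dimnames = list(c("V", "W"), c("V", "W")))
  sf <- shared_fraction_matrix(counts, c(V = 50, W = 20))
  expect_equal(sf["V", "W"], 10)
  expect_equal(sf["W", "V"], 25)
  expect_equal(diag(sf), c(V = 100, W = 100))
  expect_error(shared_fraction_matrix(counts, c(V = 50, W = 0)),
               "positive")
})

test_that("ortholog components match a union-find oracle on random graphs", {
  # chain merges transitively; disjoint pairs stay apart
  chain <- data.frame(virus_a = c("A", "B"), virus_b = c("B", "C"),
                      protein_a = c("a1", "b1"), protein_b = c("b1", "c1"),
                      stringsAsFactors = FALSE)
  cl <- cluster_components(chain)
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_identical(nrow(cl), 3L)

  set.seed(4)
  for (rep in 1:10) {
    n <- 25L
    edges <- data.frame(
      virus_a = "X", virus_b = "Y",
      protein_a = paste0("n", sample.int(n, 30, replace = TRUE)),
      protein_b = paste0("m", sample.int(n, 30, replace = TRUE)),
      stringsAsFactors = FALSE)
    cl <- cluster_components(edges)
    # union-find oracle
    parent <- seq_len(2 * n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (e in seq_len(nrow(edges))) {
      i <- as.integer(sub("n", "", edges$protein_a[e]))
      j <- n + as.integer(sub("m", "", edges$protein_b[e]))
      parent[find(i)] <- find(j)
    }
    node_of <- function(v, p) {
      if (v == "X") as.integer(sub("n", "", p)) else
        n + as.integer(sub("m", "", p))
    }
    roots <- vapply(seq_len(nrow(cl)), function(r) {
      find(node_of(cl$virus[r], cl$protein[r]))
    }, integer(1))
    # same partition: cluster ids and oracle roots induce the same blocks
    expect_identical(
      unname(split(seq_len(nrow(cl)), cl$cluster_id)[
        order(vapply(split(seq_len(nrow(cl)), cl$cluster_id), min, 1L))]),
      unname(split(seq_len(nrow(cl)), roots)[
        order(vapply(split(seq_len(nrow(cl)), roots), min, 1L))]))
  }
})
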