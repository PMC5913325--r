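make_locus <- function(n, seed, shuffle = FALSE, identity = 0.8) {
  set.seed(seed)
  prots <- vapply(seq_len(n), function(i) random_aa_str(100), "")
  starts <- cumsum(c(0L, rep(1500L, n - 1L)))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  ref <- gene_table(data.frame(id = sprintf("r%d", 1:n), chrom = "R",
                               start = starts, end = starts + 300L,
                               strand = strands, protein = prots,
                               stringsAsFactors = FALSE))
  ord <- if (shuffle) sample(n) else seq_len(n)
  qprots <- vapply(seq_len(n), function(i)
    mutate_protein(prots[ord[i]], identity, seed = seed + i), "")
  qry <- gene_table(data.frame(id = sprintf("q%d", 1:n), chrom = "Q",
                               start = starts, end = starts + 300L,
                               strand = strands[ord], protein = qprots,
                               stringsAsFactors = FALSE))
  list(query = qry, reference = ref, order = ord)
}

test_that("identical proteomes pair perfectly; non-matching genes stay unpaired", {
  loc <- make_locus(6, seed = 71, identity = 1)
  pairs <- assign_orthologs(loc$query, loc$reference)
  expect_equal(nrow(pairs), 6)
  expect_identical(sub("^q", "r", pairs$query_gene), pairs$reference_gene)
  expect_true(all(pairs$identity == 100))
  # a query gene with no reference hit above threshold stays unpaired
  loc$query$protein[1] <- strrep("W", 100)
  pairs2 <- assign_orthologs(loc$query, loc$reference)
  expect_false("q1" %in% pairs2$query_gene)
  # empty tables
  expect_equal(nrow(assign_orthologs(loc$query[0, ], loc$reference)), 0)
})

test_that("reciprocal best hits match the brute-force all-vs-all oracle", {
  loc <- make_locus(6, seed = 72)
  # plant a paralog pair: q2 becomes a near-copy of r3's protein
  loc$query$protein[2] <- mutate_protein(loc$reference$protein[3], 0.9,
                                         seed = 99)
  pairs <- assign_orthologs(loc$query, loc$reference)
  scheme <- scoring_scheme("protein")
  score1 <- function(a, b) {
    h <- search_hsps(a, c(x = b), scheme)
    if (nrow(h) == 0) -Inf else h$raw_score[1]
  }
  S <- outer(seq_len(6), seq_len(6), Vectorize(function(i, j)
    score1(loc$query$protein[i], loc$reference$protein[j])))
  expected <- list()
  for (i in 1:6) {
    j <- which.max(S[i, ])
    if (is.finite(S[i, j]) && which.max(S[, j]) == i)
      expected[[length(expected) + 1]] <- c(loc$query$id[i],
                                            loc$reference$id[j])
  }
  exp_df <- do.call(rbind, expected)
  expect_setequal(paste(pairs$query_gene, pairs$reference_gene),
                  paste(exp_df[, 1], exp_df[, 2]))
  # RBH symmetry: swapping the tables transposes the pairing
  rev_pairs <- assign_orthologs(loc$reference, loc$query)
  expect_setequal(paste(pairs$query_gene, pairs$reference_gene),
                  paste(rev_pairs$reference_gene, rev_pairs$query_gene))
  expect_lte(nrow(pairs), 6)
})

test_that("order concordance captures identical, reversed and trivial layouts", {
  loc <- make_locus(10, seed = 73, identity = 0.85)
  pairs <- assign_orthologs(loc$query, loc$reference)
  res <- compare_order(pairs, loc$query, loc$reference)
  expect_equal(res$shared_count, nrow(pairs))
  expect_equal(res$order_concordance, 1.0)
  expect_equal(res$orientation_agreement, 1.0)
  # fully reversed query locus: concordance -1, flip-adjusted view reported
  qrev <- loc$query
  qrev$start <- rev(qrev$start)
  qrev$end <- qrev$start + 300L
  res_rev <- compare_order(pairs, qrev, loc$reference)
  expect_equal(res_rev$order_concordance, -1.0)
  expect_equal(res_rev$flip_adjusted$order_concordance, 1.0)
  # single pair: concordance undefined
  res1 <- compare_order(pairs[1, ], loc$query, loc$reference)
  expect_true(is.na(res1$order_concordance))
})
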