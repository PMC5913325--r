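test_that("k-mer recruitment matches the brute-force set-intersection oracle", {
  set.seed(21)
  bait <- random_dna_str(400, 0.5)
  mk_read <- function() {
    if (runif(1) < 0.5) {
      st <- sample(1:300, 1)
      r <- substring(bait, st, st + 99)
      if (runif(1) < 0.5) r <- rc_oracle(r)
      r
    } else random_dna_str(100)
  }
  reads <- read_set(sprintf("r%04d", 1:300),
                    vapply(1:300, function(i) mk_read(), ""))
  got <- recruit_reads(bait, reads, seed_k = 21, min_shared = 2)
  expect_setequal(got$id, recruit_oracle(bait, reads, 21, 2))
  # identifiers preserved, sequences oriented to the bait strand
  expect_true(all(got$id %in% reads$id))
  for (i in seq_len(nrow(got))) {
    orig <- reads$seq[reads$id == got$id[i]]
    expect_true(got$seq[i] == orig || got$seq[i] == rc_oracle(orig))
  }
})

test_that("greedy assembly merges overlaps and leaves disjoint reads apart", {
  a <- random_dna_str(60); b <- random_dna_str(60)
  o <- 25
  r1 <- paste0(a, substring(b, 1, o))
  r2 <- b
  ct <- assemble_greedy(read_set(c("r1", "r2"), c(r1, r2)), min_overlap = 20)
  expect_length(ct, 1)
  expect_equal(nchar(ct[[1]]$sequence), nchar(r1) + nchar(r2) - o)
  expect_identical(ct[[1]]$sequence, paste0(a, b))
  expect_setequal(ct[[1]]$read_ids, c("r1", "r2"))
  # support counts: o positions covered twice
  expect_equal(sum(ct[[1]]$support == 2), o)
  # disjoint reads: one contig per read
  ct2 <- assemble_greedy(read_set(c("x", "y"),
                                  c(random_dna_str(50), random_dna_str(50))),
                         min_overlap = 20)
  expect_length(ct2, 2)
  expect_length(assemble_greedy(read_set(character(0), character(0))), 0)
})

test_that("error-free tiling reads reconstruct the planted sequence exactly", {
  set.seed(22)
  truth <- random_dna_str(300, 0.55)
  starts <- seq(1, 251, by = 10)
  reads <- read_set(sprintf("r%03d", seq_along(starts)),
                    substring(truth, starts, starts + 49))
  ct <- assemble_greedy(reads, min_overlap = 25)
  expect_length(ct, 1)
  expect_identical(ct[[1]]$sequence, truth)
})

test_that("consensus takes the majority base and resolves ties alphabetically", {
  base <- random_dna_str(80, 0.5)
  mut <- base
  substring(mut, 40, 40) <- if (substring(base, 40, 40) == "A") "C" else "A"
  # two votes for the original against one mutated copy
  ct <- assemble_greedy(read_set(c("a", "b", "c"), c(base, base, mut)),
                        min_overlap = 25)
  expect_length(ct, 1)
  expect_identical(ct[[1]]$sequence, base)
  # 1-1 tie resolves to the alphabetically first base
  ct2 <- assemble_greedy(read_set(c("a", "b"), c(base, mut)), min_overlap = 25)
  tie_base <- min(substring(base, 40, 40), substring(mut, 40, 40))
  expect_identical(substring(ct2[[1]]$sequence, 40, 40), tie_base)
})

test_that("recovery completes on clean data and recruitment grows monotonically", {
  ref <- make_reference(gene_spec(), seed = 31)
  reads <- simulate_reads(ref$transcript,
                          sim_config(depth = 60, error_rate = 0, seed = 32))
  bait <- mutate_protein(ref$protein, 0.7, seed = 33)
  rec <- iterate_recovery(bait, reads)
  expect_identical(rec$state$status, "orf_complete")
  expect_true(grepl(ref$cds, rec$contig$sequence, fixed = TRUE))
  expect_identical(rec$annotation$protein, ref$protein)
  expect_false(is.unsorted(rec$state$log$n_recruited))
  # determinism of the whole loop
  rec2 <- iterate_recovery(bait, reads)
  expect_identical(rec$contig$sequence, rec2$contig$sequence)
  expect_identical(rec$state$log, rec2$state$log)
})

test_that("degenerate recovery inputs give the documented terminal states", {
  ref <- make_reference(gene_spec(cds_length = 300, n_exons = 1,
                                  intron_lengths = integer(0)), seed = 34)
  reads <- simulate_reads(ref$transcript,
                          sim_config(depth = 20, error_rate = 0, seed = 35))
  # max_rounds = 0 returns immediately
  r0 <- iterate_recovery("MKWVTFISLLFLFSSAYS", reads,
                         recovery_params(max_rounds = 0))
  expect_identical(r0$state$status, "max_rounds")
  # a bait with no similarity stalls in round 1 with an empty result
  r1 <- iterate_recovery(strrep("W", 60), reads)
  expect_identical(r1$state$status, "stalled")
  expect_equal(r1$state$round, 1)
  expect_null(r1$contig)
})

test_that("starved datasets stall while deep datasets complete under strong bias", {
  ref <- make_reference(gene_spec(), seed = 36)
  bait <- mutate_protein(ref$protein, 0.7, seed = 37)
  bias <- bias_model(lambda_bias = 8)
  shallow <- simulate_reads(ref$transcript,
                            sim_config(depth = 5, error_rate = 0.005, seed = 38),
                            bias)
  deep <- simulate_reads(ref$transcript,
                         sim_config(depth = 200, error_rate = 0.005, seed = 38),
                         bias)
  r_sh <- iterate_recovery(bait, shallow)
  r_dp <- iterate_recovery(bait, deep)
  expect_false(r_sh$state$status == "orf_complete")
  expect_identical(r_dp$state$status, "orf_complete")
  expect_true(grepl(ref$cds, r_dp$contig$sequence, fixed = TRUE))
})
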