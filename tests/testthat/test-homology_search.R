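test_that("six-frame translation follows the standard code and frame geometry", {
  tr <- translate6("ATGAAATAA")
  expect_identical(tr[["+1"]], "MK*")
  s <- "ATGCCGTTANGG"
  tr <- translate6(s)
  for (f in 1:3)
    expect_equal(nchar(tr[[paste0("+", f)]]), (nchar(s) - f + 1) %/% 3)
  expect_identical(unname(translate6("")), rep("", 6))
})

test_that("reverse-complementing the input swaps +/- frames; frames match a codon-loop oracle", {
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna_str(sample(30:90, 1))
    tr <- translate6(s)
    # against the naive per-codon oracle
    expect_identical(tr[["+1"]], translate_oracle(s, 1))
    expect_identical(tr[["+2"]], translate_oracle(s, 2))
    expect_identical(tr[["-1"]], translate_oracle(rc_oracle(s), 1))
    # frame permutation under reverse complement
    trc <- translate6(rc_oracle(s))
    for (f in 1:3) {
      expect_identical(trc[[paste0("+", f)]], tr[[paste0("-", f)]])
      expect_identical(trc[[paste0("-", f)]], tr[[paste0("+", f)]])
    }
  }
})

test_that("search finds exact substrings at 100% identity and respects seeds", {
  set.seed(12)
  bait <- random_aa_str(50)
  target <- paste0(random_aa_str(20), bait, random_aa_str(15))
  h <- search_hsps(bait, c(t1 = target))
  expect_equal(nrow(h), 1)
  expect_equal(h$percent_identity, 100)
  expect_equal(h$query_end - h$query_start, 50)
  expect_equal(h$subject_start, 20)
  # no shared seed k-mer => empty result
  h0 <- search_hsps(strrep("W", 30), c(t1 = strrep("A", 60)))
  expect_equal(nrow(h0), 0)
  expect_error(search_hsps("ACGT", c(t1 = "MKWV"), scoring_scheme("dna")),
               "alphabet mismatch")
})

test_that("seeded search score equals exhaustive Smith-Waterman on seeded pairs", {
  set.seed(13)
  scheme <- scoring_scheme("protein", min_score = 1)
  n_checked <- 0
  for (i in 1:60) {
    pr <- seeded_pair()
    h <- search_hsps(pr$bait, c(t = pr$target), scheme)
    if (nrow(h) == 0) next # no seed k-mer survived mutation
    n_checked <- n_checked + 1
    expect_equal(h$raw_score[1], sw_score_oracle(pr$bait, pr$target, scheme))
  }
  expect_gte(n_checked, 50)
})

test_that("translated search reports nucleotide coordinates on the correct strand", {
  set.seed(14)
  prot <- random_aa_str(40)
  # encode the protein, embed at nt offset 30, and also reverse-complement
  cod <- vapply(strsplit(prot, "")[[1]], function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, "")
  cds <- paste(cod, collapse = "")
  fwd <- paste0(random_dna_str(30), cds, random_dna_str(21))
  h <- search_hsps(prot, c(t = fwd))
  expect_equal(h$percent_identity[1], 100)
  expect_equal(h$subject_start[1], 30)
  expect_equal(h$subject_end[1], 30 + nchar(cds))
  hr <- search_hsps(prot, c(t = rc_oracle(fwd)))
  expect_equal(hr$percent_identity[1], 100)
  expect_lt(hr$frame[1], 0)
  expect_equal(hr$subject_start[1], 21)
})

test_that("raising min_score never adds hits", {
  set.seed(15)
  bait <- random_aa_str(60)
  targets <- setNames(vapply(1:30, function(i) {
    paste0(random_aa_str(10), substring(bait, sample(1:30, 1), sample(31:60, 1)),
           random_aa_str(10))
  }, ""), sprintf("t%02d", 1:30))
  lo <- search_hsps(bait, targets, min_score = 20)
  hi <- search_hsps(bait, targets, min_score = 60)
  expect_true(all(hi$subject_id %in% lo$subject_id))
  expect_lte(nrow(hi), nrow(lo))
  expect_true(all(lo$raw_score >= 20), all(hi$raw_score >= 60))
  # sorted by descending score
  expect_false(is.unsorted(rev(lo$raw_score)))
})

test_that("global percent identity/similarity match hand-checked cases and are symmetric", {
  expect_equal(percent_similarity("MKWVTF", "MKWVTF")$similarity, 100)
  r <- percent_similarity("AAAA", "AAAC")
  expect_equal(r$identity, 75)
  # BLOSUM62: A vs C scores 0, not positive, so similarity equals identity
  expect_equal(r$similarity, 75)
  # K vs R is a positive substitution => counted as similar, not identical
  r2 <- percent_similarity("AKAA", "ARAA")
  expect_equal(r2$identity, 75)
  expect_equal(r2$similarity, 100)
  set.seed(16)
  for (i in 1:10) {
    a <- random_aa_str(30); b <- random_aa_str(25)
    expect_equal(percent_similarity(a, b)$similarity,
                 percent_similarity(b, a)$similarity)
  }
})
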