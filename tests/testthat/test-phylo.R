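test_that("progressive alignment preserves inputs and handles simple cases", {
  two <- c(a = "MKWVTF", b = "MKWVTF")
  msa <- align_progressive(two)
  expect_identical(unclass(msa), two)
  # one internal deletion: one gap column, other columns match
  msa2 <- align_progressive(c(a = "ACDE", b = "ACE"))
  expect_equal(nchar(msa2[["a"]]), 4)
  expect_equal(sum(strsplit(msa2[["b"]], "")[[1]] == "-"), 1)
  # degapping reproduces every input; columns >= longest input
  set.seed(61)
  seqs <- setNames(vapply(1:6, function(i) random_aa_str(sample(40:60, 1)), ""),
                   sprintf("s%d", 1:6))
  msa3 <- align_progressive(seqs)
  expect_equal(length(unique(nchar(msa3))), 1)
  expect_gte(nchar(msa3[[1]]), max(nchar(seqs)))
  for (id in names(seqs))
    expect_identical(gsub("-", "", msa3[[id]]), seqs[[id]])
})

test_that("gap-column filter removes strictly-more-than-threshold columns only", {
  rows <- c(sprintf("s%02d", 1:10))
  # column 1: 9/10 gaps (removed); column 2: 8/10 gaps (retained);
  # column 3: gapless
  col1 <- c("A", rep("-", 9))
  col2 <- c("A", "A", rep("-", 8))
  col3 <- rep("C", 10)
  msa <- setNames(paste0(col1, col2, col3), rows)
  filt <- filter_gap_columns(msa, 0.8)
  expect_equal(nchar(filt[[1]]), 2)
  expect_identical(substring(filt[[1]], 1, 1), "A")
  # gapless alignment is untouched
  clean <- setNames(rep("MKWV", 4), sprintf("t%d", 1:4))
  expect_identical(unclass(filter_gap_columns(clean)), clean)
})

test_that("distances are Poisson-corrected p-distances over shared columns", {
  msa <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAAAATTTTT")
  D <- suppressWarnings(distance_matrix(msa))
  expect_equal(D["a", "b"], 0)
  expect_equal(D["a", "c"], -log(1 - 0.5))
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # gapped pair: p computed over mutually ungapped columns only
  msa2 <- c(a = "AA--AAAAAA", b = "AAAAAATTAA")
  D2 <- suppressWarnings(distance_matrix(msa2))
  expect_equal(D2["a", "b"], -log(1 - 2 / 8))
  expect_true(any(attr(D2, "low_overlap")))
})

test_that("NJ recovers additive matrices and is order-invariant", {
  # fixed 4-taxon additive matrix with known split ab|cd
  D <- matrix(c(0, 2, 7, 7,
                2, 0, 7, 7,
                7, 7, 0, 2,
                7, 7, 2, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- nj_tree(D)
  expect_true(same_topology(tr, ape::read.tree(text = "((a,b),(c,d));")))
  # permuting the input order leaves the topology invariant
  pp <- c("c", "a", "d", "b")
  expect_true(same_topology(nj_tree(D[pp, pp]), tr))
  # random additive matrices: exact topology recovery, and agreement with
  # the independent NJ in ape
  for (i in 1:25) {
    ra <- random_additive(sample(4:8, 1), seed = 100 + i)
    got <- nj_tree(ra$D)
    expect_true(same_topology(got, ra$tree))
    expect_true(same_topology(got, ape::nj(ra$D)))
    # reconstructed branch lengths reproduce the additive distances
    expect_equal(cophenetic(got)[rownames(ra$D), rownames(ra$D)], ra$D,
                 tolerance = 1e-6)
  }
})

test_that("bootstrap gives full support for duplicated-column alignments and fixed-seed reproducibility", {
  base <- c(a = "AAAAAAAAC", b = "AAAAAAAAT", c = "TTTTTTTTC",
            d = "TTTTTTTTT")
  msa <- setNames(vapply(base, function(s) strrep(s, 10), ""), names(base))
  bt <- bootstrap_nj(msa, n_reps = 100, seed = 9)
  expect_true(all(bt$supports == 100))
  bt2 <- bootstrap_nj(msa, n_reps = 100, seed = 9)
  expect_identical(bt$supports, bt2$supports)
  expect_true(all(bt$supports >= 0 & bt$supports <= 100))
})

test_that("clade membership test recovers planted clades from simulated families", {
  ok <- 0
  for (i in 1:20) {
    root <- with(list(), {
      set.seed(200 + i); random_aa_str(120)
    })
    tree <- ape::read.tree(text = paste0(
      "(((A1:0.1,A2:0.1):0.05,(A3:0.1,A4:0.1):0.05):0.45,",
      "((B1:0.1,B2:0.1):0.05,(B3:0.1,B4:0.1):0.05):0.45,out:0.9);"))
    fam <- simulate_protein_family(tree, root, rate = 0.4, seed = 300 + i)
    msa <- filter_gap_columns(align_progressive(fam))
    tr <- nj_tree(suppressWarnings(distance_matrix(msa)))
    if (clade_test(tr, c("A1", "A2", "A3", "A4"), "out")) ok <- ok + 1
  }
  expect_gte(ok, 19)
  # conventions: singleton focal set, and all-but-outgroup
  ra <- random_additive(6, seed = 7)
  tr <- nj_tree(ra$D)
  expect_true(clade_test(tr, tr$tip.label[1], tr$tip.label[6]))
  expect_true(clade_test(tr, tr$tip.label[1:5], tr$tip.label[6]))
})
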