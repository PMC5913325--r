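# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (full dynamic programming, brute-force
# scans) and share only published constants (genetic code, BLOSUM62)
# with the implementation under test.

# full Smith-Waterman local score with affine gaps (gap of length L costs
# gap_open + L * gap_ext; gaps open from the match state only, matching
# the package's recurrence); plain O(mn) loops, no seeding or banding
sw_score_oracle <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  mat <- scheme$matrix
  sc <- function(x, y) {
    if (x %in% rownames(mat) && y %in% rownames(mat)) mat[x, y] else 0
  }
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(-Inf, m + 1, n + 1)
  Y <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      X[i, j] <- max(M[i - 1, j] - scheme$gap_open - scheme$gap_ext,
                     X[i - 1, j] - scheme$gap_ext)
      Y[i, j] <- max(M[i, j - 1] - scheme$gap_open - scheme$gap_ext,
                     Y[i, j - 1] - scheme$gap_ext)
      M[i, j] <- max(0, sc(A[i - 1], B[j - 1]) +
                       max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# codon-by-codon translation loop on the published genetic code
translate_oracle <- function(seq, offset1 = 1L) {
  gc <- Biostrings::GENETIC_CODE
  out <- character(0)
  i <- offset1
  while (i + 2 <= nchar(seq)) {
    cod <- substring(seq, i, i + 2)
    out <- c(out, if (cod %in% names(gc)) gc[[cod]] else "X")
    i <- i + 3
  }
  paste(out, collapse = "")
}

rc_oracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# brute-force k-mer-set intersection recruitment filter
recruit_oracle <- function(bait, reads, k, min_shared) {
  bk <- unique(substring(bait, 1:(nchar(bait) - k + 1), k:nchar(bait)))
  hit <- vapply(reads$seq, function(s) {
    ks <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
    rs <- rc_oracle(s)
    kr <- substring(rs, 1:(nchar(rs) - k + 1), k:nchar(rs))
    max(sum(ks %in% bk), sum(kr %in% bk)) >= min_shared
  }, TRUE, USE.NAMES = FALSE)
  reads$id[hit]
}

# random additive distance matrix: path metric of a random binary tree
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.2, 1.5))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  list(tree = tr, D = cophenetic(tr)[tr$tip.label, tr$tip.label])
}

same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2))[1] == 0
}

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_aa_str <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, replace = TRUE),
        collapse = "")
}

# a (bait, target) pair guaranteed to share seed k-mers: the target embeds
# a substitution-and-indel-mutated copy of a bait segment
seeded_pair <- function(len_bait = 50, len_target = 60, p_sub = 0.1,
                        n_indel_max = 3) {
  bait <- random_aa_str(len_bait)
  seg <- strsplit(substring(bait, 6, len_bait - 5), "")[[1]]
  nsub <- rbinom(1, length(seg), p_sub)
  if (nsub > 0) {
    pos <- sample(seq_along(seg), nsub)
    for (p in pos) seg[p] <- random_aa_str(1)
  }
  for (k in seq_len(sample(0:n_indel_max, 1))) {
    if (runif(1) < 0.5 && length(seg) > 2) {
      seg <- seg[-sample(seq_along(seg), 1)]
    } else {
      at <- sample(seq_along(seg), 1)
      seg <- append(seg, random_aa_str(1), after = at)
    }
  }
  core <- paste(seg, collapse = "")
  pad <- max(0, len_target - nchar(core))
  left <- sample(0:pad, 1)
  target <- paste0(random_aa_str(left), core, random_aa_str(pad - left))
  list(bait = bait, target = target)
}
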