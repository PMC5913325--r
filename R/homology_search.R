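#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code. Codons containing N translate to `X` when
#' ambiguous, stop codons are rendered `*`, and frames -1..-3 translate the
#' reverse complement. Trailing partial codons are dropped, so the
#' translation in frame f has `floor((nchar(seq) - offset(f)) / 3)` residues.
#'
#' @param seq nucleotide sequence over A, C, G, T, N.
#' @return named character vector of six proteins, names "+1".."-3".
#' @examples
#' translate6("ATGAAATAA")[["+1"]] # "MK*"
#' @export
translate6 <- function(seq) {
  stopifnot_scalar_string(seq, "seq")
  seq <- toupper(seq)
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  if (nchar(seq) == 0)
    return(setNames(rep("", 6), frames))
  rc <- revcomp(seq)
  out <- character(6)
  for (i in 1:3) {
    out[i] <- translate_frame(seq, i)
    out[i + 3] <- translate_frame(rc, i)
  }
  setNames(out, frames)
}

translate_frame <- function(seq, offset1) {
  n <- nchar(seq)
  len <- (n - offset1 + 1L) %/% 3L
  if (len < 1) return("")
  starts <- offset1 + 3L * (seq_len(len) - 1L)
  aa <- codon_table()[substring(seq, starts, starts + 2L)]
  aa[is.na(aa)] <- "X" # codons containing N (or other ambiguity)
  paste(aa, collapse = "")
}

# standard genetic code as a codon -> residue lookup (stops are "*")
codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- Biostrings::GENETIC_CODE
    tab
  }
})

#' Seeded local similarity search
#'
#' The "probe" stage: finds local alignments of a bait against a set of
#' target sequences by exact `seed_k`-mer matching followed by banded local
#' extension with affine gaps (band half-width `scheme$band` around the seed
#' diagonals). Three mode combinations are supported and chosen from the
#' alphabets: protein bait vs nucleotide targets (targets are searched in
#' all six frames and hit coordinates are reported in nucleotides on the
#' target), protein vs protein, and nucleotide vs nucleotide (both target
#' strands searched). One best-scoring alignment is reported per
#' (target, frame).
#'
#' @param bait single bait sequence (protein or nucleotide).
#' @param targets named character vector of target sequences, or a
#'   [read_set()].
#' @param scheme a [scoring_scheme()] matching the bait alphabet; defaults
#'   to a protein or nucleotide scheme inferred from the bait.
#' @param bait_id,min_score optional overrides.
#' @return data frame of hits sorted by decreasing `raw_score` (ties by
#'   subject id, then subject start): query/subject ids, 0-based half-open
#'   query and subject ranges (subject range always in nucleotides for
#'   nucleotide targets), `frame`, `raw_score`, `percent_identity`,
#'   `percent_similarity`, and the two aligned strings.
#' @examples
#' hits <- search_hsps("MKWVTFISLLFLFSSAYS",
#'                     c(t1 = "ATGAAGTGGGTAACCTTTATTTCCCTTCTTTTTCTCTTTAGCTCGGCTTATTCC"))
#' hits$percent_identity
#' @export
search_hsps <- function(bait, targets, scheme = NULL, bait_id = "bait",
                        min_score = NULL) {
  if (inherits(targets, "read_set"))
    targets <- setNames(targets$seq, targets$id)
  stopifnot(length(bait) == 1, nchar(bait) > 0)
  if (is.null(names(targets)))
    names(targets) <- sprintf("t%d", seq_along(targets))
  bait_alpha <- guess_alphabet(bait)
  targ_alpha <- if (length(targets)) guess_alphabet(targets) else bait_alpha
  if (is.null(scheme))
    scheme <- scoring_scheme(if (bait_alpha == "protein") "protein" else "dna")
  if (scheme$type == "protein" && bait_alpha != "protein")
    stop("alphabet mismatch: protein scheme with nucleotide bait", call. = FALSE)
  if (scheme$type == "dna" && bait_alpha == "protein")
    stop("alphabet mismatch: nucleotide scheme with protein bait", call. = FALSE)
  if (bait_alpha == "dna" && targ_alpha == "protein")
    stop("alphabet mismatch: nucleotide bait against protein targets",
         call. = FALSE)
  if (!is.null(min_score)) scheme$min_score <- min_score

  if (bait_alpha == "protein" && targ_alpha == "dna") {
    # translated search, six frames per target
    frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
    tr <- lapply(targets, translate6)
    flat <- unlist(tr, use.names = FALSE)
    t_idx <- rep(seq_along(targets), each = 6L)
    f_idx <- rep(frames, times = length(targets))
    hits <- run_cpp_search(bait, flat, scheme)
    if (nrow(hits) == 0) return(empty_hsps())
    ti <- t_idx[hits$target]
    fr <- f_idx[hits$target]
    tlen <- nchar(targets)[ti]
    off <- as.integer(substring(fr, 2)) - 1L # 0-based frame offset
    plus <- startsWith(fr, "+")
    # aa range -> nt range on the translated strand
    nt_s <- off + 3L * hits$subject_start
    nt_e <- off + 3L * hits$subject_end
    sub_s <- ifelse(plus, nt_s, tlen - nt_e)
    sub_e <- ifelse(plus, nt_e, tlen - nt_s)
    res <- build_hsps(bait_id, names(targets)[ti], hits, sub_s, sub_e,
                      frame = ifelse(plus, 1L, -1L) * (off + 1L), scheme)
  } else if (bait_alpha == "protein") {
    hits <- run_cpp_search(bait, unname(targets), scheme)
    if (nrow(hits) == 0) return(empty_hsps())
    res <- build_hsps(bait_id, names(targets)[hits$target], hits,
                      hits$subject_start, hits$subject_end, frame = NA_integer_,
                      scheme)
  } else {
    # nucleotide vs nucleotide, both strands
    fwd <- unname(targets)
    rev <- revcomp(fwd)
    flat <- c(rbind(fwd, rev))
    t_idx <- rep(seq_along(targets), each = 2L)
    plus_v <- rep(c(TRUE, FALSE), times = length(targets))
    hits <- run_cpp_search(bait, flat, scheme)
    if (nrow(hits) == 0) return(empty_hsps())
    ti <- t_idx[hits$target]
    plus <- plus_v[hits$target]
    tlen <- nchar(targets)[ti]
    sub_s <- ifelse(plus, hits$subject_start, tlen - hits$subject_end)
    sub_e <- ifelse(plus, hits$subject_end, tlen - hits$subject_start)
    res <- build_hsps(bait_id, names(targets)[ti], hits, sub_s, sub_e,
                      frame = ifelse(plus, 1L, -1L), scheme)
  }
  res[order(-res$raw_score, res$subject_id, res$subject_start), ,
      drop = FALSE]
}

run_cpp_search <- function(bait, targets, scheme) {
  cpp_search(bait, targets, scheme$matrix, scheme$alphabet, scheme$seed_k,
             scheme$band, scheme$gap_open, scheme$gap_ext, scheme$min_score)
}

aln_stats <- function(q, s, mat) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc)
  both <- qc != "-" & sc != "-"
  id <- sum(qc == sc & both)
  pos <- id
  mm <- which(both & qc != sc)
  for (i in mm) {
    a <- qc[i]; b <- sc[i]
    if (a %in% rownames(mat) && b %in% rownames(mat) && mat[a, b] > 0)
      pos <- pos + 1L
  }
  c(identity = 100 * id / n, similarity = 100 * pos / n)
}

build_hsps <- function(bait_id, subject_id, hits, sub_s, sub_e, frame, scheme) {
  st <- t(vapply(seq_len(nrow(hits)),
                 function(i) aln_stats(hits$query_aln[i], hits$subject_aln[i],
                                       scheme$matrix),
                 c(identity = 0, similarity = 0)))
  data.frame(query_id = bait_id, subject_id = subject_id,
             query_start = hits$query_start, query_end = hits$query_end,
             subject_start = as.integer(sub_s), subject_end = as.integer(sub_e),
             frame = frame, raw_score = hits$raw_score,
             percent_identity = st[, "identity"],
             percent_similarity = st[, "similarity"],
             query_aln = hits$query_aln, subject_aln = hits$subject_aln,
             stringsAsFactors = FALSE)
}

empty_hsps <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             query_start = integer(0), query_end = integer(0),
             subject_start = integer(0), subject_end = integer(0),
             frame = integer(0), raw_score = numeric(0),
             percent_identity = numeric(0), percent_similarity = numeric(0),
             query_aln = character(0), subject_aln = character(0),
             stringsAsFactors = FALSE)
}

#' Percent identity and similarity over a global alignment
#'
#' Aligns two sequences globally with affine gaps and reports
#' `100 * identities / columns` and
#' `100 * (identities + positive-scoring non-identical pairs) / columns` --
#' the usual "positives" convention for similarity.
#'
#' @param a,b sequences (both protein or both nucleotide).
#' @param scheme a [scoring_scheme()]; inferred from `a` when NULL.
#' @return list with `identity`, `similarity`, `score`, and the two aligned
#'   strings.
#' @examples
#' percent_similarity("AAAA", "AAAC")$identity # 75
#' @export
percent_similarity <- function(a, b, scheme = NULL) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  if (is.null(scheme))
    scheme <- scoring_scheme(if (guess_alphabet(a) == "protein") "protein" else "dna")
  g <- cpp_global_align(a, b, scheme$matrix, scheme$alphabet,
                        scheme$gap_open, scheme$gap_ext)
  st <- aln_stats(g$a_aln, g$b_aln, scheme$matrix)
  list(identity = unname(st["identity"]), similarity = unname(st["similarity"]),
       score = g$score, a_aln = g$a_aln, b_aln = g$b_aln)
}
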