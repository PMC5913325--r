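#' Recruit reads sharing exact k-mers with a bait sequence
#'
#' A read is recruited iff it, or its reverse complement, shares at least
#' `min_shared` exact nucleotide `seed_k`-mers with the bait. Recruited
#' reads keep their identifiers and are returned oriented to the bait
#' strand (the orientation sharing more k-mers wins; ties keep the forward
#' read), which is what makes the orientation-naive greedy assembler
#' downstream applicable.
#'
#' @param bait nucleotide bait (typically the current contig).
#' @param reads a [read_set()].
#' @param seed_k k-mer length (must not exceed the read length to have any
#'   effect).
#' @param min_shared minimum number of shared k-mers.
#' @return a [read_set()] subset with an added logical column `flipped`.
#' @export
recruit_reads <- function(bait, reads, seed_k = 21L, min_shared = 2L) {
  stopifnot(inherits(reads, "data.frame"), nchar(bait) >= seed_k)
  bait_kmers <- unique(seq_kmers(toupper(bait), seed_k))
  n <- nrow(reads)
  if (n == 0) return(reads[0, ])
  fwd <- vapply(reads$seq, function(s)
    sum(seq_kmers(s, seed_k) %in% bait_kmers), 0L, USE.NAMES = FALSE)
  rcs <- revcomp(reads$seq)
  rev <- vapply(rcs, function(s)
    sum(seq_kmers(s, seed_k) %in% bait_kmers), 0L, USE.NAMES = FALSE)
  keep <- pmax(fwd, rev) >= min_shared
  out <- reads[keep, , drop = FALSE]
  flip <- rev[keep] > fwd[keep]
  out$seq[flip] <- rcs[keep][flip]
  out$qual[flip] <- vapply(out$qual[flip],
                           function(q) paste(rev(strsplit(q, "")[[1]]),
                                             collapse = ""), "")
  out$flipped <- flip
  class(out) <- c("read_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of sequences with the longest suffix-prefix
#' overlap of at least `min_overlap` nucleotides and mismatch fraction at
#' most `max_mismatch_frac`; ties are broken by higher overlap identity,
#' then by the lexicographically smaller pair of representative read ids.
#' The consensus base at each position is the majority vote of the
#' supporting reads; ties resolve to the alphabetically first base. The
#' procedure terminates when no mergeable pair remains. Reads are assumed
#' to be in a consistent orientation (see [recruit_reads()]).
#'
#' @param reads a [read_set()] (or data frame with `id` and `seq`).
#' @param min_overlap minimum overlap, nt.
#' @param max_mismatch_frac maximum fraction of mismatching positions in an
#'   acceptable overlap.
#' @param round_created iteration index recorded on each contig.
#' @return list of contigs, longest first; each contig is a list with
#'   `sequence`, per-position `support` counts, `read_ids`, and
#'   `round_created`.
#' @examples
#' rs <- read_set(c("a", "b"), c("ACGTACGTACGTACGTAAAA", "ACGTACGTAAAACCCCGGGG"))
#' assemble_greedy(rs, min_overlap = 8)[[1]]$sequence
#' @export
assemble_greedy <- function(reads, min_overlap = 25L,
                            max_mismatch_frac = 0.05, round_created = 1L) {
  stopifnot(is.data.frame(reads))
  if (nrow(reads) == 0) return(list())
  raw <- cpp_assemble_greedy(reads$seq, reads$id, as.integer(min_overlap),
                             max_mismatch_frac)
  lapply(raw, function(ct) {
    list(sequence = ct$sequence, support = ct$support,
         read_ids = reads$id[ct$members], round_created = round_created)
  })
}

#' Default parameters for iterative gene recovery
#'
#' @param max_rounds maximum recruitment/assembly rounds.
#' @param min_score round-1 protein hit threshold (raw BLOSUM62 units).
#' @param seed_k_nt,min_shared nucleotide recruitment parameters for rounds
#'   after the first.
#' @param min_overlap,max_mismatch_frac assembly parameters.
#' @param bait_coverage fraction of the bait that the candidate protein
#'   alignment must span for the ORF to count as complete.
#' @param min_growth minimum contig length growth (nt) per round; below
#'   this the iteration is declared stalled.
#' @export
recovery_params <- function(max_rounds = 20L, min_score = 40,
                            seed_k_nt = 21L, min_shared = 2L,
                            min_overlap = 25L, max_mismatch_frac = 0.05,
                            bait_coverage = 0.9, min_growth = 5L) {
  list(max_rounds = as.integer(max_rounds), min_score = min_score,
       seed_k_nt = as.integer(seed_k_nt), min_shared = as.integer(min_shared),
       min_overlap = as.integer(min_overlap),
       max_mismatch_frac = max_mismatch_frac,
       bait_coverage = bait_coverage, min_growth = as.integer(min_growth))
}

#' Iterative bait-seeded gene recovery
#'
#' The core method. Round 1 recruits reads by translated local search of
#' the protein bait against the dataset; the recruited reads are assembled
#' by greedy overlap consensus; the best contig (highest bait similarity,
#' then longest) is promoted to the new bait and later rounds recruit by
#' exact nucleotide k-mer sharing against it. Iteration ends with status
#' `orf_complete` when the annotated ORF has a start codon, an in-frame
#' stop, and a bait alignment covering at least `bait_coverage` of the
#' bait; `stalled` when the recruited read set stops growing or the contig
#' grows by less than `min_growth` nt in a round; otherwise `max_rounds`.
#'
#' @param bait_protein amino-acid bait (a diverged ortholog of the target).
#' @param reads a [read_set()] of the full dataset.
#' @param params a [recovery_params()] list.
#' @return list with `contig` (best contig or NULL), `annotation` (from
#'   [annotate_gene()], or NULL), and `state`: round, status, the cumulative
#'   recruited id set, and a per-round log data frame.
#' @export
iterate_recovery <- function(bait_protein, reads,
                             params = recovery_params()) {
  stopifnot(nchar(bait_protein) > 0, inherits(reads, "data.frame"))
  log <- data.frame(round = integer(0), n_recruited = integer(0),
                    contig_length = integer(0), status = character(0),
                    stringsAsFactors = FALSE)
  state <- list(round = 0L, status = "stalled", recruited = character(0),
                log = log)
  empty <- list(contig = NULL, annotation = NULL, state = state)
  if (params$max_rounds < 1) {
    state$status <- "max_rounds"
    empty$state <- state
    return(empty)
  }
  pscheme <- scoring_scheme("protein", min_score = params$min_score)
  hits <- search_hsps(bait_protein, reads, pscheme)
  if (nrow(hits) == 0) {
    state$round <- 1L
    state$log <- rbind(log, data.frame(round = 1L, n_recruited = 0L,
                                       contig_length = 0L,
                                       status = "stalled"))
    empty$state <- state
    return(empty)
  }
  # orient round-1 recruits by the frame sign of their best hit
  best_frame <- tapply(seq_len(nrow(hits)), hits$subject_id,
                       function(ii) hits$frame[ii[which.max(hits$raw_score[ii])]])
  recruited <- reads[match(names(best_frame), reads$id), , drop = FALSE]
  flip <- best_frame < 0
  recruited$seq[flip] <- revcomp(recruited$seq[flip])
  recruited$flipped <- as.vector(flip)
  rownames(recruited) <- NULL

  contig <- NULL
  ann <- NULL
  prev_len <- 0L
  status <- NULL
  round <- 0L
  for (round in seq_len(params$max_rounds)) {
    contigs <- assemble_greedy(recruited, params$min_overlap,
                               params$max_mismatch_frac, round_created = round)
    contig <- pick_best_contig(contigs, bait_protein, pscheme)
    ann <- annotate_gene(contig$sequence, bait_protein, pscheme,
                         bait_coverage = params$bait_coverage)
    log <- rbind(log, data.frame(round = round,
                                 n_recruited = nrow(recruited),
                                 contig_length = nchar(contig$sequence),
                                 status = ann$status))
    if (ann$status == "complete") { status <- "orf_complete"; break }
    if (round == params$max_rounds) { status <- "max_rounds"; break }
    newly <- recruit_reads(contig$sequence, reads,
                           seed_k = params$seed_k_nt,
                           min_shared = params$min_shared)
    add <- !(newly$id %in% recruited$id)
    grew_reads <- any(add)
    grew_contig <- nchar(contig$sequence) - prev_len >= params$min_growth
    prev_len <- nchar(contig$sequence)
    # stall when either signal dies: no new reads to recruit, or the last
    # batch of recruits failed to extend the contig
    if (!grew_reads || !grew_contig) { status <- "stalled"; break }
    if (grew_reads)
      recruited <- rbind(recruited, newly[add, , drop = FALSE])
  }
  state <- list(round = round, status = status,
                recruited = recruited$id, log = log)
  list(contig = contig, annotation = ann, state = state)
}

pick_best_contig <- function(contigs, bait_protein, pscheme) {
  stopifnot(length(contigs) > 0)
  if (length(contigs) == 1) return(contigs[[1]])
  seqs <- vapply(contigs, `[[`, "", "sequence")
  hits <- search_hsps(bait_protein, setNames(seqs, sprintf("c%d", seq_along(seqs))),
                      pscheme, min_score = 1)
  score <- rep(0, length(contigs))
  if (nrow(hits) > 0) {
    idx <- as.integer(sub("^c", "", hits$subject_id))
    for (i in seq_len(nrow(hits)))
      score[idx[i]] <- max(score[idx[i]], hits$raw_score[i])
  }
  ord <- order(-score, -nchar(seqs))
  contigs[[ord[1]]]
}
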