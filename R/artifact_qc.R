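#' Longest homopolymer runs per base
#'
#' Exact maximal-run scan. Long mononucleotide runs in assemblies of
#' extremely GC-rich regions are a characteristic artifact signature, so
#' any run at or above `flag_threshold` raises a flag.
#'
#' @param seq nucleotide sequence.
#' @param flag_threshold run length, nt, at which a run is flagged.
#' @return list with `runs` (data frame: base, length, 0-based start of the
#'   longest run per base present) and `flagged` (data frame of all runs
#'   at or above the threshold).
#' @examples
#' longest_runs("GGGGG")$runs
#' @export
longest_runs <- function(seq, flag_threshold = 15L) {
  stopifnot_scalar_string(seq, "seq")
  if (nchar(seq) == 0) {
    empty <- data.frame(base = character(0), length = integer(0),
                        start = integer(0), stringsAsFactors = FALSE)
    return(list(runs = empty, flagged = empty))
  }
  r <- rle(strsplit(toupper(seq), "")[[1]])
  starts <- c(0L, cumsum(r$lengths)[-length(r$lengths)])
  all_runs <- data.frame(base = r$values, length = r$lengths, start = starts,
                         stringsAsFactors = FALSE)
  best <- do.call(rbind, lapply(split(all_runs, all_runs$base), function(d) {
    d[which.max(d$length), ]
  }))
  rownames(best) <- NULL
  flagged <- all_runs[all_runs$length >= flag_threshold, , drop = FALSE]
  rownames(flagged) <- NULL
  list(runs = best[order(best$base), ], flagged = flagged)
}

#' Terminal deficits and internal insertions relative to a reference
#'
#' Globally aligns a query to a trusted reference and reports how many
#' reference bases fall beyond the query's first and last aligned base
#' (5' and 3' deficits), and all query-only blocks of at least
#' `min_insertion` nt with their positions -- the two artifact classes
#' (terminal truncation, homopolymer insertion) that distinguish an
#' assembly artifact from a verified sequence.
#'
#' @param query,reference nucleotide sequences.
#' @param scheme nucleotide [scoring_scheme()].
#' @param min_insertion minimum internal query-only block length to report.
#' @return list with `deficit5`, `deficit3` (nt counts) and
#'   `internal_insertions` (data frame: `query_start` 0-based on the query,
#'   `ref_pos` 0-based reference position of the insertion point,
#'   `length`, `sequence`).
#' @export
terminal_deficit <- function(query, reference, scheme = scoring_scheme("dna"),
                             min_insertion = 10L) {
  g <- cpp_global_align(query, reference, scheme$matrix, scheme$alphabet,
                        scheme$gap_open, scheme$gap_ext)
  qc <- strsplit(g$a_aln, "")[[1]]
  rc <- strsplit(g$b_aln, "")[[1]]
  qgap <- qc == "-"
  # leading / trailing columns where the query is absent
  n <- length(qc)
  lead <- if (all(qgap)) n else which(!qgap)[1] - 1L
  trail <- if (all(qgap)) 0L else n - max(which(!qgap))
  deficit5 <- sum(rc[seq_len(lead)] != "-")
  deficit3 <- if (trail > 0) sum(rc[(n - trail + 1L):n] != "-") else 0L
  # query-only blocks: runs of reference gaps strictly inside the alignment
  rgap <- rc == "-"
  ins <- data.frame(query_start = integer(0), ref_pos = integer(0),
                    length = integer(0), sequence = character(0),
                    stringsAsFactors = FALSE)
  r <- rle(rgap)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  qpos <- cumsum(!qgap) # query residues consumed up to each column
  rpos <- cumsum(!rgap)
  for (k in which(r$values)) {
    if (starts[k] == 1L || ends[k] == n) next # query overhangs, not internal
    len <- r$lengths[k]
    if (len < min_insertion) next
    ins <- rbind(ins, data.frame(
      query_start = qpos[starts[k]] - 1L,
      ref_pos = rpos[starts[k]],
      length = len,
      sequence = paste(qc[starts[k]:ends[k]], collapse = ""),
      stringsAsFactors = FALSE))
  }
  list(deficit5 = deficit5, deficit3 = deficit3, internal_insertions = ins)
}

#' Assemble an artifact-QC report for a set of sequences
#'
#' Runs the homopolymer scan on every sequence and, when a reference is
#' supplied, the terminal-deficit comparison. Any flagged homopolymer run,
#' nonzero terminal deficit, or internal insertion marks the report as
#' failed, which callers can translate into a nonzero exit status for
#' pipeline gating.
#'
#' @param seqs named character vector of sequences to check.
#' @param reference optional trusted reference sequence.
#' @param flag_threshold homopolymer flag threshold, nt.
#' @return a `qc_report` list, one entry per sequence, plus `any_flag`.
#' @export
qc_report <- function(seqs, reference = NULL, flag_threshold = 15L) {
  stopifnot(!is.null(names(seqs)))
  per <- lapply(names(seqs), function(id) {
    runs <- longest_runs(seqs[[id]], flag_threshold)
    entry <- list(id = id, length = nchar(seqs[[id]]),
                  longest_runs = runs$runs, flagged_runs = runs$flagged)
    if (!is.null(reference)) {
      td <- terminal_deficit(seqs[[id]], reference)
      entry$deficit5 <- td$deficit5
      entry$deficit3 <- td$deficit3
      entry$internal_insertions <- td$internal_insertions
    }
    entry$flag <- nrow(runs$flagged) > 0 ||
      (!is.null(reference) && (entry$deficit5 > 0 || entry$deficit3 > 0 ||
                               nrow(entry$internal_insertions) > 0))
    entry
  })
  names(per) <- names(seqs)
  structure(list(sequences = per,
                 any_flag = any(vapply(per, `[[`, TRUE, "flag"))),
            class = "qc_report")
}

#' Write a QC report as JSON
#' @param report a [qc_report()].
#' @param file output path.
#' @export
write_qc_json <- function(report, file) {
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(file)
}
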