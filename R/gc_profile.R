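#' GC content of a sequence
#'
#' (G+C) / (A+C+G+T); ambiguity codes are excluded from both numerator and
#' denominator. Returns NaN for a sequence with no unambiguous base.
#'
#' @param seq nucleotide sequence.
#' @examples
#' gc_content("ATGCN") # 0.5
#' @export
gc_content <- function(seq) {
  stopifnot_scalar_string(seq, "seq")
  ch <- strsplit(toupper(seq), "")[[1]]
  sum(ch %in% c("G", "C")) / sum(ch %in% DNA_BASES)
}

#' Sliding-window GC profile
#'
#' @param seq nucleotide sequence.
#' @param window window size, nt.
#' @param step step between window starts, nt.
#' @return data frame with 0-based half-open `start`, `end` and `gc` per
#'   window (only full windows are reported).
#' @export
gc_windows <- function(seq, window = 100L, step = 50L) {
  stopifnot_scalar_string(seq, "seq")
  L <- nchar(seq)
  if (L < window)
    return(data.frame(start = integer(0), end = integer(0), gc = numeric(0)))
  ch <- strsplit(toupper(seq), "")[[1]]
  cgc <- c(0, cumsum(ch %in% c("G", "C")))
  cok <- c(0, cumsum(ch %in% DNA_BASES))
  starts <- seq(0L, L - window, by = step)
  num <- cgc[starts + window + 1L] - cgc[starts + 1L]
  den <- cok[starts + window + 1L] - cok[starts + 1L]
  data.frame(start = starts, end = starts + window,
             gc = ifelse(den > 0, num / den, NaN))
}

#' Cross-group GC contrast
#'
#' Computes per-group mean GC over labeled sequence sets and, for exactly
#' two groups with at least two members each, a one-sided Wilcoxon
#' rank-sum comparison of the first group against the second. The contrast
#' is flagged when the first group's GC exceeds the second's at p < alpha.
#' Reported as a descriptive statistic, mirroring how GC separation between
#' lineages is typically shown graphically.
#'
#' @param groups named list of named character vectors of sequences; order
#'   determines the direction of the one-sided test (first > second).
#' @param alpha flagging level.
#' @return list with `means`, per-sequence `gc` table, `p_value` (NA when
#'   not applicable) and logical `flagged`.
#' @export
gc_contrast <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  tab <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group = g,
               id = if (is.null(names(groups[[g]])))
                 sprintf("%s_%d", g, seq_along(groups[[g]])) else names(groups[[g]]),
               gc = vapply(groups[[g]], gc_content, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  means <- tapply(tab$gc, tab$group, mean)[names(groups)]
  p <- NA_real_
  if (length(groups) == 2 && all(lengths(groups) >= 2)) {
    p <- wilcox.test(tab$gc[tab$group == names(groups)[1]],
                     tab$gc[tab$group == names(groups)[2]],
                     alternative = "greater", exact = FALSE)$p.value
  }
  list(means = means, gc = tab, p_value = p,
       flagged = !is.na(p) && p < alpha)
}

#' Write a sliding-window GC profile as TSV
#' @param profile data frame from [gc_windows()].
#' @param file output path.
#' @export
write_gc_tsv <- function(profile, file) {
  write.table(profile, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
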