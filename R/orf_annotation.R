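#' Find candidate open reading frames in all six frames
#'
#' Scans every frame for ATG-to-stop ORFs. Stop-free stretches that lack an
#' ATG, and ATG-initiated stretches that run off the end of the sequence
#' without a stop, are also reported and flagged via `has_start` /
#' `has_stop`, so that truncated genes remain visible. Coordinates are
#' 0-based half-open on the forward strand of the input.
#'
#' @param contig nucleotide sequence.
#' @param min_aa minimum protein length (excluding stop) to report.
#' @return data frame sorted by decreasing protein length: `start`, `end`
#'   (nt, forward-strand coords; the range includes the stop codon when
#'   present), `strand`, `frame`, `protein`, `has_start`, `has_stop`.
#' @examples
#' find_orfs("ATGAAATAA")[1, c("protein", "has_start", "has_stop")]
#' @export
find_orfs <- function(contig, min_aa = 1L) {
  stopifnot_scalar_string(contig, "contig")
  L <- nchar(contig)
  tr <- translate6(contig)
  out <- list()
  for (f in names(tr)) {
    aa <- tr[[f]]
    n <- nchar(aa)
    if (n == 0) next
    off <- as.integer(substring(f, 2)) - 1L
    plus <- startsWith(f, "+")
    ch <- strsplit(aa, "")[[1]]
    stops <- which(ch == "*")
    seg_start <- c(1L, stops + 1L)       # aa index where each segment begins
    seg_stop <- c(stops, n + 1L)         # aa index of terminating stop (n+1 = none)
    for (k in seq_along(seg_start)) {
      s0 <- seg_start[k]
      s1 <- seg_stop[k]                  # exclusive of protein, stop position
      if (s1 - s0 < min_aa) next
      seg <- ch[s0:(s1 - 1L)]
      atg <- which(seg == "M")
      has_stop <- s1 <= n
      if (length(atg)) {
        p0 <- s0 + atg[1] - 1L           # first ATG
        has_start <- TRUE
      } else {
        p0 <- s0
        has_start <- FALSE
      }
      if (s1 - p0 < min_aa) next
      prot <- paste(ch[p0:(s1 - 1L)], collapse = "")
      # aa coords -> nt on the translated strand, including the stop codon
      nt0 <- off + 3L * (p0 - 1L)
      nt1 <- off + 3L * (s1 - 1L) + ifelse(has_stop, 3L, 0L)
      if (plus) {
        start <- nt0; end <- nt1
      } else {
        start <- L - nt1; end <- L - nt0
      }
      out[[length(out) + 1L]] <- data.frame(
        start = start, end = end, strand = if (plus) "+" else "-",
        frame = ifelse(plus, 1L, -1L) * (off + 1L), protein = prot,
        has_start = has_start, has_stop = has_stop, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), has_start = logical(0),
                      has_stop = logical(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-nchar(res$protein), res$start, res$frame), , drop = FALSE]
}

#' Classify ORF completeness against the bait span
#'
#' An ORF is `complete` iff it begins with ATG, ends at an in-frame stop,
#' and the bait alignment covers at least `bait_coverage` of the bait
#' length. Otherwise it is `partial5` (stop present, start missing, bait
#' coverage above half), `partial3` (start present, stop missing, coverage
#' above half), or `fragment`.
#'
#' @param has_start,has_stop logical ORF structure flags.
#' @param coverage fraction of the bait covered by the alignment to the
#'   candidate protein.
#' @param bait_coverage completeness threshold on `coverage`.
#' @return one of "complete", "partial5", "partial3", "fragment".
#' @export
orf_status <- function(has_start, has_stop, coverage, bait_coverage = 0.9) {
  if (has_start && has_stop && coverage >= bait_coverage) return("complete")
  if (!has_start && has_stop && coverage > 0.5) return("partial5")
  if (has_start && !has_stop && coverage > 0.5) return("partial3")
  "fragment"
}

#' Annotate the best bait-matching ORF of a contig
#'
#' Finds the ORF whose translation scores best against the bait, computes
#' its completeness status, scans for the superfamily motif, predicts
#' transmembrane segments by hydropathy, and partitions the protein into
#' intracellular / transmembrane / extracellular domains under type-II
#' membrane topology.
#'
#' @param contig nucleotide sequence.
#' @param bait_protein amino-acid bait.
#' @param scheme protein [scoring_scheme()].
#' @param bait_coverage completeness threshold (fraction of bait length).
#' @param motif optional PROSITE-syntax pattern to scan on the protein.
#' @return a `gene_annotation` list: `orf_range`, `strand`, `protein`,
#'   `complete5`, `complete3`, `coverage`, `status`, `motif_hits`,
#'   `tm_segments`, `domains`.
#' @export
annotate_gene <- function(contig, bait_protein, scheme = scoring_scheme("protein"),
                          bait_coverage = 0.9, motif = NULL) {
  orfs <- find_orfs(contig, min_aa = 10L)
  if (nrow(orfs) == 0) {
    return(structure(list(orf_range = c(0L, 0L), strand = "+", protein = "",
                          complete5 = FALSE, complete3 = FALSE, coverage = 0,
                          status = "fragment", motif_hits = NULL,
                          tm_segments = NULL, domains = NULL),
                     class = "gene_annotation"))
  }
  # score each candidate ORF protein against the bait
  hits <- search_hsps(bait_protein,
                      setNames(orfs$protein, sprintf("o%d", seq_len(nrow(orfs)))),
                      scheme, min_score = 1)
  if (nrow(hits) > 0) {
    best_id <- hits$subject_id[1]
    i <- as.integer(sub("^o", "", best_id))
    cov <- (hits$query_end[1] - hits$query_start[1]) / nchar(bait_protein)
  } else {
    i <- 1L
    cov <- 0
  }
  orf <- orfs[i, ]
  # homology-guided start selection: an ORF scan anchors at the first ATG
  # of a stop-free segment, which can sit upstream of the real start when
  # the 5' UTR happens to contain an in-frame ATG; re-anchor to the
  # methionine closest to where the bait alignment implies the protein
  # begins
  if (orf$has_start && nrow(hits) > 0) {
    exp_start <- hits$subject_start[1] - hits$query_start[1]
    mpos <- which(strsplit(orf$protein, "")[[1]] == "M") - 1L # 0-based
    if (exp_start > 0 && length(mpos) > 1) {
      best_m <- mpos[which.min(abs(mpos - exp_start))]
      if (best_m > 0) {
        orf$protein <- substring(orf$protein, best_m + 1L)
        if (orf$strand == "+") orf$start <- orf$start + 3L * best_m
        else orf$end <- orf$end - 3L * best_m
        cov <- (hits$query_end[1] - hits$query_start[1]) / nchar(bait_protein)
      }
    }
  }
  status <- orf_status(orf$has_start, orf$has_stop, cov, bait_coverage)
  mh <- if (!is.null(motif)) scan_motif(orf$protein, motif) else NULL
  tm <- predict_tm(orf$protein)
  dom <- partition_domains(orf$protein, tm)
  structure(list(orf_range = c(orf$start, orf$end), strand = orf$strand,
                 protein = orf$protein, complete5 = orf$has_start,
                 complete3 = orf$has_stop, coverage = cov, status = status,
                 motif_hits = mh, tm_segments = tm, domains = dom),
            class = "gene_annotation")
}

#' Scan a protein with a PROSITE-syntax pattern
#'
#' Supports the common PROSITE constructs: elements separated by `-`; `x`
#' any residue; `[ABC]` alternatives; `{ABC}` exclusions; `(n)` / `(n,m)`
#' repetition; `<` / `>` anchors. Matches are non-overlapping, leftmost
#' first.
#'
#' @param protein amino-acid sequence.
#' @param pattern PROSITE pattern, e.g. `"G-x-G"` or `"[LV]-x(2)-{P}-G"`.
#' @return data frame with 0-based half-open `start`, `end` and the matched
#'   substring.
#' @examples
#' scan_motif("AGAGA", "G-x-G") # one match at [1, 4)
#' @export
scan_motif <- function(protein, pattern) {
  rx <- prosite_to_regex(pattern)
  m <- gregexpr(rx, protein, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len,
             match = substring(protein, m, m + len - 1),
             stringsAsFactors = FALSE)
}

prosite_to_regex <- function(pattern) {
  pattern <- sub("\\.$", "", trimws(pattern))
  anchored_start <- startsWith(pattern, "<")
  anchored_end <- endsWith(pattern, ">")
  pattern <- sub("^<", "", sub(">$", "", pattern))
  toks <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  one <- function(tok) {
    rep_rx <- ""
    m <- regmatches(tok, regexec("\\(([0-9]+)(,([0-9]+))?\\)$", tok))[[1]]
    if (length(m)) {
      rep_rx <- if (m[4] == "") paste0("{", m[2], "}")
                else paste0("{", m[2], ",", m[4], "}")
      tok <- sub("\\([0-9]+(,[0-9]+)?\\)$", "", tok)
    }
    core <- if (tok == "x" || tok == "X") "."
      else if (grepl("^\\[[A-Za-z]+\\]$", tok)) tok
      else if (grepl("^\\{[A-Za-z]+\\}$", tok))
        paste0("[^", substring(tok, 2, nchar(tok) - 1), "]")
      else if (grepl("^[A-Za-z]$", tok)) tok
      else stop("unsupported PROSITE element: ", tok, call. = FALSE)
    paste0(core, rep_rx)
  }
  rx <- paste(vapply(toks, one, ""), collapse = "")
  if (anchored_start) rx <- paste0("^", rx)
  if (anchored_end) rx <- paste0(rx, "$")
  rx
}

#' Default TNF-superfamily motif pattern
#'
#' The conserved C-terminal signature of TNF-family ligands in PROSITE
#' syntax, shipped as a configurable default rather than hard-coded into
#' the annotation stage.
#' @export
tnf_motif_pattern <- function() {
  "[LV]-x-[LIVM]-x(3)-G-[LIVMF]-Y-[LIVMFY]-[LIVMFY]-x(2)-[QEKHL]-[LIVMGT]-x-[LIVMFY]"
}

# Kyte-Doolittle hydropathy values
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by sliding-window hydropathy
#'
#' A window-centered Kyte-Doolittle mean is computed at every position with
#' a full window; maximal runs of positions with mean hydropathy at or
#' above `threshold` are expanded to the underlying window span, clipped to
#' the protein, and reported when at least `min_len` residues long. This is
#' a deliberately simple hydropathy stand-in for dedicated HMM-based
#' topology predictors.
#'
#' @param protein amino-acid sequence.
#' @param window odd window length, aa.
#' @param threshold mean hydropathy cutoff.
#' @param min_len minimum reported segment length, aa.
#' @return data frame of 0-based half-open aa ranges.
#' @export
predict_tm <- function(protein, window = 19L, threshold = 1.6, min_len = 15L) {
  ch <- strsplit(protein, "")[[1]]
  h <- unname(KD_SCALE[ch])
  h[is.na(h)] <- 0
  n <- length(h)
  if (n < window)
    return(data.frame(start = integer(0), end = integer(0)))
  cs <- c(0, cumsum(h))
  centers0 <- (window %/% 2):(n - 1L - window %/% 2) # 0-based centers
  means <- (cs[centers0 + window %/% 2 + 2L] -
            cs[centers0 - window %/% 2 + 1L]) / window
  hot <- means >= threshold
  if (!any(hot)) return(data.frame(start = integer(0), end = integer(0)))
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  seg <- data.frame(start = integer(0), end = integer(0))
  for (k in which(r$values)) {
    c0 <- centers0[starts[k]]
    c1 <- centers0[ends[k]]
    s <- max(0L, c0 - window %/% 2L)
    e <- min(n, c1 + window %/% 2L + 1L)
    if (e - s >= min_len)
      seg <- rbind(seg, data.frame(start = s, end = e))
  }
  seg
}

#' Partition a protein into domains under type-II membrane topology
#'
#' TNF-family ligands are type-II transmembrane proteins: intracellular
#' N-terminus, one transmembrane helix, extracellular C-terminus. With no
#' predicted TM segment the whole protein is reported extracellular with a
#' warning; with more than one segment the partition is flagged for manual
#' review.
#'
#' @param protein amino-acid sequence.
#' @param tm_segments data frame from [predict_tm()].
#' @return list with 0-based half-open `intracellular`, `transmembrane`,
#'   `extracellular` ranges (NULL when absent) and a `flag`.
#' @export
partition_domains <- function(protein, tm_segments) {
  L <- nchar(protein)
  if (is.null(tm_segments) || nrow(tm_segments) == 0) {
    warning("no transmembrane segment predicted; whole protein reported extracellular")
    return(list(intracellular = NULL, transmembrane = NULL,
                extracellular = c(0L, L), flag = "no_tm"))
  }
  if (nrow(tm_segments) > 1) {
    return(list(intracellular = NULL, transmembrane = NULL,
                extracellular = NULL, flag = "multiple_tm"))
  }
  s <- tm_segments$start[1]; e <- tm_segments$end[1]
  list(intracellular = if (s > 0) c(0L, s) else NULL,
       transmembrane = c(s, e),
       extracellular = if (e < L) c(e, L) else NULL,
       flag = "ok")
}

#' Write ORF, motif and TM features as GFF3
#'
#' @param ann a `gene_annotation` from [annotate_gene()].
#' @param contig_id sequence id to report in column 1.
#' @param file output path.
#' @export
write_gff3 <- function(ann, contig_id, file) {
  rows <- list(sprintf("%s\tgcrescue\tCDS\t%d\t%d\t.\t%s\t0\tID=orf1;status=%s",
                       contig_id, ann$orf_range[1] + 1L, ann$orf_range[2],
                       ann$strand, ann$status))
  aa2nt <- function(r) ann$orf_range[1] + 3L * r # forward-strand ORFs only
  if (!is.null(ann$motif_hits) && nrow(ann$motif_hits) > 0 && ann$strand == "+")
    for (i in seq_len(nrow(ann$motif_hits)))
      rows <- c(rows, sprintf("%s\tgcrescue\tsequence_motif\t%d\t%d\t.\t+\t.\tID=motif%d",
                              contig_id, aa2nt(ann$motif_hits$start[i]) + 1L,
                              aa2nt(ann$motif_hits$end[i]), i))
  if (!is.null(ann$tm_segments) && nrow(ann$tm_segments) > 0 && ann$strand == "+")
    for (i in seq_len(nrow(ann$tm_segments)))
      rows <- c(rows, sprintf("%s\tgcrescue\ttransmembrane_helix\t%d\t%d\t.\t+\t.\tID=tm%d",
                              contig_id, aa2nt(ann$tm_segments$start[i]) + 1L,
                              aa2nt(ann$tm_segments$end[i]), i))
  writeLines(c("##gff-version 3", unlist(rows)), file)
  invisible(file)
}
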