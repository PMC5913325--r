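#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings that present sequences as named character
#' vectors, the representation used throughout the package. Readers are
#' gzip-transparent and accept CRLF line endings; `write_fasta()` wraps
#' sequences at 60 columns.
#'
#' @param file path to a FASTA file (optionally gzipped on read).
#' @param seqs named character vector of sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(file) {
  ss <- Biostrings::readBStringSet(file)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, file) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0) next
    starts <- seq(1, n, by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, n)), con)
  }
  invisible(file)
}

#' Read and write FASTQ files
#'
#' A validating four-line-record FASTQ reader/writer. The reader is
#' gzip-transparent, accepts CRLF input, and reports a parse error naming
#' the offending record when a sequence and its quality string differ in
#' length or a record header is malformed. Returned reads are a `read_set`
#' data frame with columns `id`, `seq` and `qual`.
#'
#' @param file path to a FASTQ file (optionally gzipped on read).
#' @param reads a data frame with columns `id` and `seq` (and optionally
#'   `qual`; a constant Q30 placeholder is written when absent).
#' @return `read_fastq()` returns a `read_set` data frame.
#' @export
read_fastq <- function(file) {
  ln <- sub("\r$", "", readLines(file))
  if (length(ln) %% 4 != 0)
    stop("malformed FASTQ '", file, "': ", length(ln),
         " lines is not a multiple of 4", call. = FALSE)
  n <- length(ln) / 4
  hd <- ln[seq(1, length(ln), 4)]
  sq <- ln[seq(2, length(ln), 4)]
  pl <- ln[seq(3, length(ln), 4)]
  ql <- ln[seq(4, length(ln), 4)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stop("malformed FASTQ record '", hd[bad[1]], "' (record ", bad[1],
         " in ", file, ")", call. = FALSE)
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop("FASTQ record '", sub("^@", "", hd[bad[1]]),
         "': sequence and quality lengths differ (", nchar(sq[bad[1]]),
         " vs ", nchar(ql[bad[1]]), ")", call. = FALSE)
  read_set(id = sub("\\s.*$", "", sub("^@", "", hd)),
           seq = toupper(sq), qual = ql)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, file) {
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("?", n), "") # '?' = Q30
  writeLines(as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual)),
             file)
  invisible(file)
}

#' Construct a read set
#'
#' A read set is a plain data frame (`id`, `seq`, `qual`) with class
#' `read_set`; it is what the simulator emits, the recruitment stage
#' filters, and the assembler consumes.
#'
#' @param id,seq,qual character vectors of equal length (`qual` optional).
#' @export
read_set <- function(id, seq, qual = NULL) {
  if (is.null(qual)) qual <- vapply(nchar(seq), function(n) strrep("?", n), "")
  structure(data.frame(id = as.character(id), seq = toupper(seq),
                       qual = qual, stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write local-search hits as a 12-column tab-separated table
#'
#' Column layout follows the familiar tabular BLAST convention
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, raw score, percent
#' similarity), except that coordinates stay 0-based half-open and the last
#' two columns carry the raw score and percent similarity instead of
#' E-value and bit score, which this package does not compute.
#'
#' @param hsps a data frame of hits as returned by [search_hsps()].
#' @param file output path.
#' @export
write_hsp_tsv <- function(hsps, file) {
  aln_len <- nchar(hsps$query_aln)
  gapopens <- vapply(gregexpr("-+", paste0(hsps$query_aln, "x", hsps$subject_aln)),
                     function(g) if (g[1] == -1) 0L else length(g), 0L)
  tab <- data.frame(hsps$query_id, hsps$subject_id,
                    sprintf("%.2f", hsps$percent_identity), aln_len,
                    round(aln_len * (1 - hsps$percent_identity / 100)),
                    gapopens, hsps$query_start, hsps$query_end,
                    hsps$subject_start, hsps$subject_end,
                    hsps$raw_score, sprintf("%.2f", hsps$percent_similarity))
  write.table(tab, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read and write BED-like gene tables
#'
#' Tab-separated with header columns `id`, `chrom`, `start`, `end`,
#' `strand` (0-based half-open, strand "+"/"-"); protein sequences live in
#' a companion FASTA keyed by gene id and are attached as a `protein`
#' column.
#'
#' @param file TSV path.
#' @param protein_fasta optional FASTA path with one protein per gene id.
#' @export
read_gene_table <- function(file, protein_fasta = NULL) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table must have columns ", paste(need, collapse = ", "))
  if (!is.null(protein_fasta)) {
    prot <- read_fasta(protein_fasta)
    tab$protein <- unname(prot[tab$id])
  }
  gene_table(tab)
}

#' @rdname read_gene_table
#' @param tab a data frame with the columns above (plus optional `protein`).
#' @export
gene_table <- function(tab) {
  stopifnot(all(tab$start < tab$end), !anyDuplicated(tab$id))
  structure(as.data.frame(tab), class = c("gene_table", "data.frame"))
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(tab, file) {
  write.table(tab[setdiff(names(tab), "protein")], file, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(file)
}
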