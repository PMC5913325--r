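#!/usr/bin/env Rscript
# Annotate the recovered contig: ORF completeness against the bait,
# superfamily motif scan, hydropathy-based transmembrane prediction, and
# type-II domain partition.

library(gcrescue)

seed <- 1L
out <- "results/annotation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ref <- make_reference(gene_spec(), seed = seed)
contig <- read_fasta("results/recovery/contig.fasta")[[1]]
bait <- read_fasta("results/recovery/bait.faa")[[1]]

ann <- annotate_gene(contig, bait, motif = tnf_motif_pattern())
cat(sprintf("ORF [%d, %d) strand %s: %d aa, status %s (bait coverage %.2f)\n",
            ann$orf_range[1], ann$orf_range[2], ann$strand,
            nchar(ann$protein), ann$status, ann$coverage))
cat(sprintf("protein identical to planted truth: %s\n",
            identical(ann$protein, ref$protein)))
if (nrow(ann$motif_hits) > 0)
  cat(sprintf("motif hit at aa [%d, %d): %s\n", ann$motif_hits$start[1],
              ann$motif_hits$end[1], ann$motif_hits$match[1]))
if (nrow(ann$tm_segments) > 0) {
  cat(sprintf("TM segment at aa [%d, %d)\n", ann$tm_segments$start[1],
              ann$tm_segments$end[1]))
} else cat("no TM segment predicted (random synthetic protein need not have one)\n")

write_gff3(ann, "contig", file.path(out, "annotation.gff3"))
write_fasta(c(candidate_protein = ann$protein), file.path(out, "protein.faa"))
sim <- percent_similarity(ann$protein, bait)
cat(sprintf("candidate vs bait: %.1f%% identity, %.1f%% similarity\n",
            sim$identity, sim$similarity))
cat("wrote", out, "\n")
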