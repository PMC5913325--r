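#!/usr/bin/env Rscript
# Synteny verification logic: reciprocal-best-hit ortholog assignment
# between a candidate locus and a reference locus, then gene order and
# orientation concordance.

library(gcrescue)

seed <- 1L
out <- "results/synteny"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

loc <- gcrescue:::make_toy_locus(ph_seed = seed, n_genes = 10)
pairs <- assign_orthologs(loc$query, loc$reference)
res <- compare_order(pairs, loc$query, loc$reference)
cat(sprintf("RBH pairs: %d of %d genes; order concordance %.2f; orientation agreement %.2f\n",
            res$shared_count, nrow(loc$query), res$order_concordance,
            res$orientation_agreement))

# the literal one-way best-hit criterion for comparison
ow <- assign_orthologs(loc$query, loc$reference, one_way = TRUE)
cat(sprintf("one-way best hits: %d (RBH is the stricter default)\n", nrow(ow)))

write_gene_table(loc$query, file.path(out, "query_genes.tsv"))
write_gene_table(loc$reference, file.path(out, "reference_genes.tsv"))
write_synteny(res, file.path(out, "pairs.tsv"), file.path(out, "summary.json"))
cat("wrote", out, "\n")
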