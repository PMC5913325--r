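# gcrescue

Targeted recovery and verification of GC-rich "missing" genes from
short-read data.

Extremely GC-rich genes can be effectively invisible to short-read
sequencing: library preparation and sequencing chemistry deplete GC-rich
fragments, so the locus gets a fraction of its expected coverage and
assemblers either omit it or emit artifacts (long homopolymer runs,
truncated ends). Such genes end up "missing" from genome assemblies and
annotations even though they are present and expressed — a recurrent
situation in avian genomes, where several immune genes were long thought
absent. `gcrescue` is for researchers who suspect a gene is missing rather
than absent and want to pull it out of deep short-read datasets, then
verify that what they recovered is a genuine ortholog.

## The method

The core is bait-seeded iterative assembly. Given a diverged ortholog
protein $B$ and a read set $R$:

1. **Recruit** reads by translated local search of $B$ against all six
   frames of every read: exact 4-mer seeds, banded Smith–Waterman
   extension with affine gaps under BLOSUM62, raw score ≥ 40.
2. **Assemble** recruited reads by greedy overlap-layout-consensus:
   repeatedly merge the pair with the longest suffix–prefix overlap
   (≥ 25 nt, mismatch fraction ≤ 0.05); consensus is the support-weighted
   majority base.
3. **Promote** the best contig (highest bait similarity, then longest) to
   the new bait and recruit again, now by exact nucleotide 21-mers
   (≥ 2 shared, either strand).
4. **Stop** when the open reading frame is complete — initiator ATG,
   in-frame stop, and a bait alignment covering ≥ 90% of the bait — or
   when recruitment stalls.

Verification stages around the core: sliding-window GC profiles and a
rank-sum GC contrast between sequence groups; ORF annotation with a
PROSITE-style motif scan, Kyte–Doolittle transmembrane prediction and
type-II domain partition; progressive protein alignment with a
strictly-more-than-80%-gap column filter, Poisson-corrected p-distances
($d = -\ln(1-p)$), neighbor joining and 1,000-replicate bootstrap;
reciprocal-best-hit synteny with Kendall-tau order concordance; and
artifact QC reporting exact homopolymer runs and terminal deficits
against a trusted reference.

A synthetic-data module generates the study system — an 858-nt, four-exon
CDS at GC 0.66 planted in a GC 0.42 background, with GC-bias-dropout read
simulation (start-position weight $e^{-\lambda\,\max(0,\mathrm{GC}-0.5)}$)
— so the entire pipeline runs and is tested without any downloads.

All coordinates are 0-based, half-open. Strands are `+`/`-`.

## Worked example

```r
library(gcrescue)

ref   <- make_reference(gene_spec(), seed = 1)      # plant the gene
reads <- simulate_reads(ref$transcript,
                        sim_config(depth = 60, error_rate = 0.005, seed = 2))
bait  <- mutate_protein(ref$protein, identity = 0.7, seed = 3)

rec <- iterate_recovery(bait, reads)
rec$state$status                      # "orf_complete"
nchar(rec$contig$sequence)            # 962
grepl(ref$cds, rec$contig$sequence, fixed = TRUE)   # TRUE

ann <- annotate_gene(rec$contig$sequence, bait, motif = tnf_motif_pattern())
nchar(ann$protein)                    # 285
identical(ann$protein, ref$protein)   # TRUE
```

The numbered scripts under `analysis/` run the full study:
`01_simulate.R` builds the reference and read sets (CDS coverage 71.8×
unbiased vs 47.2× at λ = 8, both nominal 60×); `02_recover.R` reaches
`orf_complete` in one round with a 962-nt contig from 554 recruited reads
whose CDS is identical to the truth; `03_annotate.R` reports the 285-aa
protein (69.8% identity / 73.3% similarity to the bait); `04_gc_profile.R`
flags the 0.65-vs-0.48 GC contrast in 100/100 seeded draws;
`05_phylo.R` recovers the planted clade as monophyletic with bootstrap
supports of 89–100; `06_synteny.R` pairs 10/10 genes by RBH at order
concordance 1.0; `07_artifact_qc.R` reports a 216-nt 5' deficit and the
planted poly-G insertion on the artifact fixture while passing the
verified sequence; and `08_depth_sweep.R` shows the dataset-size phase
change under strong bias — success rates 0.00 / 0.95 / 1.00 / 1.00 at
nominal depths 5× / 20× / 80× / 200× (20 seeds each). Each script writes
its tables under `results/`.

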