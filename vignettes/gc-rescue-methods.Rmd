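---
title: "Recovering GC-rich missing genes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering GC-rich missing genes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcrescue)
```

## The problem

Some genes are "missing": present in the genome and expressed, but absent
from assemblies and annotations because their extreme GC content makes them
nearly invisible to short-read sequencing. Library preparation and
sequencing chemistry deplete GC-rich fragments, so the locus receives a
small fraction of its expected coverage; assemblers then either drop it or
produce characteristic artifacts (long homopolymer runs, truncated ends).
Avian genomes, with their pockets of exceptionally GC-rich sequence, are
the classic setting, and immune genes such as TNF-family cytokines are
prominent casualties.

The rescue strategy implemented here is targeted, not global. A diverged
ortholog protein from another lineage serves as a bait; the few reads that
do cover the locus are recruited by translated homology; recruited reads
are assembled by greedy overlap consensus; and the growing contig is
promoted to the new bait for further rounds of nucleotide-level
recruitment, until the open reading frame is complete or no further signal
exists. The remaining modules verify that a recovered candidate behaves
like a genuine ortholog: its GC signature, its placement in a protein
phylogeny, conservation of its genomic neighborhood, and the absence of
assembly-artifact signatures.

## The synthetic study system

Every stage is exercised on synthetic data, so the whole pipeline is
testable offline. `gene_spec()` plants a protein-coding gene with
controlled GC in a lower-GC background; the defaults mirror the motivating
case: an 858-nt CDS (285 residues plus stop) in four exons at GC 0.66,
with introns, flanks and UTRs at GC 0.42. The CDS generator samples codons
at the target GC, rejects in-frame stops, and then repairs single bases
(A<->G, T<->C, never creating a stop) until the GC count is exact;
infeasible targets (start and stop codons bound the achievable range) are
an error rather than a silent approximation.

Reads are simulated from the spliced transcript plus 300 nt of
untranslated flank on each side. The flank length is a deliberate
condition: the bias model weighs candidate read start positions by
footprint GC, so if the template were almost entirely CDS, re-weighting
would merely renormalize within the gene. With a ~40% background fraction
the gene body is genuinely depleted — about 2-fold at the default strong
bias — while total dataset size stays fixed, which is the phenomenon of
interest. Splice-aware alignment is out of scope, so recovery operates on
transcript-derived reads; the genomic sequence (with introns) is still
emitted for GC profiling and coordinate truth.

### The bias model

Start positions are drawn with weight

$$ w(\mathrm{GC}) = \exp(-\lambda \cdot \max(0, \mathrm{GC} - p)) $$

where GC is the fraction over the read's footprint (ambiguous bases
excluded from numerator and denominator), $p = 0.5$ is the pivot and
$\lambda \ge 0$ the strength. The literature documents severe
underrepresentation but no usable dose-response curve, so the functional
form is this package's choice, picked for having a single interpretable
parameter and reducing exactly to uniform sampling at $\lambda = 0$.
$\lambda = 8$ — the value used in the depth-sweep experiments — puts a
0.66-GC window at 28% of the weight of a sub-pivot window, and is read as
"strong bias", not as a calibrated instrument constant.

Reads are reverse-complemented with probability 0.5 and receive i.i.d.
substitution errors (default 0.5%); indel errors, PCR duplicates and
insert-size structure are deliberately not modeled. Qualities are written
as a constant Q30 placeholder since no stage consumes them. The read count
is exactly `round(depth * L / read_length)`, so simulated bases are
conserved exactly.

## Search, assembly, iteration

The probe stage is a seeded local search: exact k-mer seeds (4 aa / 12 nt)
between bait and target, then banded Smith–Waterman extension with affine
gaps (gap of length $L$ costs `gap_open` $+ L \cdot$ `gap_ext`; BLOSUM62
for proteins, +2/−3 for DNA). The band (half-width 16 columns, configurable)
spans all seed diagonals, so on short targets the result is in practice the
exact local optimum — the test suite asserts equality with an independent
full-DP oracle. E-values are not computed; a raw-score threshold is the
reporting criterion, which avoids statistical calibration that nothing
downstream needs. Symbols outside the matrix alphabet (N, X, stops) score
zero against everything. One best local alignment is reported per
(target, frame).

Assembly is greedy overlap-layout-consensus, chosen over de Bruijn graphs
because it mirrors how such genes are assembled interactively, is fully
deterministic, and is auditable merge by merge: always join the pair with
the longest suffix–prefix overlap (≥ 25 nt, mismatch fraction ≤ 0.05),
ties broken by overlap identity and then by the lexicographically smaller
pair of read ids; consensus is the support-weighted majority with
alphabetic tie-break. Identical reads are collapsed with multiplicity
before overlap discovery, which feeds the same majority vote at much lower
cost.

The iteration recruits by translated search in round 1 (raw score ≥ 40)
and by exact nucleotide k-mers against the current contig afterwards
(k = 21, ≥ 2 shared, either strand; recruits are oriented to the bait
strand before assembly). The loop is monotone — the recruited set only
grows — and terminates in one of three states: `orf_complete`, `stalled`
(no new reads, or contig growth under 5 nt in a round), or `max_rounds`
(default 20). All randomness lives in the simulator; recovery itself is
deterministic.

"Complete ORF" is defined operationally as the conjunction of two readings:
the ORF has an initiator ATG and an in-frame stop, *and* the bait
alignment covers at least 90% of the bait (configurable). Coverage alone
would accept stop-less fragments; start/stop alone would accept any short
spurious ORF. The 90% default tolerates diverged termini without admitting
half genes. ORF start codons are resolved by homology: when a stop-free
segment contains several in-frame ATGs, the one closest to the
bait-implied protein start is chosen, which prevents a random upstream
ATG in the UTR from inflating the protein.

## Verification stages

**GC profiling.** Windowed GC (defaults 100/50, declared rather than
inferred from any published figure) and a group contrast: per-group mean
GC plus a one-sided Wilcoxon rank-sum test, flagged at p < 0.05. The test
is descriptive — the underlying claim is graphical in origin — and single
member groups report means only.

**Phylogenetic placement.** A deliberately simple, fully in-repo stack:
progressive alignment (3-mer distance, average-linkage guide tree,
profile–profile global alignment with affine gaps; ids sorted before
guide-tree construction so input order is irrelevant), removal of columns
with *strictly more than* 80% gaps, Poisson-corrected p-distances
$d = -\ln(1-p)$ over mutually ungapped columns (p capped at 0.95 with a
warning; pairs sharing < 20 columns flagged), neighbor joining with a
deterministic smallest-(i,j) tie-break and negative branch estimates
clamped to zero, and column-resampling bootstrap (default 1,000
replicates) with supports as internal node labels. This replaces
maximum-likelihood inference: the placement claims being verified are
topological (is the candidate inside the expected clade when rooted on an
outgroup?), and NJ provably recovers additive distances — a property the
test suite checks against exhaustive least-squares search over all
topologies for up to six taxa. Rate heterogeneity and model selection are
out of scope.

**Synteny.** Ortholog assignment is reciprocal best hit over the seeded
protein search — stricter than the one-directional best hit the original
analysis used; `one_way = TRUE` restores the literal criterion. Gene-order
concordance is a Kendall tau over the ranks of paired genes, orientation
agreement the fraction of strand-consistent pairs; when raw concordance is
negative a globally flipped view is also reported, since a translocated
segment may be inverted as a unit.

**Artifact QC.** Exact maximal homopolymer runs (flag threshold 15 nt —
beyond common Illumina homopolymer fidelity, and configurable) and a
global alignment of candidate against a trusted reference reporting 5'/3'
terminal deficits and internal query-only insertions ≥ 10 nt (the minimum
block filters out ordinary single-base indels). On error-free fixtures
these reports are exact by construction, and the tests hold them to that.

## Problem sizes and determinism

The shipped experiments use the full default gene (858 nt, four exons) with
100-nt reads. Success-rate experiments run 20 seeded replicates per
condition; the depth sweep covers nominal depths 5, 20, 80 and 200 under
$\lambda = 8$; oracle-equality checks use 200 random bait/target pairs of
length ≤ 60; NJ recovery uses 100 random additive matrices with 4–8 taxa;
the GC contrast uses 100 draws of 8 + 8 sequences of 500 nt. Every
stochastic quantity is reproducible from a single integer seed, and every
deterministic stage is byte-stable, which the tests assert on output
digests.

## What passing does and does not show

The simulator emulates GC-dependent start-position dropout, substitution
error and both read orientations. It does not emulate coverage
autocorrelation, fragment-level GC effects on both mates, indels,
chimeras, or transcript abundance variation, and the planted gene sits in
a random — not compositionally structured — background. Success on
synthetic data therefore demonstrates that the method's logic is sound
and its implementation exact, not that any particular real dataset will
yield a complete ORF; on real data the binding constraint is whether the
dataset contains enough GC-rich fragments at all, which is exactly the
dataset-size dependence the depth-sweep experiment reproduces. The
accession-based checks (translating a deposited CDS and comparing
extracellular domains against a mammalian ortholog) require the user to
supply the public records as FASTA files; see `check_accession_targets()`.

## Known limitations

Paired-end information is ignored; consensus is quality-blind; the
aligner is a progressive heuristic without iterative refinement; the
transmembrane predictor is a hydropathy window (Kyte–Doolittle, window 19,
threshold 1.6, minimum segment 15 aa) standing in for HMM-based topology
prediction, and type-II topology is asserted rather than inferred. These
are acceptable because each plays a verification role with generous
margins, not a discovery role.
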