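#' Specification of a planted GC-rich multi-exon gene
#'
#' Describes the synthetic locus the simulator builds: a protein-coding gene
#' whose CDS has a controlled (typically high) GC fraction, split over
#' `n_exons` exons separated by introns of background composition, embedded
#' in flanking background sequence. The defaults mirror the recovered avian
#' cytokine gene: an 858-nt CDS (285 amino acids plus stop) in four exons at
#' GC 0.66, in a 0.42-GC background.
#'
#' @param cds_length CDS length in nucleotides; must be a multiple of 3.
#' @param n_exons number of exons (> 0).
#' @param gc_target CDS GC fraction in [0, 1]; realized CDS GC is exact to
#'   the base after repair, hence always within 0.03 of the target, or an
#'   error is thrown when start/stop codons make the target infeasible.
#' @param background_gc GC fraction of flanks, introns and UTRs.
#' @param flank_length background flank on each side of the gene, nt.
#' @param intron_lengths integer vector of length `n_exons - 1`.
#' @param utr_length untranslated sequence carried into the transcript on
#'   each side of the CDS (capped at `flank_length`), nt.
#' @return an object of class `gene_spec`.
#' @examples
#' gene_spec()
#' gene_spec(cds_length = 300, n_exons = 1, intron_lengths = integer(0))
#' @export
gene_spec <- function(cds_length = 858L, n_exons = 4L, gc_target = 0.66,
                      background_gc = 0.42, flank_length = 300L,
                      intron_lengths = rep(200L, max(0L, n_exons - 1L)),
                      utr_length = 300L) {
  if (cds_length %% 3 != 0) stop("cds_length must be a multiple of 3")
  if (n_exons < 1) stop("n_exons must be positive")
  if (length(intron_lengths) != n_exons - 1)
    stop("need exactly n_exons - 1 intron lengths")
  if (gc_target < 0 || gc_target > 1 || background_gc < 0 || background_gc > 1)
    stop("GC fractions must lie in [0, 1]")
  structure(list(cds_length = as.integer(cds_length),
                 n_exons = as.integer(n_exons), gc_target = gc_target,
                 background_gc = background_gc,
                 flank_length = as.integer(flank_length),
                 intron_lengths = as.integer(intron_lengths),
                 utr_length = as.integer(min(utr_length, flank_length))),
            class = "gene_spec")
}

#' GC-dependent sampling-bias model for the read simulator
#'
#' Read start positions are drawn with weight
#' `w(GC) = exp(-lambda_bias * max(0, GC - gc_pivot))`, where GC is the GC
#' fraction of the read's genomic footprint (ambiguous bases excluded from
#' numerator and denominator). `lambda_bias = 0` recovers uniform sampling;
#' weights always lie in (0, 1]. The exponential-penalty form is this
#' package's one-parameter model of the empirical observation that GC-rich
#' fragments are strongly underrepresented in Illumina data.
#'
#' @param lambda_bias dimensionless penalty strength, >= 0.
#' @param gc_pivot GC fraction above which the penalty applies.
#' @param window window size, nt, used by GC-profile defaults.
#' @export
bias_model <- function(lambda_bias = 0, gc_pivot = 0.5, window = 100L) {
  stopifnot(lambda_bias >= 0, gc_pivot >= 0, gc_pivot <= 1)
  structure(list(lambda_bias = lambda_bias, gc_pivot = gc_pivot,
                 window = as.integer(window)), class = "bias_model")
}

#' Read-simulation configuration
#'
#' @param depth mean fold coverage (> 0); the number of reads is
#'   `round(depth * genome_length / read_length)`.
#' @param read_length read length, nt.
#' @param error_rate i.i.d. substitution rate per base, in [0, 0.25).
#' @param seed integer RNG seed; identical (template, config, bias, seed)
#'   give byte-identical output.
#' @export
sim_config <- function(depth = 30, read_length = 100L, error_rate = 0.005,
                       seed = 1L) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 0.25, read_length >= 1)
  structure(list(depth = depth, read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Build a synthetic reference with a planted GC-rich gene
#'
#' Constructs the genomic sequence (flank + exons/introns + flank), the
#' spliced transcript (UTR + CDS + UTR), and a truth annotation with exact
#' 0-based half-open coordinates. The CDS starts with ATG, ends with a stop
#' codon, contains no internal stop in frame, and its GC count is repaired
#' to the exact target rounding of `gc_target * cds_length`.
#'
#' @param spec a [gene_spec()].
#' @param seed integer seed; identical (spec, seed) give identical output.
#' @return a list with elements `genome`, `transcript`, `cds`, `protein`,
#'   `exons` (data frame: feature, start, end, strand on the genome),
#'   `cds_transcript_range` (0-based half-open on the transcript), and the
#'   spec used.
#' @examples
#' ref <- make_reference(gene_spec(cds_length = 300, n_exons = 2,
#'                                 intron_lengths = 80L), seed = 1)
#' nchar(ref$protein) # 99 residues, stop excluded
#' @export
make_reference <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "gene_spec"))
  with_seed(seed, {
    cds <- make_cds(spec$cds_length, spec$gc_target)
    # split CDS into exons (boundaries need not respect codons)
    sizes <- rep(spec$cds_length %/% spec$n_exons, spec$n_exons)
    extra <- spec$cds_length %% spec$n_exons
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    ends <- cumsum(sizes)
    starts <- c(0L, head(ends, -1L))
    exon_seqs <- substring(cds, starts + 1L, ends)
    introns <- vapply(spec$intron_lengths, random_dna, "",
                      gc = spec$background_gc)
    flank5 <- random_dna(spec$flank_length, spec$background_gc)
    flank3 <- random_dna(spec$flank_length, spec$background_gc)
    pieces <- character(0)
    pos <- spec$flank_length
    exons <- data.frame(feature = "exon", start = integer(spec$n_exons),
                        end = integer(spec$n_exons), strand = "+",
                        stringsAsFactors = FALSE)
    for (i in seq_len(spec$n_exons)) {
      exons$start[i] <- pos
      exons$end[i] <- pos + sizes[i]
      pieces <- c(pieces, exon_seqs[i])
      pos <- pos + sizes[i]
      if (i < spec$n_exons) {
        pieces <- c(pieces, introns[i])
        pos <- pos + spec$intron_lengths[i]
      }
    }
    genome <- paste0(flank5, paste(pieces, collapse = ""), flank3)
    u <- spec$utr_length
    utr5 <- if (u > 0) substring(flank5, spec$flank_length - u + 1L) else ""
    utr3 <- if (u > 0) substring(flank3, 1L, u) else ""
    transcript <- paste0(utr5, cds, utr3)
    protein <- translate_cds(cds)
    list(genome = genome, transcript = transcript, cds = cds,
         protein = protein, exons = exons,
         cds_transcript_range = c(nchar(utr5), nchar(utr5) + spec$cds_length),
         spec = spec)
  })
}

# CDS with exact GC count, ATG start, TGA stop, no internal in-frame stop
make_cds <- function(cds_length, gc_target) {
  n_codons <- cds_length %/% 3L
  if (n_codons < 2) stop("cds_length too short for start and stop codons")
  target_gc <- round(gc_target * cds_length)
  internal <- cds_length - 6L
  # ATG and TGA each contribute exactly one G/C
  if (target_gc < 2 || target_gc > internal + 2)
    stop("infeasible gc_target: start/stop codons force GC count into [2, ",
         internal + 2, "] of ", cds_length, " nt", call. = FALSE)
  p <- (target_gc - 2) / internal
  body <- character(n_codons - 2L)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_along(body)) {
    repeat {
      cod <- paste(sample(DNA_BASES, 3, replace = TRUE,
                          prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
                   collapse = "")
      if (!(cod %in% stops)) break
    }
    body[i] <- cod
  }
  cds <- strsplit(paste0("ATG", paste(body, collapse = ""), "TGA"), "")[[1]]
  # repair realized GC to the exact target without creating in-frame stops
  repeat {
    have <- sum(cds %in% c("G", "C"))
    if (have == target_gc) break
    idx <- sample(4:(cds_length - 3L)) # internal positions only
    changed <- FALSE
    for (i in idx) {
      old <- cds[i]
      new <- if (have < target_gc) {
        if (old == "A") "G" else if (old == "T") "C" else next
      } else {
        if (old == "G") "A" else if (old == "C") "T" else next
      }
      cds[i] <- new
      cstart <- i - (i - 1L) %% 3L
      if (paste(cds[cstart:(cstart + 2L)], collapse = "") %in% stops) {
        cds[i] <- old
        next
      }
      changed <- TRUE
      break
    }
    if (!changed)
      stop("could not repair CDS GC to target without creating stop codons")
  }
  paste(cds, collapse = "")
}

translate_cds <- function(cds) {
  sub("\\*$", "", translate_frame(cds, 1L))
}

#' Simulate GC-bias-dropout short reads
#'
#' Draws exactly `round(depth * L / read_length)` reads from a template
#' sequence. Start positions are sampled proportional to the bias weight of
#' each read's footprint GC (see [bias_model()]); each read is
#' reverse-complemented with probability 0.5, and i.i.d. substitution errors
#' are applied at `error_rate`. Total simulated bases equal
#' `n_reads * read_length` exactly.
#'
#' @param genome template nucleotide sequence (a genome, transcript, or any
#'   region of interest).
#' @param cfg a [sim_config()].
#' @param bias a [bias_model()]; default is unbiased.
#' @return a [read_set()] with attributes `truth` (data frame of start,
#'   strand per read) and `n_reads`.
#' @examples
#' ref <- make_reference(gene_spec(cds_length = 300, n_exons = 1,
#'                                 intron_lengths = integer(0)), seed = 1)
#' rs <- simulate_reads(ref$transcript, sim_config(depth = 5, seed = 7))
#' nrow(rs)
#' @export
simulate_reads <- function(genome, cfg, bias = bias_model()) {
  stopifnot(inherits(cfg, "sim_config"), inherits(bias, "bias_model"))
  stopifnot_scalar_string(genome, "genome")
  L <- nchar(genome)
  if (L == 0) stop("empty genome", call. = FALSE)
  rl <- cfg$read_length
  if (rl > L) stop("read_length exceeds template length", call. = FALSE)
  n_reads <- round(cfg$depth * L / rl)
  ch <- strsplit(genome, "")[[1]]
  is_gc <- cumsum(ch %in% c("G", "C"))
  is_acgt <- cumsum(ch %in% DNA_BASES)
  starts0 <- 0:(L - rl) # 0-based candidate starts
  gc_num <- is_gc[starts0 + rl] - c(0, is_gc)[starts0 + 1L]
  gc_den <- is_acgt[starts0 + rl] - c(0, is_acgt)[starts0 + 1L]
  gc <- ifelse(gc_den > 0, gc_num / gc_den, 0)
  w <- exp(-bias$lambda_bias * pmax(0, gc - bias$gc_pivot))
  with_seed(cfg$seed, {
    st <- sample(starts0, n_reads, replace = TRUE, prob = w)
    strand <- ifelse(runif(n_reads) < 0.5, "-", "+")
    seqs <- substring(genome, st + 1L, st + rl)
    flip <- strand == "-"
    if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
    if (cfg$error_rate > 0) {
      nerr <- rbinom(n_reads, rl, cfg$error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(rl, nerr[i])
        s <- strsplit(seqs[i], "")[[1]]
        for (p in pos) s[p] <- sample(setdiff(DNA_BASES, s[p]), 1)
        seqs[i] <- paste(s, collapse = "")
      }
    }
    rs <- read_set(id = sprintf("r%06d", seq_len(n_reads)), seq = seqs)
    attr(rs, "truth") <- data.frame(start = st, strand = strand,
                                    stringsAsFactors = FALSE)
    attr(rs, "n_reads") <- n_reads
    rs
  })
}

#' Plant a homopolymer run into a sequence
#'
#' Inserts `run_length` copies of `base` at a 0-based offset; used to build
#' fixtures that mimic the long mononucleotide insertions characteristic of
#' assembly artifacts in extremely GC-rich regions.
#'
#' @param seq nucleotide sequence.
#' @param base single base to insert.
#' @param run_length number of copies (> 0).
#' @param position 0-based offset at which the run starts in the output.
#' @examples
#' plant_homopolymer("ACGT", "G", 3, 2) # "ACGGGGT"
#' @export
plant_homopolymer <- function(seq, base, run_length, position) {
  stopifnot_scalar_string(seq, "seq")
  if (run_length <= 0) stop("run_length must be positive", call. = FALSE)
  if (position < 0 || position > nchar(seq))
    stop("position out of range", call. = FALSE)
  paste0(substring(seq, 1, position), strrep(base, run_length),
         substring(seq, position + 1))
}

#' Remove the first n bases of a sequence
#'
#' Models a 5'-truncated variant of a reference sequence.
#'
#' @param seq nucleotide sequence.
#' @param n number of leading bases to remove; must be < `nchar(seq)` unless
#'   zero-length output is acceptable (n == nchar is an error).
#' @examples
#' truncate_5prime("ACGTACGT", 3) # "TACGT"
#' @export
truncate_5prime <- function(seq, n) {
  stopifnot_scalar_string(seq, "seq")
  if (n < 0 || n >= nchar(seq))
    stop("n must lie in [0, nchar(seq))", call. = FALSE)
  substring(seq, n + 1)
}

#' Derive a diverged ortholog bait from a protein
#'
#' Substitutes residues at random positions until the requested identity to
#' the input is reached; used to emulate probing with a non-avian ortholog
#' of the planted gene.
#'
#' @param protein amino-acid sequence.
#' @param identity target fractional identity of the returned bait.
#' @param seed integer seed.
#' @export
mutate_protein <- function(protein, identity = 0.7, seed = 1L) {
  with_seed(seed, {
    s <- strsplit(protein, "")[[1]]
    n_mut <- round((1 - identity) * length(s))
    pos <- sample(seq_along(s), n_mut)
    for (p in pos) s[p] <- sample(setdiff(AA20, s[p]), 1)
    paste(s, collapse = "")
  })
}

#' Simulate a protein family along a tree
#'
#' Evolves a root sequence down a phylo tree with i.i.d. substitutions at
#' `rate` expected replacements per site per unit branch length; returns the
#' tip sequences. Used to build two-clade reference sets for testing
#' phylogenetic placement.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param root_seq amino-acid sequence at the root.
#' @param rate expected substitutions per site per unit branch length.
#' @param seed integer seed.
#' @return named character vector of tip sequences.
#' @export
simulate_protein_family <- function(tree, root_seq, rate = 0.5, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- strsplit(root_seq, "")[[1]]
    # cladewise order guarantees parents are visited before children
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
      s <- seqs[[par]]
      p_sub <- 1 - exp(-rate * tr$edge.length[e])
      hit <- which(runif(length(s)) < p_sub)
      for (h in hit) s[h] <- sample(setdiff(AA20, s[h]), 1)
      seqs[[chi]] <- s
    }
    out <- vapply(seqs[seq_len(ntip)], paste, "", collapse = "")
    names(out) <- tree$tip.label
    out
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the genome and truth CDS as FASTA, the reads as FASTQ (constant
#' Q30 qualities), and the truth annotation as TSV (contig, start, end,
#' strand, feature; 0-based half-open).
#'
#' @param ref a reference from [make_reference()].
#' @param reads a [read_set()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(ref, reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(genome = ref$genome, transcript = ref$transcript),
              file.path(dir, "reference.fasta"))
  write_fasta(c(cds_truth = ref$cds, protein_truth = ref$protein),
              file.path(dir, "truth.fasta"))
  write_fastq(reads, file.path(dir, "reads.fastq"))
  ann <- data.frame(contig = "genome", start = ref$exons$start,
                    end = ref$exons$end, strand = ref$exons$strand,
                    feature = ref$exons$feature)
  write.table(ann, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
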