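#' Default end-to-end pipeline configuration
#'
#' A single nested key-value list covering every stage; amenable to YAML
#' (`yaml::write_yaml(default_config(), "config.yaml")`). The defaults run
#' a small but complete recovery-and-verification exercise in seconds.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param out_dir output directory.
#' @export
default_config <- function(seed = 1L, out_dir = "gcrescue_out") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = list(cds_length = 858L, n_exons = 4L, gc_target = 0.66,
                    background_gc = 0.42, flank_length = 300L,
                    depth = 60, read_length = 100L, error_rate = 0.005,
                    lambda_bias = 0, gc_pivot = 0.5,
                    bait_identity = 0.7),
    recover = list(max_rounds = 20L, min_score = 40),
    annotate = list(motif = tnf_motif_pattern()),
    gc = list(window = 100L, step = 50L),
    phylo = list(n_tips_per_clade = 4L, rate = 0.3, n_reps = 200L),
    synteny = list(n_genes = 6L),
    qc = list(flag_threshold = 15L)
  )
}

#' Run the full pipeline from a configuration
#'
#' Chains simulate -> recover -> annotate -> gc -> phylo -> synteny -> qc
#' on synthetic data per the configuration, logging each stage's
#' parameters and writing all outputs (FASTA/FASTQ/TSV/GFF3/newick/JSON)
#' under `config$out_dir`. Fully deterministic given (config, seed).
#'
#' @param config a list as produced by [default_config()], or a path to a
#'   YAML file with the same structure.
#' @return list of in-memory stage results (invisibly includes paths).
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  logf <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat(sprintf("gcrescue pipeline, seed %d\n", seed), file = logf)

  # -- simulate -------------------------------------------------------------
  sm <- config$simulate
  spec <- gene_spec(cds_length = sm$cds_length, n_exons = sm$n_exons,
                    gc_target = sm$gc_target, background_gc = sm$background_gc,
                    flank_length = sm$flank_length)
  ref <- make_reference(spec, seed = seed)
  reads <- simulate_reads(ref$transcript,
                          sim_config(depth = sm$depth,
                                     read_length = sm$read_length,
                                     error_rate = sm$error_rate,
                                     seed = seed + 1L),
                          bias_model(lambda_bias = sm$lambda_bias,
                                     gc_pivot = sm$gc_pivot))
  write_simulation(ref, reads, config$out_dir)
  log_line("simulate: %d reads from %d-nt transcript (digest %s)",
           nrow(reads), nchar(ref$transcript),
           unname(tools::md5sum(file.path(config$out_dir, "reads.fastq"))))

  # -- recover --------------------------------------------------------------
  bait <- mutate_protein(ref$protein, identity = sm$bait_identity,
                         seed = seed + 2L)
  rec <- iterate_recovery(bait, reads,
                          recovery_params(max_rounds = config$recover$max_rounds,
                                          min_score = config$recover$min_score))
  if (!is.null(rec$contig))
    write_fasta(c(contig = rec$contig$sequence),
                file.path(config$out_dir, "contig.fasta"))
  writeLines(vapply(seq_len(nrow(rec$state$log)), function(i)
    jsonlite::toJSON(as.list(rec$state$log[i, ]), auto_unbox = TRUE),
    ""), file.path(config$out_dir, "rounds.jsonl"))
  log_line("recover: status %s after %d round(s), contig %d nt",
           rec$state$status, rec$state$round,
           if (is.null(rec$contig)) 0L else nchar(rec$contig$sequence))

  # -- annotate -------------------------------------------------------------
  ann <- NULL
  if (!is.null(rec$contig)) {
    ann <- annotate_gene(rec$contig$sequence, bait,
                         motif = config$annotate$motif)
    write_gff3(ann, "contig", file.path(config$out_dir, "annotation.gff3"))
    write_fasta(c(candidate_protein = ann$protein),
                file.path(config$out_dir, "protein.fasta"))
    log_line("annotate: %d-aa protein, status %s, %d motif hit(s), %d TM segment(s)",
             nchar(ann$protein), ann$status,
             if (is.null(ann$motif_hits)) 0L else nrow(ann$motif_hits),
             nrow(ann$tm_segments))
  }

  # -- gc -------------------------------------------------------------------
  prof <- gc_windows(ref$genome, config$gc$window, config$gc$step)
  write_gc_tsv(prof, file.path(config$out_dir, "gc_profile.tsv"))
  contrast <- gc_contrast(list(gene = setNames(ref$cds, "cds"),
                               background = c(
                                 flank5 = substring(ref$genome, 1, spec$flank_length),
                                 flank3 = substring(ref$genome,
                                                    nchar(ref$genome) - spec$flank_length + 1))))
  log_line("gc: gene %.3f vs background %.3f", contrast$means[1],
           contrast$means[2])

  # -- phylo ----------------------------------------------------------------
  ph <- config$phylo
  fam_tree <- two_clade_tree(ph$n_tips_per_clade)
  fam <- simulate_protein_family(fam_tree, ref$protein, rate = ph$rate,
                                 seed = seed + 3L)
  fam["outgroup"] <- mutate_protein(ref$protein, 0.35, seed = seed + 4L)
  msa <- filter_gap_columns(align_progressive(fam))
  bt <- bootstrap_nj(msa, n_reps = ph$n_reps, seed = seed + 5L)
  write_msa(msa, file.path(config$out_dir, "family_aln.fasta"))
  write_newick(bt$tree, file.path(config$out_dir, "family_nj.nwk"))
  focal <- grep("^cladeA", names(fam), value = TRUE)
  mono <- clade_test(bt$tree, focal, "outgroup")
  log_line("phylo: %d taxa, clade A monophyletic: %s", length(fam), mono)

  # -- synteny --------------------------------------------------------------
  sy <- make_toy_locus(ph_seed = seed + 6L, n_genes = config$synteny$n_genes)
  pairs <- assign_orthologs(sy$query, sy$reference)
  syn <- compare_order(pairs, sy$query, sy$reference)
  write_synteny(syn, file.path(config$out_dir, "synteny_pairs.tsv"),
                file.path(config$out_dir, "synteny.json"))
  log_line("synteny: %d pairs, concordance %.2f", syn$shared_count,
           syn$order_concordance)

  # -- qc -------------------------------------------------------------------
  qc_in <- c(truth = ref$cds)
  if (!is.null(rec$contig) && !is.null(ann) && ann$status == "complete")
    qc_in <- c(qc_in, candidate = substring(rec$contig$sequence,
                                            ann$orf_range[1] + 1,
                                            ann$orf_range[2]))
  qc <- qc_report(qc_in, reference = ref$cds,
                  flag_threshold = config$qc$flag_threshold)
  write_qc_json(qc, file.path(config$out_dir, "qc.json"))
  log_line("qc: any_flag %s", qc$any_flag)

  invisible(list(reference = ref, reads = reads, recovery = rec,
                 annotation = ann, gc = contrast, phylo = bt,
                 clade_monophyletic = mono, synteny = syn, qc = qc,
                 out_dir = config$out_dir))
}

# balanced two-clade tree with tip labels cladeA_i / cladeB_i
two_clade_tree <- function(n_per_clade = 4L, depth = 0.4, tip_len = 0.15) {
  tipset <- function(prefix) {
    paste0("(", paste(sprintf("%s_%d:%g", prefix, seq_len(n_per_clade),
                              tip_len), collapse = ","), "):", depth)
  }
  ape::read.tree(text = paste0("(", tipset("cladeA"), ",", tipset("cladeB"),
                               ");"))
}

# toy pair of gene tables: reference locus and a query locus with the same
# gene order and slightly diverged proteins
make_toy_locus <- function(ph_seed = 1L, n_genes = 6L, prot_len = 120L) {
  with_seed(ph_seed, {
    prots <- vapply(seq_len(n_genes), function(i) random_protein(prot_len), "")
    starts <- cumsum(c(0L, rep(2000L, n_genes - 1L)))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    reference <- gene_table(data.frame(
      id = sprintf("ref_g%d", seq_len(n_genes)), chrom = "refchr",
      start = starts, end = starts + 3L * prot_len, strand = strands,
      protein = prots, stringsAsFactors = FALSE))
    qprots <- vapply(seq_len(n_genes), function(i)
      mutate_protein(prots[i], identity = 0.8, seed = ph_seed + i), "")
    query <- gene_table(data.frame(
      id = sprintf("qry_g%d", seq_len(n_genes)), chrom = "qrychr",
      start = starts, end = starts + 3L * prot_len, strand = strands,
      protein = qprots, stringsAsFactors = FALSE))
    list(query = query, reference = reference)
  })
}
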