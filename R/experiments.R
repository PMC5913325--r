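#' One seeded recovery replicate under controlled conditions
#'
#' Builds a fresh synthetic reference, simulates reads at the requested
#' depth / bias / error rate, derives a diverged bait from the truth
#' protein, and runs the full iterative recovery. Success means the
#' iteration reached `orf_complete` and the recovered contig contains the
#' planted CDS verbatim.
#'
#' @param seed base seed; the reference, read, and bait seeds are derived
#'   from it so replicates are independent and reproducible.
#' @param depth nominal fold coverage.
#' @param lambda_bias GC-bias strength (see [bias_model()]).
#' @param error_rate substitution error rate.
#' @param spec a [gene_spec()] describing the planted gene.
#' @param bait_identity fractional identity of the derived bait to the
#'   truth protein.
#' @param params [recovery_params()].
#' @return list with `success`, `status`, `identical_cds`, `rounds`,
#'   `n_reads`, `contig_length`.
#' @export
recovery_replicate <- function(seed, depth, lambda_bias = 0,
                               error_rate = 0.005, spec = gene_spec(),
                               bait_identity = 0.7,
                               params = recovery_params()) {
  ref <- make_reference(spec, seed = seed)
  reads <- simulate_reads(ref$transcript,
                          sim_config(depth = depth, read_length = 100L,
                                     error_rate = error_rate,
                                     seed = seed + 1L),
                          bias_model(lambda_bias = lambda_bias))
  bait <- mutate_protein(ref$protein, identity = bait_identity,
                         seed = seed + 2L)
  rec <- suppressWarnings(iterate_recovery(bait, reads, params))
  ident <- !is.null(rec$contig) &&
    grepl(ref$cds, rec$contig$sequence, fixed = TRUE)
  list(success = rec$state$status == "orf_complete" && ident,
       status = rec$state$status, identical_cds = ident,
       rounds = rec$state$round, n_reads = nrow(reads),
       contig_length = if (is.null(rec$contig)) 0L
                       else nchar(rec$contig$sequence))
}

#' Recovery success rate over seeded replicates
#'
#' @param n_seeds number of replicates.
#' @param depth,lambda_bias,error_rate,spec,bait_identity,params passed to
#'   [recovery_replicate()].
#' @param base_seed replicate i uses seeds derived from
#'   `base_seed + 10 * i`.
#' @return list with `rate`, per-replicate `results`, and the conditions.
#' @export
recovery_success_rate <- function(n_seeds = 20L, depth = 60,
                                  lambda_bias = 0, error_rate = 0.005,
                                  spec = gene_spec(), bait_identity = 0.7,
                                  params = recovery_params(),
                                  base_seed = 1L) {
  results <- lapply(seq_len(n_seeds), function(i)
    recovery_replicate(base_seed + 10L * i, depth, lambda_bias, error_rate,
                       spec, bait_identity, params))
  list(rate = mean(vapply(results, `[[`, TRUE, "success")),
       results = results, depth = depth, lambda_bias = lambda_bias,
       error_rate = error_rate, n_seeds = n_seeds)
}

#' Synthetic GC-contrast draw: high-GC vs background-GC sequence groups
#'
#' Draws two groups of sequences whose per-sequence GC targets are sampled
#' from normal distributions and asks whether [gc_contrast()] flags the
#' separation; emulates comparing a high-GC lineage's orthologs against
#' lower-GC orthologs from other lineages.
#'
#' @param seed integer seed.
#' @param n_per_group sequences per group.
#' @param gc_a,gc_b group mean GC.
#' @param gc_sd between-sequence GC standard deviation.
#' @param len sequence length, nt.
#' @return logical: was group A flagged above group B?
#' @export
gc_contrast_draw <- function(seed, n_per_group = 8L, gc_a = 0.65,
                             gc_b = 0.48, gc_sd = 0.02, len = 500L) {
  with_seed(seed, {
    draw <- function(mu) {
      gc <- pmin(0.95, pmax(0.05, stats::rnorm(n_per_group, mu, gc_sd)))
      vapply(gc, function(g) random_dna(len, g), "")
    }
    a <- setNames(draw(gc_a), sprintf("a%d", seq_len(n_per_group)))
    b <- setNames(draw(gc_b), sprintf("b%d", seq_len(n_per_group)))
    gc_contrast(list(high = a, background = b))$flagged
  })
}
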