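test_that("planted CDS has the requested structure and composition", {
  spec <- gene_spec(cds_length = 858, n_exons = 4, gc_target = 0.66,
                    background_gc = 0.42)
  ref <- make_reference(spec, seed = 5)
  expect_identical(substring(ref$cds, 1, 3), "ATG")
  expect_true(substring(ref$cds, 856, 858) %in% c("TAA", "TAG", "TGA"))
  # stop-free protein of 285 aa (858/3 - 1)
  expect_equal(nchar(ref$protein), 285)
  expect_false(grepl("*", ref$protein, fixed = TRUE))
  expect_lt(abs(gc_content(ref$cds) - 0.66), 0.03)
  # exon coordinates are exact: splicing the genome reproduces the CDS
  spliced <- paste(substring(ref$genome, ref$exons$start + 1, ref$exons$end),
                   collapse = "")
  expect_identical(spliced, ref$cds)
  # CDS sits inside the transcript at the annotated range
  r <- ref$cds_transcript_range
  expect_identical(substring(ref$transcript, r[1] + 1, r[2]), ref$cds)
})

test_that("single-exon spec gives one contiguous CDS interval", {
  ref <- make_reference(gene_spec(cds_length = 300, n_exons = 1,
                                  intron_lengths = integer(0)), seed = 2)
  expect_equal(nrow(ref$exons), 1)
  expect_equal(ref$exons$end - ref$exons$start, 300)
})

test_that("reference construction is deterministic and rejects infeasible GC", {
  spec <- gene_spec(cds_length = 300, n_exons = 2, intron_lengths = 50L)
  a <- make_reference(spec, seed = 42)
  b <- make_reference(spec, seed = 42)
  expect_identical(a$genome, b$genome)
  expect_identical(a$transcript, b$transcript)
  expect_error(make_reference(gene_spec(cds_length = 300, n_exons = 1,
                                        intron_lengths = integer(0),
                                        gc_target = 0.999), seed = 1),
               "infeasible")
})

test_that("simulator emits the exact read count and conserves bases", {
  ref <- make_reference(gene_spec(cds_length = 300, n_exons = 1,
                                  intron_lengths = integer(0),
                                  flank_length = 4850), seed = 3)
  expect_equal(nchar(ref$genome), 10000)
  rs <- simulate_reads(ref$genome, sim_config(depth = 10, read_length = 100,
                                              seed = 4))
  expect_equal(nrow(rs), 1000)
  expect_equal(sum(nchar(rs$seq)), 1000 * 100)
  # byte-identical FASTQ under an identical seed
  rs2 <- simulate_reads(ref$genome, sim_config(depth = 10, read_length = 100,
                                               seed = 4))
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(rs, f1); write_fastq(rs2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(simulate_reads("", sim_config()), "empty")
  expect_error(simulate_reads("ACGT", sim_config(read_length = 100)),
               "read_length")
})

test_that("unbiased coverage is consistent with uniform Poisson sampling", {
  set.seed(7)
  genome <- random_dna_str(10000, gc = 0.5)
  rs <- simulate_reads(genome, sim_config(depth = 30, read_length = 100,
                                          error_rate = 0, seed = 8),
                       bias_model(lambda_bias = 0))
  st <- attr(rs, "truth")$start
  # read starts over window bins; uniform sampling => multinomial with
  # equal class probabilities, tested by chi-squared goodness of fit
  bins <- findInterval(st, seq(0, 9900, by = 100), rightmost.closed = FALSE)
  counts <- tabulate(bins, nbins = 99)
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.01)
})

test_that("GC bias depletes coverage of a high-GC segment", {
  set.seed(9)
  genome <- paste0(random_dna_str(4000, 0.40), random_dna_str(2000, 0.70),
                   random_dna_str(4000, 0.40))
  rs <- simulate_reads(genome, sim_config(depth = 30, read_length = 100,
                                          error_rate = 0, seed = 10),
                       bias_model(lambda_bias = 8))
  st <- attr(rs, "truth")$start
  hi <- sum(st >= 4000 & st < 5900)
  lo <- sum(st < 3900 | st >= 6000)
  n_hi_windows <- 1900; n_lo_windows <- 7900
  # one-sided binomial test of depletion relative to footprint share
  p_exp <- n_hi_windows / (n_hi_windows + n_lo_windows)
  p <- binom.test(hi, hi + lo, p = p_exp, alternative = "less")$p.value
  expect_lt(p, 0.01)
  # empirical coverage monotonicity across GC above the pivot
  gcw <- gc_windows(genome, 100, 100)
  cov <- tabulate(findInterval(st, gcw$start), nbins = nrow(gcw))
  hi_gc <- gcw$gc > 0.6
  mid_gc <- gcw$gc > 0.5 & gcw$gc <= 0.6
  expect_lt(mean(cov[hi_gc]), mean(cov[mid_gc]))
})

test_that("homopolymer planting and 5' truncation behave exactly", {
  expect_identical(plant_homopolymer("ACGT", "G", 3, 2), "ACGGGGT")
  expect_error(plant_homopolymer("ACGT", "G", 0, 2), "run_length")
  s <- random_dna_str(200)
  planted <- plant_homopolymer(s, "G", 55, 120)
  expect_equal(nchar(planted), 255)
  expect_identical(substring(planted, 121, 175), strrep("G", 55))
  # planting then deleting the same span restores the input
  restored <- paste0(substring(planted, 1, 120), substring(planted, 176))
  expect_identical(restored, s)
  expect_identical(truncate_5prime(s, 0), s)
  expect_equal(nchar(truncate_5prime(strrep("A", 858), 216)), 642)
  expect_error(truncate_5prime("ACGT", 4), "n must")
})
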