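test_that("maximal homopolymer runs are reported exactly", {
  r <- longest_runs("GGGGG")
  expect_equal(r$runs$base, "G")
  expect_equal(r$runs$length, 5)
  expect_equal(r$runs$start, 0)
  empty <- longest_runs("")
  expect_equal(nrow(empty$runs), 0)
  set.seed(81)
  s <- random_dna_str(300, 0.5)
  planted <- plant_homopolymer(s, "G", 55, 200)
  fl <- longest_runs(planted)$flagged
  expect_gte(nrow(fl), 1)
  expect_true(any(fl$base == "G" & fl$length >= 55))
})

test_that("terminal deficits and internal insertions are exact on planted fixtures", {
  set.seed(82)
  ref <- random_dna_str(900, 0.55)
  same <- terminal_deficit(ref, ref)
  expect_equal(same$deficit5, 0)
  expect_equal(same$deficit3, 0)
  expect_equal(nrow(same$internal_insertions), 0)
  # the published artifact pair: 216 nt missing 5', 55-G inserted 3'
  td <- terminal_deficit(truncate_5prime(ref, 216), ref)
  expect_equal(td$deficit5, 216)
  expect_equal(td$deficit3, 0)
  ins <- terminal_deficit(plant_homopolymer(ref, "G", 55, 800), ref)
  expect_equal(ins$deficit5, 0)
  expect_equal(sum(ins$internal_insertions$length), 55)
  # grid of (truncation, run length) cases stays exact
  for (n in c(10, 60, 150, 216, 400)) {
    expect_equal(terminal_deficit(truncate_5prime(ref, n), ref)$deficit5, n)
  }
  for (run in c(12, 25, 55, 80)) {
    got <- terminal_deficit(plant_homopolymer(ref, "C", run, 450), ref)
    expect_equal(sum(got$internal_insertions$length), run)
  }
  # combined artifact
  both <- terminal_deficit(plant_homopolymer(truncate_5prime(ref, 216),
                                             "G", 55, 600), ref)
  expect_equal(both$deficit5, 216)
  expect_equal(sum(both$internal_insertions$length), 55)
  # 3' loss is symmetric
  td3 <- terminal_deficit(substring(ref, 1, 700), ref)
  expect_equal(td3$deficit3, 200)
})

test_that("QC reports flag artifacts and pass clean sequences", {
  set.seed(83)
  ref <- random_dna_str(600, 0.5)
  rep1 <- qc_report(c(clean = ref), reference = ref)
  expect_false(rep1$any_flag)
  bad <- plant_homopolymer(truncate_5prime(ref, 50), "G", 20, 300)
  rep2 <- qc_report(c(clean = ref, artifact = bad), reference = ref)
  expect_true(rep2$any_flag)
  expect_false(rep2$sequences$clean$flag)
  expect_true(rep2$sequences$artifact$flag)
  expect_equal(rep2$sequences$artifact$deficit5, 50)
  f <- tempfile(fileext = ".json")
  write_qc_json(rep2, f)
  back <- jsonlite::read_json(f)
  expect_true(back$any_flag)
})
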