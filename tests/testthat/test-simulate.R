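test_that("strain references substitute exactly the requested positions", {
  expect_equal(buildStrainReference("ACGT", 2L, "T"), "ATGT")
  expect_equal(buildStrainReference("ACGT", integer(), character()), "ACGT")
  expect_equal(buildStrainReference("ACGT", c(4L, 1L), c("A", "G")),
               buildStrainReference("ACGT", c(1L, 4L), c("G", "A")))
  expect_warning(buildStrainReference("ACGT", 1L, "A"),
                 "non-discriminating")
  expect_error(buildStrainReference("ACGT", 9L, "A"), "outside")
})

test_that("read allocation is largest-remainder exact", {
  expect_equal(unname(allocateReads(500, c(10, 20, 30))),
               c(83L, 167L, 250L))
  expect_equal(unname(allocateReads(0, c(1, 2, 3))), c(0L, 0L, 0L))
  expect_equal(unname(allocateReads(7, c(1, 0, 0))), c(7L, 0L, 0L))
  expect_error(allocateReads(5, c(0, 0)), "all ASE values are zero")
  # conservation on fuzzed inputs
  set.seed(14)
  for (i in 1:200) {
    total <- sample(0:5000, 1)
    ase <- rexp(sample(2:5, 1))
    counts <- allocateReads(total, ase)
    expect_equal(sum(counts), total)
    expect_true(all(abs(counts - total * ase / sum(ase)) < 1))
  }
})

test_that("fragment placement covers 2 x readLen bases per fragment", {
  set.seed(31)
  pl <- generateFragments(250L, 20L)
  expect_true(all(pl$start == 1L))
  expect_equal(pl$r1_strand, rep("+", 20))
  expect_equal(pl$r2_strand, rep("-", 20))

  pl <- generateFragments(1000L, 50L)
  expect_true(all(pl$start >= 1L & pl$r2_end <= 1000L))
  expect_true(all(pl$r1_end - pl$r1_start == 99L))
  expect_true(all(pl$r2_end - pl$r2_start == 99L))
  expect_true(all(pl$r2_start - pl$r1_end == 51L))  # 50 bp inner gap

  # coverage accounting: total depth mass equals 200 per fragment
  pl <- cbind(data.frame(transcript = "t1", strain = "s1",
                         stringsAsFactors = FALSE),
              generateFragments(600L, 30L))
  ref <- c(t1 = strrep("ACGT", 150))
  pu <- placementsToPileup(pl, list(s1 = ref), ref)
  expect_equal(sum(pileupColumns(pu)$depth), 200L * 30L)

  # short transcripts fall back to single reads
  pl <- generateFragments(80L, 10L)
  expect_true(all(is.na(pl$r2_start)))
  expect_true(all(pl$r1_end - pl$r1_start == 79L))
})

test_that("truth pileups encode strain variants and parse back", {
  ref <- c(t1 = strrep("AC", 150))
  strain_seq <- list(s1 = c(t1 = buildStrainReference(ref, 10L, "G")),
                     s2 = c(t1 = unname(ref)))
  pl <- rbind(
    cbind(data.frame(transcript = "t1", strain = "s1"),
          data.frame(start = 1L, r1_start = 1L, r1_end = 100L,
                     r1_strand = "+", r2_start = 151L, r2_end = 250L,
                     r2_strand = "-")),
    cbind(data.frame(transcript = "t1", strain = "s2"),
          data.frame(start = 6L, r1_start = 6L, r1_end = 105L,
                     r1_strand = "+", r2_start = 156L, r2_end = 255L,
                     r2_strand = "-")))
  pu <- placementsToPileup(pl, strain_seq, ref)
  cc <- pileupColumns(pu)
  # depth 1 in the single-covered prefix, 2 where both overlap, gap uncovered
  expect_equal(cc$depth[cc$pos == 3L], 1L)
  expect_equal(cc$depth[cc$pos == 50L], 2L)
  expect_false(120L %in% cc$pos)  # inner gap of both fragments
  # the variant strain's base appears as a mismatch at position 10
  tt <- tallyBases(pu, 0L)
  at10 <- tt[tt$pos == 10L, ]
  expect_equal(at10$G_plus, 1L)
  expect_equal(at10$C_plus, 1L)
  # round-trip through the text format reproduces the columns
  f <- withr::local_tempfile(fileext = ".mpileup")
  writeMpileup(pu, f)
  expect_equal(pileupColumns(readMpileup(f)), cc)
})

test_that("FASTQ output contains 2n reads of the right length", {
  set.seed(5)
  ref <- c(t1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                      collapse = ""))
  pl <- cbind(data.frame(transcript = "t1", strain = "s1",
                         stringsAsFactors = FALSE),
              generateFragments(400L, 7L))
  prefix <- withr::local_tempfile()
  writeFastq(pl, list(s1 = ref), prefix)
  r1 <- readLines(paste0(prefix, "_R1.fastq"))
  r2 <- readLines(paste0(prefix, "_R2.fastq"))
  expect_length(r1, 7L * 4L)
  expect_length(r2, 7L * 4L)
  expect_true(all(nchar(r1[seq(2, 28, 4)]) == 100L))
  # R2 is the reverse complement of the fragment-end substring
  i <- 1L
  frag_end <- substring(ref, pl$r2_start[i], pl$r2_end[i])
  expect_equal(r2[2], as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(frag_end))))
})

test_that("recovery evaluation flags constant inputs and scores trends", {
  strains <- c("a", "b", "c")
  truth <- data.frame(transcript = c("t1", "t2", "t3"),
                      a = c(10, 10, 5), b = c(20, 10, 5), c = c(30, 10, 5))
  est_perfect <- truth
  r <- evaluateRecovery(truth, est_perfect, strains)
  expect_equal(r$per_transcript$r[1], 1)
  expect_true(all(r$per_transcript$constant[2:3]))
  est_rev <- transform(truth, a = c, c = a)
  expect_equal(evaluateRecovery(truth, est_rev,
                                strains)$per_transcript$r[1], -1)
  expect_error(evaluateRecovery(truth, truth[1:2, ], strains),
               "different transcript sets")
})

test_that("a fixed seed makes the whole simulation bit-reproducible", {
  s1 <- simulateTriploidExperiment(nTranscripts = 2, transcriptLength = 300,
                                   fragmentsRange = c(50L, 80L),
                                   parentFragments = 40L, seed = 123)
  s2 <- simulateTriploidExperiment(nTranscripts = 2, transcriptLength = 300,
                                   fragmentsRange = c(50L, 80L),
                                   parentFragments = 40L, seed = 123)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$truth, s2$truth)
  expect_identical(pileupColumns(s1$polyploidPileup),
                   pileupColumns(s2$polyploidPileup))
})
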