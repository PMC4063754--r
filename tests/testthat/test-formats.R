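test_that("FASTA reading preserves records, folds lines and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "AC", "gt", ">t2 description", "GGGG"), f)
  seqs <- readTranscripts(f)
  expect_equal(names(seqs), c("t1", "t2"))
  expect_equal(as.character(seqs), c(t1 = "ACGT", t2 = "GGGG"))

  writeLines(character(), f)
  expect_length(readTranscripts(f), 0L)

  writeLines(c("ACGT"), f)
  expect_error(readTranscripts(f), "line 1")
  writeLines(c(">t1", ">t2", "ACGT"), f)
  expect_error(readTranscripts(f), "no sequence")
  writeLines(c(">t1", "AC", ">t1", "GG"), f)
  expect_error(readTranscripts(f), "duplicate")
})

test_that("mpileup lines resolve the read-base grammar", {
  col <- parseMpileupLine("t1\t343\tC\t4\t..,,\tIIII")
  expect_s4_class(col, "PileupColumn")
  expect_equal(pileupDepth(col), 4L)
  obs <- observations(col)
  expect_equal(obs$base, rep("C", 4))
  expect_equal(obs$strand, c("+", "+", "-", "-"))
  expect_equal(obs$quality, rep(40L, 4))

  # read start (with mapping quality), insertion, read end, mismatch case
  col <- parseMpileupLine("t1\t47\tA\t3\t^I.+2AGt.$\tIIH")
  obs <- observations(col)
  expect_equal(obs$base, c("A", "T", "A"))
  expect_equal(obs$strand, c("+", "-", "+"))
  expect_equal(obs$quality, c(40L, 40L, 39L))

  # declared depth inconsistent with the base string is a format error
  expect_error(parseMpileupLine("t1\t343\tC\t10\tTTTTT\tIIIII"),
               "depth field 10")
  # base/quality length mismatch is a format error
  expect_error(parseMpileupLine("t1\t343\tC\t5\tTTTTT\tIII"),
               "length mismatch")
})

test_that("pileup columns round-trip through serialisation (fuzzed)", {
  set.seed(421)
  for (i in 1:40) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    obs <- random_observations(sample(0:30, 1), ref)
    line <- make_mpileup_line("tx", i, ref, obs,
                              decorate = nrow(obs) > 2 && i %% 2 == 0)
    col <- parseMpileupLine(line)
    expect_equal(pileupDepth(col), nrow(obs))
    expect_equal(observations(col)$base, obs$base)
    expect_equal(observations(col)$strand, obs$strand)
    expect_equal(observations(col)$quality, obs$quality)
    # per-base tallies sum to depth minus placeholders / low-quality reads
    tt <- tallyBases(col, minBaseQuality = 0L)
    counted <- tt$A_plus + tt$A_minus + tt$C_plus + tt$C_minus +
      tt$G_plus + tt$G_minus + tt$T_plus + tt$T_minus
    expect_equal(counted, sum(obs$base %in% c("A", "C", "G", "T")))
    expect_equal(tt$depth, nrow(obs))
  }
})

test_that("Pileup files round-trip through writeMpileup/readMpileup", {
  set.seed(77)
  sim <- simulateTriploidExperiment(nTranscripts = 2,
                                    transcriptLength = 300,
                                    fragmentsRange = c(30L, 60L),
                                    parentFragments = 30L, seed = 5)
  f <- withr::local_tempfile(fileext = ".mpileup")
  writeMpileup(sim$polyploidPileup, f)
  back <- readMpileup(f)
  expect_equal(pileupColumns(back), pileupColumns(sim$polyploidPileup))
  expect_equal(nrow(pileupColumns(readMpileup(
    withr::local_tempfile(lines = character(), fileext = ".mpileup")))), 0L)
})

test_that("report tables write deterministically and round-trip", {
  rec <- data.frame(transcript = c("t1", "t2"),
                    HNI = c(12.345678, 0), OR = c(1.5, 2.25),
                    whole_gene = c(13.845678, 2.25),
                    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeReportTable(rec, f)
  lines <- readLines(f)
  expect_equal(lines[1], "transcript\tHNI\tOR\twhole_gene")
  expect_length(lines, 3L)
  back <- readReportTable(f)
  expect_equal(back$HNI, rec$HNI, tolerance = 1e-7)
  expect_equal(back$transcript, rec$transcript)

  writeReportTable(rec[0, ], f)
  expect_length(readLines(f), 1L)  # header only
  expect_error(writeReportTable(rec, f, columns = c("transcript", "nope")),
               "schema")
})
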