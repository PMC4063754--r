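test_that("base tallies respect the quality threshold but keep depth", {
  q30 <- strrep("?", 5)  # '?' = Phred 30
  q10 <- strrep("+", 5)  # '+' = Phred 10
  pl <- new("Pileup", columns = data.frame(
    transcript = "t1", pos = 1L, ref = "C", depth = 10L,
    bases = "TTTTTTTTTT", quals = paste0(q30, q10),
    stringsAsFactors = FALSE))
  tt <- tallyBases(pl, minBaseQuality = 25L)
  expect_equal(tt$T_plus, 5L)
  expect_equal(tt$depth, 10L)
  expect_equal(tt$counted, 5L)
  expect_equal(tt$T_qual, 30)

  tt0 <- tallyBases(pl, minBaseQuality = 0L)
  expect_equal(tt0$T_plus, 10L)

  empty <- new("Pileup", columns = data.frame(
    transcript = character(), pos = integer(), ref = character(),
    depth = integer(), bases = character(), quals = character(),
    stringsAsFactors = FALSE))
  expect_equal(nrow(tallyBases(empty)), 0L)
})

test_that("variant significance matches hypergeometric enumeration", {
  expect_equal(variantSignificance(10, 0), 1)
  expect_equal(variantSignificance(5, 15), oracle_variant_p(5, 15))
  # every table with total <= 30, against the enumeration oracle,
  # plus monotonicity in variant reads at fixed total
  for (total in c(1, 5, 12, 30)) {
    p <- variantSignificance(total - 0:total, 0:total)
    p_oracle <- vapply(0:total, function(v)
      oracle_variant_p(total - v, v), numeric(1))
    expect_equal(p, p_oracle, tolerance = 1e-12)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p > 0 & p <= 1))
  }
  # and agrees with the one-sided Fisher test on spot checks
  for (tab in list(c(5, 15), c(20, 5), c(10, 1))) {
    ft <- fisher.test(matrix(c(tab[1], tab[2], sum(tab), 0), nrow = 2,
                             byrow = TRUE), alternative = "less")
    expect_equal(variantSignificance(tab[1], tab[2]), ft$p.value,
                 tolerance = 1e-9)
  }
})

test_that("strand filter needs both strands and a minority fraction", {
  expect_false(strandCheck(10, 0))
  expect_true(strandCheck(9, 1, 0.10))   # 1/10 boundary is inclusive
  expect_true(strandCheck(5, 5))
  expect_false(strandCheck(19, 1, 0.10)) # 1/20 below the fraction
  expect_false(strandCheck(0, 0))
})

test_that("consensus calls follow the documented threshold chain", {
  th <- consensusThresholds()
  # depth below 15x is never evaluated
  res <- consensusCalls(callConsensus(make_tally_row(14, 14, 7, 7), th))
  expect_equal(res$iupac, "N")
  expect_equal(res$flags, "LOW_COVERAGE")
  # 4/20 reads = 20% frequency but below the 5-read floor: reference
  res <- consensusCalls(callConsensus(make_tally_row(20, 4, 2, 2), th))
  expect_equal(res$iupac, "C")
  expect_equal(res$flags, "")
  # balanced heterozygote C/T -> Y
  res <- consensusCalls(callConsensus(make_tally_row(20, 10, 5, 5), th))
  expect_equal(res$iupac, "Y")
  # 18/20 variant reads: above the homozygous threshold
  res <- consensusCalls(callConsensus(make_tally_row(20, 18, 9, 9), th))
  expect_equal(res$iupac, "T")
  # single-strand variant support is flagged, not called
  res <- consensusCalls(callConsensus(make_tally_row(20, 10, 10, 0), th))
  expect_equal(res$iupac, "N")
  expect_match(res$flags, "STRAND_FAIL")
  expect_error(callConsensus(make_tally_row(20, 0, 0, 0) |>
                               transform(ref = "X")), "reference base")
})

test_that("adding a variant read never reverts a called variant to reference", {
  th <- consensusThresholds()
  set.seed(11)
  for (i in 1:200) {
    d <- sample(15:40, 1)
    v <- sample(0:d, 1)
    vp <- sample(0:v, 1)
    before <- consensusCalls(callConsensus(make_tally_row(d, v, vp, v - vp), th))
    if (before$iupac %in% c("T", "Y")) {
      after <- consensusCalls(callConsensus(
        make_tally_row(d + 1, v + 1, vp + 1, v - vp), th))
      expect_false(after$iupac == "C",
                   info = sprintf("d=%d v=%d vp=%d", d, v, vp))
    }
  }
})
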