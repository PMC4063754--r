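test_that("coefficient of variation hits the silencing landmarks", {
  expect_equal(coefficientOfVariation(c(5, 5, 5)), 0)
  expect_equal(coefficientOfVariation(c(7, 7, 0)), sqrt(3) / 2,
               tolerance = 1e-12)
  expect_equal(coefficientOfVariation(c(9, 0, 0)), sqrt(3),
               tolerance = 1e-12)
  expect_warning(res <- coefficientOfVariation(c(0, 0, 0)), "undefined")
  expect_true(is.na(res))
  # bounded by sqrt(k) for non-negative k-tuples; sup at one-nonzero
  set.seed(8)
  for (i in 1:300) {
    v <- rexp(3) * rbinom(3, 1, 0.8)
    if (all(v == 0)) next
    cv <- coefficientOfVariation(v)
    expect_true(cv >= 0 && cv <= sqrt(3) + 1e-12)
  }
})

test_that("equality test is the chi-square goodness of fit", {
  res <- equalExpressionTest(c(10, 10, 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res <- equalExpressionTest(c(30, 0, 0))
  expect_equal(res$statistic, 60)
  expect_equal(res$p_value, exp(-30), tolerance = 1e-10)  # df-2 closed form
  res <- equalExpressionTest(c(12, 9, 9))
  expect_equal(res$statistic, 0.6)
  expect_equal(res$p_value, exp(-0.3), tolerance = 1e-10)
  expect_equal(round(res$p_value, 2), 0.74)
  expect_true(is.na(equalExpressionTest(c(0, 0))$p_value))
})

test_that("imbalance categories follow the 2-fold-vs-median rule", {
  expect_equal(classifyCategory(c(HNI = 10, OR = 10, SOK = 10), 1),
               "even")
  expect_equal(classifyCategory(c(HNI = 0, OR = 20, SOK = 22), 1e-5),
               "HNI_down")
  expect_equal(classifyCategory(c(HNI = 50, OR = 10, SOK = 12), 1e-5),
               "HNI_up")
  expect_equal(classifyCategory(c(HNI = 18, OR = 10, SOK = 12), 1e-5),
               "spread")
  # scale invariance at fixed p
  set.seed(12)
  for (i in 1:100) {
    v <- setNames(rexp(3, 1 / 10), c("a", "b", "c"))
    p <- runif(1)
    expect_equal(classifyCategory(v, p), classifyCategory(v * 37.5, p))
  }
})

test_that("quadrants partition on the 2-fold and dispersion thresholds", {
  expect_equal(classifyQuadrant(10, 10, 0.2), "0")
  expect_equal(classifyQuadrant(30, 10, 0.2), "II")
  expect_equal(classifyQuadrant(10, 10, 1.0), "I")
  expect_equal(classifyQuadrant(40, 10, 1.0), "III")
  expect_error(classifyQuadrant(0, 10, 0.5), "positive")

  # exhaustive and mutually exclusive on fuzzed records
  set.seed(4)
  n <- 500
  q <- classifyQuadrant(rexp(n, 1 / 20) + 0.1, rexp(n, 1 / 20) + 0.1,
                        runif(n, 0, sqrt(3)))
  expect_true(all(q %in% c("0", "I", "II", "III")))
  expect_equal(sum(table(q)), n)
})

test_that("cross-individual concordance counts identical categories", {
  a <- data.frame(transcript = c("t1", "t2", "t3"),
                  category = c("even", "HNI_up", "spread"),
                  stringsAsFactors = FALSE)
  b <- a
  expect_equal(concordance(a, b)$count, 3L)
  b$category <- c("spread", "even", "HNI_up")
  expect_equal(concordance(a, b)$count, 0L)
  expect_error(concordance(a, a[1:2, ]), "universe")

  set.seed(21)
  cats <- c("even", "spread", "a_up", "a_down", "b_up")
  a <- data.frame(transcript = sprintf("t%03d", 1:200),
                  category = sample(cats, 200, TRUE),
                  stringsAsFactors = FALSE)
  b <- data.frame(transcript = sample(a$transcript),
                  stringsAsFactors = FALSE)
  b$category <- sample(cats, 200, TRUE)
  got <- concordance(a, b)
  brute <- sum(vapply(a$transcript, function(tx)
    a$category[a$transcript == tx] == b$category[b$transcript == tx],
    logical(1)))
  expect_equal(got$count, brute)
  expect_equal(sum(got$per_category), brute)
})

test_that("chromosome tables rank transcripts with sequential ties", {
  rec <- data.frame(transcript = c("t1", "t2", "t3", "t4"),
                    category = c("even", "a_up", "spread", "even"),
                    stringsAsFactors = FALSE)
  ann <- data.frame(transcript = c("t1", "t2", "t3"),
                    chromosome = c("chr1", "chr1", "chr1"),
                    order = c(500L, 100L, 100L),
                    stringsAsFactors = FALSE)
  tab <- chromosomeRankTable(rec, ann)
  expect_equal(tab$rank, 1:3)
  # ties at 100 keep input order (t2 before t3), t1 comes last
  expect_equal(tab$transcript, c("t2", "t3", "t1"))
  expect_equal(tab$category, c("a_up", "spread", "even"))

  expect_equal(nrow(chromosomeRankTable(rec, ann[0, ])), 0L)
  expect_error(chromosomeRankTable(rec, ann[c(1, 1), ]), "duplicate")
})
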