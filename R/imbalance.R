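#' Coefficient of variation of allele expression values
#'
#' Normalised dispersion of the per-allele ASE values of one transcript:
#' sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean. For three alleles the value lies in `[0, sqrt(3)]`; `sqrt(3)/2`
#' (~0.87) marks one silenced allele with the other two expressed evenly,
#' and `sqrt(3)` (~1.73) marks two silenced alleles.
#'
#' @param values non-negative per-allele expression values, not all zero.
#' @return the coefficient of variation; `NA` (with a warning) when all
#'   values are zero.
#' @export
coefficientOfVariation <- function(values) {
  stopifnot(length(values) >= 2L, all(values >= 0))
  if (all(values == 0)) {
    warning("coefficient of variation undefined for all-zero expression")
    return(NA_real_)
  }
  stats::sd(values) / mean(values)
}

#' Goodness-of-fit test against equal allele expression
#'
#' Pearson chi-square test of the per-allele ASE values against the null
#' hypothesis that all alleles express equally (expected value = total /
#' ploidy, df = ploidy - 1).
#'
#' @param values non-negative per-allele expression values with a
#'   positive sum.
#' @return list with `statistic` and `p_value` (upper chi-square tail).
#' @export
equalExpressionTest <- function(values) {
  stopifnot(length(values) >= 2L, all(values >= 0))
  if (sum(values) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_))
  expected <- sum(values) / length(values)
  statistic <- sum((values - expected)^2 / expected)
  list(statistic = statistic,
       p_value = pchisq(statistic, df = length(values) - 1L,
                        lower.tail = FALSE))
}

#' Allelic imbalance category of one transcript
#'
#' Transcripts whose equality test is not rejected (`p >= alpha`) are
#' `even`. Among the rest, if exactly one allele exceeds `fold` times the
#' median allele expression it is that strain's `up` category; otherwise,
#' if exactly one allele falls below median/`fold`, that strain's `down`;
#' any other deviation is `spread`.
#'
#' @param values named per-strain ASE values.
#' @param p_value p-value from [equalExpressionTest()].
#' @param alpha significance cutoff for the equality test.
#' @param fold fold-change threshold against the median.
#' @return a single category string, e.g. `"even"`, `"spread"`,
#'   `"HNI_up"`, `"SOK_down"`.
#' @export
classifyCategory <- function(values, p_value, alpha = 0.01, fold = 2) {
  stopifnot(!is.null(names(values)), all(values >= 0))
  if (is.na(p_value) || p_value >= alpha) return("even")
  med <- median(values)
  up <- values > fold * med
  down <- values < med / fold
  if (sum(up) == 1L) return(paste0(names(values)[up], "_up"))
  if (sum(down) == 1L) return(paste0(names(values)[down], "_down"))
  "spread"
}

#' Expression-change / allele-dispersion quadrant
#'
#' Joint classification of a transcript by whole-gene differential
#' expression against the parental average (2-fold either way) and by
#' allele dispersion (coefficient of variation above the one-silenced-
#' allele landmark). Quadrant 0: neither; I: dispersed only; II: changed
#' expression only; III: both.
#'
#' @param triploidExpr whole-gene expression in the polyploid (vectorised).
#' @param parentalMeanExpr average parental whole-gene expression.
#' @param cv coefficient of variation of the ASE values.
#' @param fold fold-change threshold (expression considered changed when
#'   `|log2(ratio)| > log2(fold)`).
#' @param cvThreshold dispersion threshold (default `sqrt(3)/2`).
#' @return character vector over `"0"`, `"I"`, `"II"`, `"III"`.
#' @export
classifyQuadrant <- function(triploidExpr, parentalMeanExpr, cv, fold = 2,
                             cvThreshold = sqrt(3) / 2) {
  if (any(triploidExpr <= 0) || any(parentalMeanExpr <= 0))
    stop("quadrant classification needs positive expression values")
  changed <- abs(log2(triploidExpr / parentalMeanExpr)) > log2(fold)
  dispersed <- cv > cvThreshold
  c("0", "I", "II", "III")[1L + dispersed + 2L * changed]
}

#' Classify allelic imbalance for a table of ASE records
#'
#' Applies [coefficientOfVariation()], [equalExpressionTest()],
#' [classifyCategory()] and (where parental expression is available and
#' positive) [classifyQuadrant()] to every transcript of an ASE table.
#'
#' @param ase ASE table from [computeAse()].
#' @param strains strain identifiers naming the ASE columns.
#' @param parentalExpression optional `data.frame` with columns
#'   `transcript` and `parental_mean` (average normalised parental
#'   whole-gene expression).
#' @param alpha,fold,cvThreshold see the per-record functions.
#' @return `data.frame`: `transcript`, `cv`, `p_equal`, `category`,
#'   `fold_change` (log2 polyploid/parental, NA without parental data)
#'   and `quadrant`.
#' @export
classifyImbalance <- function(ase, strains, parentalExpression = NULL,
                              alpha = 0.01, fold = 2,
                              cvThreshold = sqrt(3) / 2) {
  vals <- as.matrix(ase[, strains, drop = FALSE])
  n <- nrow(vals)
  cv <- p_equal <- fold_change <- rep(NA_real_, n)
  category <- rep("even", n)
  quadrant <- rep(NA_character_, n)
  parental <- if (!is.null(parentalExpression))
    parentalExpression$parental_mean[
      match(ase$transcript, parentalExpression$transcript)]
  else rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- setNames(vals[i, ], strains)
    if (all(v == 0)) next
    cv[i] <- coefficientOfVariation(v)
    test <- equalExpressionTest(v)
    p_equal[i] <- test$p_value
    category[i] <- classifyCategory(v, test$p_value, alpha = alpha,
                                    fold = fold)
    if (!is.na(parental[i]) && parental[i] > 0 && ase$whole_gene[i] > 0) {
      fold_change[i] <- log2(ase$whole_gene[i] / parental[i])
      quadrant[i] <- classifyQuadrant(ase$whole_gene[i], parental[i],
                                      cv[i], fold = fold,
                                      cvThreshold = cvThreshold)
    }
  }
  data.frame(transcript = ase$transcript, cv = cv, p_equal = p_equal,
             category = category, fold_change = fold_change,
             quadrant = quadrant, stringsAsFactors = FALSE)
}

#' Cross-individual category concordance
#'
#' Counts transcripts placed in the same imbalance category in two
#' individuals, overall and per category.
#'
#' @param recordsA,recordsB imbalance tables from [classifyImbalance()]
#'   over the same transcript universe.
#' @return list with `count` (transcripts with identical category) and
#'   `per_category` (named vector of shared counts per category).
#' @export
concordance <- function(recordsA, recordsB) {
  if (length(recordsA$transcript) != length(recordsB$transcript) ||
      length(setdiff(recordsA$transcript, recordsB$transcript)) ||
      length(setdiff(recordsB$transcript, recordsA$transcript)))
    stop("records cover different transcript universes")
  catB <- recordsB$category[match(recordsA$transcript,
                                  recordsB$transcript)]
  same <- recordsA$category == catB
  per <- table(factor(recordsA$category[same],
                      levels = sort(unique(c(recordsA$category, catB)))))
  list(count = sum(same), per_category = c(per))
}

#' Order imbalance records along chromosomes
#'
#' Places annotated transcripts in the rank order in which they occur on
#' each chromosome, with coordinate ties assigned sequential ranks
#' (stable in input order). Unannotated transcripts are omitted.
#'
#' @param records imbalance table with at least `transcript` (and
#'   typically `category`).
#' @param annotation `data.frame` with columns `transcript`, `chromosome`
#'   and `order` (a sortable within-chromosome coordinate).
#' @return `data.frame`: `chromosome`, `rank`, `transcript` plus any
#'   `category` column carried over from `records`.
#' @export
chromosomeRankTable <- function(records, annotation) {
  need <- c("transcript", "chromosome", "order")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns transcript, chromosome, order")
  key <- paste(annotation$chromosome, annotation$order,
               annotation$transcript)
  if (anyDuplicated(key))
    stop(sprintf("duplicate annotation entry: %s", key[duplicated(key)][1L]))
  ann <- annotation[annotation$transcript %in% records$transcript, ,
                    drop = FALSE]
  if (!nrow(ann))
    return(data.frame(chromosome = character(), rank = integer(),
                      transcript = character(), stringsAsFactors = FALSE))
  ord <- order(ann$chromosome, ann$order)  # stable: ties keep input order
  ann <- ann[ord, , drop = FALSE]
  rank <- unlist(lapply(split(seq_len(nrow(ann)), ann$chromosome),
                        seq_along), use.names = FALSE)
  # split() orders groups by chromosome, matching the sort above
  out <- data.frame(chromosome = ann$chromosome, rank = rank,
                    transcript = ann$transcript, stringsAsFactors = FALSE)
  if ("category" %in% names(records))
    out$category <- records$category[match(out$transcript,
                                           records$transcript)]
  rownames(out) <- NULL
  out
}
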