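#' Geometric mean of coverage depth
#'
#' Transcript expression measure: the geometric mean of per-position
#' coverage depth over covered positions only (depth >= 1). Computed in
#' log space so long transcripts cannot overflow. Returns 0 when no
#' position is covered.
#'
#' @param depth non-negative integer vector of per-position depths.
#' @return scalar geometric mean.
#' @export
geometricMeanDepth <- function(depth) {
  stopifnot(all(depth >= 0))
  covered <- depth[depth >= 1]
  if (!length(covered)) return(0)
  exp(mean(log(covered)))
}

#' Per-transcript geometric-mean expression from a pileup
#'
#' @param pileup a [Pileup-class] (positions absent from the pileup have
#'   zero depth and are excluded by the covered-length rule).
#' @return `data.frame` with columns `transcript`, `G` (geometric-mean
#'   depth) and `covered_length`.
#' @export
geometricMeanExpression <- function(pileup) {
  cc <- pileupColumns(pileup)
  cc <- cc[cc$depth >= 1L, , drop = FALSE]
  if (!nrow(cc))
    return(data.frame(transcript = character(), G = numeric(),
                      covered_length = integer(), stringsAsFactors = FALSE))
  dt <- data.table::data.table(transcript = cc$transcript, depth = cc$depth)
  res <- dt[, list(G = exp(mean(log(depth))),
                   covered_length = .N), by = "transcript"]
  out <- as.data.frame(res)
  out[match(unique(cc$transcript), out$transcript), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Median-of-ratios size factors for coverage-based expression
#'
#' The DESeq size-factor procedure applied to geometric-mean coverage
#' depths instead of read counts: each transcript's representative
#' expression is the geometric mean of its values across samples, and a
#' sample's size factor is the median ratio of its values to the
#' representatives. Transcripts with a zero in any sample are excluded
#' from the factor computation.
#'
#' @param G matrix-like, transcripts x samples, of geometric-mean depths.
#' @return named numeric vector of per-sample size factors; divide a
#'   sample's expression values by its factor to normalise.
#' @export
coverageSizeFactors <- function(G) {
  G <- as.matrix(G)
  if (!ncol(G)) stop("need at least one sample")
  usable <- rowSums(G > 0) == ncol(G)
  if (!any(usable))
    stop("size factors undefined: no transcript has positive expression in every sample")
  lg <- log(G[usable, , drop = FALSE])
  representative <- rowMeans(lg)
  factors <- exp(apply(lg - representative, 2L, median))
  setNames(factors, colnames(G))
}

#' Fractional expression at a dSNP position
#'
#' The portion of a transcript's expression attributable to one strain at
#' one discriminatory SNP: the fraction of reads covering the position
#' that carry the discriminating base, multiplied by the transcript's
#' geometric-mean coverage depth.
#'
#' @param G transcript geometric-mean depth (vectorised).
#' @param n reads covering the position.
#' @param ns reads carrying the discriminating base (`0 <= ns <= n`).
#' @return fractional expression values; 0 where `n == 0`.
#' @export
fractionalExpression <- function(G, n, ns) {
  stopifnot(all(G >= 0), all(n >= 0), all(ns >= 0), all(ns <= n))
  ifelse(n > 0, G * ns / n, 0)
}

#' Average strictly positive dSNP expression values
#'
#' Signal averaging across the dSNPs of one strain in one transcript:
#' only values greater than zero enter the mean, but if every value is
#' zero then zero is the reported value.
#'
#' @param values fractional expression values at one strain's dSNPs.
#' @return scalar allele-specific expression value.
#' @export
aseValues <- function(values) {
  stopifnot(length(values) >= 1L, all(values >= 0))
  pos <- values[values > 0]
  if (!length(pos)) return(0)
  mean(pos)
}

#' Read counts at dSNP positions from a polyploid sample
#'
#' For every dSNP, counts the reads covering the position (`n`, the raw
#' pileup depth) and the reads carrying the discriminating base (`ns`,
#' both strands). No base-quality filter is applied by default: every
#' aligned read dilutes or supports the allele fraction.
#'
#' @param pileup the polyploid sample as a [Pileup-class].
#' @param dsnps dSNP table from [findDsnps()] /
#'   [selectCompleteTranscripts()].
#' @param minBaseQuality Phred threshold for counting the discriminating
#'   base.
#' @return the dSNP table with columns `n` and `ns` appended (dSNP
#'   positions absent from the pileup get `n = ns = 0`).
#' @export
dsnpReadCounts <- function(pileup, dsnps, minBaseQuality = 0L) {
  cc <- pileupColumns(pileup)
  key <- paste(cc$transcript, cc$pos)
  idx <- match(paste(dsnps$transcript, dsnps$pos), key)
  out <- dsnps
  out$n <- as.integer(ifelse(is.na(idx), 0L, cc$depth[idx]))
  out$ns <- rep(0L, nrow(out))
  hit <- which(!is.na(idx) & out$n > 0L)
  if (length(hit)) {
    sub <- .new_pileup(cc[idx[hit], , drop = FALSE])
    tt <- tallyBases(sub, minBaseQuality = minBaseQuality)
    counts <- cbind(A = tt$A_plus + tt$A_minus, C = tt$C_plus + tt$C_minus,
                    G = tt$G_plus + tt$G_minus, T = tt$T_plus + tt$T_minus)
    out$ns[hit] <- counts[cbind(seq_along(hit),
                                match(out$base[hit], .BASES))]
  }
  out
}

#' Allele-specific expression values for dSNP-complete transcripts
#'
#' Combines per-dSNP fractional expression into one ASE value per strain
#' and transcript (zero-excluding signal averaging, [aseValues()]), plus
#' the whole-gene expression as the sum over strains.
#'
#' @param dsnpCounts dSNP table with read counts from [dsnpReadCounts()].
#' @param expression `data.frame` with columns `transcript` and `G`
#'   (normalised geometric-mean depth of the same sample).
#' @param strains character vector of all strain identifiers; every
#'   transcript in `dsnpCounts` must carry at least one dSNP per strain.
#' @return `data.frame`: `transcript`, one ASE column per strain, and
#'   `whole_gene` (their sum).
#' @export
computeAse <- function(dsnpCounts, expression, strains) {
  if (!nrow(dsnpCounts))
    return(cbind(data.frame(transcript = character(),
                            stringsAsFactors = FALSE),
                 matrix(numeric(), 0, length(strains),
                        dimnames = list(NULL, strains)),
                 data.frame(whole_gene = numeric())))
  per_tx <- split(dsnpCounts$strain, dsnpCounts$transcript)
  incomplete <- names(per_tx)[!vapply(per_tx, function(s)
    all(strains %in% s), logical(1))]
  if (length(incomplete))
    stop(sprintf("transcript(s) without a dSNP for every strain: %s",
                 paste(head(incomplete, 5L), collapse = ", ")))
  G <- expression$G[match(dsnpCounts$transcript, expression$transcript)]
  if (anyNA(G))
    stop("expression table lacks transcripts present in the dSNP table")
  frac <- fractionalExpression(G, dsnpCounts$n, dsnpCounts$ns)
  dt <- data.table::data.table(transcript = dsnpCounts$transcript,
                               strain = dsnpCounts$strain, frac = frac)
  agg <- dt[, list(ase = aseValues(frac)), by = c("transcript", "strain")]
  wide <- data.table::dcast(agg, transcript ~ strain, value.var = "ase")
  wide <- as.data.frame(wide)
  tx_order <- unique(dsnpCounts$transcript)
  wide <- wide[match(tx_order, wide$transcript),
               c("transcript", strains), drop = FALSE]
  wide$whole_gene <- rowSums(wide[, strains, drop = FALSE])
  rownames(wide) <- NULL
  wide
}

#' Spearman comparison of two whole-gene expression measures
#'
#' Rank correlation (average ranks for ties) between paired expression
#' measurements of the same transcripts, e.g. geometric-mean coverage
#' depth versus aligned fragment counts.
#'
#' @param x,y paired numeric vectors, length >= 2.
#' @return Spearman's rho.
#' @export
compareExpressionMeasures <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("need at least two paired observations")
  cor(x, y, method = "spearman")
}
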