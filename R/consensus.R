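#' Default consensus-calling thresholds
#'
#' The conservative VarScan-style constraints used for parental consensus
#' calling: a position needs 15x raw coverage to be considered at all;
#' reads need base quality >= 25 to count towards base tallies; a variant
#' must be supported by >= 20% of counted reads and by >= 5 reads, with a
#' one-sided Fisher exact p-value < 0.01 and both-strand support (the
#' minority strand carrying >= 10% of variant reads); a variant at
#' frequency >= 0.75 is called homozygous, otherwise a heterozygous IUPAC
#' code of reference and variant is emitted.
#'
#' @param minCoverage minimum raw depth for a position to be evaluated.
#' @param minBaseQuality minimum Phred base quality for a read to count.
#' @param minVarFreq minimum variant allele frequency (inclusive).
#' @param minVarReads minimum variant-supporting reads (inclusive).
#' @param maxP variant p-value must be strictly below this.
#' @param homFreq variant frequency at or above which the call is a
#'   homozygous variant.
#' @param strandMinFraction minimum fraction of variant reads on the
#'   minority strand.
#' @return named list of thresholds.
#' @export
consensusThresholds <- function(minCoverage = 15L, minBaseQuality = 25L,
                                minVarFreq = 0.20, minVarReads = 5L,
                                maxP = 0.01, homFreq = 0.75,
                                strandMinFraction = 0.10) {
  list(minCoverage = minCoverage, minBaseQuality = minBaseQuality,
       minVarFreq = minVarFreq, minVarReads = minVarReads, maxP = maxP,
       homFreq = homFreq, strandMinFraction = strandMinFraction)
}

.BASES <- c("A", "C", "G", "T")

#' Tally base observations per pileup position
#'
#' Resolves the pileup grammar of every column and counts A/C/G/T
#' observations by strand, excluding reads below the base-quality
#' threshold from the tallies (they still contribute to `depth`).
#' Deletion placeholders (`*`) and reference skips count towards depth
#' only.
#'
#' @param x a [Pileup-class] or [PileupColumn-class].
#' @param minBaseQuality Phred threshold below which reads are not counted.
#' @return a `data.frame` with columns `transcript`, `pos`, `ref`, `depth`,
#'   strand-resolved counts `A_plus` ... `T_minus`, per-base mean qualities
#'   `A_qual` ... `T_qual` (NA where uncounted), and `counted`, the total
#'   quality-passing A/C/G/T observations.
#' @export
tallyBases <- function(x, minBaseQuality = 25L) {
  if (is(x, "PileupColumn")) {
    obs <- observations(x)
    bases <- paste0(ifelse(obs$base == x@ref & obs$strand == "+", ".",
                    ifelse(obs$base == x@ref & obs$strand == "-", ",",
                    ifelse(obs$strand == "+", obs$base,
                           tolower(obs$base)))), collapse = "")
    quals <- paste0(intToUtf8(obs$quality + 33L, multiple = TRUE),
                    collapse = "")
    cc <- data.frame(transcript = x@transcript, pos = x@position,
                     ref = x@ref, depth = x@depth, bases = bases,
                     quals = quals, stringsAsFactors = FALSE)
  } else {
    stopifnot(is(x, "Pileup"))
    cc <- pileupColumns(x)
  }
  if (!nrow(cc)) {
    out <- cc[, c("transcript", "pos", "ref", "depth")]
    for (nm in c(paste0(rep(.BASES, each = 2), c("_plus", "_minus")),
                 paste0(.BASES, "_qual"), "counted"))
      out[[nm]] <- numeric(0)
    return(out)
  }
  m <- .pileupBaseCounts(cc$bases, cc$quals, cc$ref,
                         as.integer(minBaseQuality))
  if (any(m[, 14] != cc$depth))
    stop(sprintf(
      "mpileup format error: depth field disagrees with observations at %s:%d",
      cc$transcript[m[, 14] != cc$depth][1L],
      cc$pos[m[, 14] != cc$depth][1L]))
  out <- data.frame(transcript = cc$transcript, pos = cc$pos, ref = cc$ref,
                    depth = cc$depth, stringsAsFactors = FALSE)
  cols <- paste0(rep(.BASES, each = 2), c("_plus", "_minus"))
  for (j in seq_along(cols)) out[[cols[j]]] <- as.integer(m[, j])
  for (b in seq_along(.BASES)) {
    n <- m[, (b - 1) * 2 + 1] + m[, (b - 1) * 2 + 2]
    out[[paste0(.BASES[b], "_qual")]] <- ifelse(n > 0, m[, 8 + b] / n, NA_real_)
  }
  out$counted <- as.integer(m[, 13])
  out
}

#' One-sided exact test for variant support
#'
#' Fisher's exact one-sided p-value for the 2x2 table contrasting the
#' observed reference/variant read split with an all-reference expectation
#' (`[[ref, var], [ref + var, 0]]`), computed from the hypergeometric tail.
#' Small values indicate variant support unlikely under a no-variant model.
#'
#' @param refReads,varReads non-negative read counts (vectorised).
#' @return p-values in (0, 1].
#' @export
variantSignificance <- function(refReads, varReads) {
  stopifnot(all(refReads >= 0), all(varReads >= 0))
  n <- refReads + varReads
  p <- phyper(varReads - 1, m = varReads, n = 2 * refReads + varReads,
              k = n, lower.tail = FALSE)
  p[n == 0] <- 1
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Strand filter for variant calls
#'
#' A variant passes when both strands carry at least one supporting read
#' and the minority strand carries at least `minFraction` of the variant
#' reads (inclusive). Guards against strand-biased artifacts such as PCR
#' over-amplification.
#'
#' @param varPlus,varMinus variant-supporting reads per strand (vectorised).
#' @param minFraction minimum minority-strand fraction.
#' @return logical vector, `TRUE` = pass.
#' @export
strandCheck <- function(varPlus, varMinus, minFraction = 0.10) {
  stopifnot(all(varPlus >= 0), all(varMinus >= 0))
  total <- varPlus + varMinus
  minority <- pmin(varPlus, varMinus)
  total > 0 & minority >= 1 & (minority / total) >= minFraction
}

#' Call per-position IUPAC consensus codes for one strain
#'
#' Applies the full threshold chain of [consensusThresholds()] to each
#' position of a parental sample. Positions below the coverage floor are
#' `N` (`LOW_COVERAGE`); the single most frequent non-reference base (ties
#' broken alphabetically) is the candidate variant; candidates lacking 20%
#' frequency or 5 supporting reads fall back to a homozygous reference
#' call; candidates with support but failing the exact test or the strand
#' filter yield `N` flagged `INSIGNIFICANT` / `STRAND_FAIL`; called
#' variants are homozygous at frequency >= `homFreq`, else the
#' heterozygous IUPAC code of reference and variant.
#'
#' @param x a [Pileup-class], or a tally `data.frame` from [tallyBases()]
#'   (already quality-filtered at `thresholds$minBaseQuality`).
#' @param thresholds see [consensusThresholds()].
#' @param strain strain label stored on the returned track.
#' @return a [ConsensusTrack-class].
#' @export
callConsensus <- function(x, thresholds = consensusThresholds(),
                          strain = "strain") {
  tt <- if (is(x, "Pileup")) tallyBases(x, thresholds$minBaseQuality) else x
  n <- nrow(tt)
  if (n && !all(tt$ref %in% .BASES))
    stop(sprintf("unknown reference base '%s' at %s:%d",
                 tt$ref[!(tt$ref %in% .BASES)][1L],
                 tt$transcript[!(tt$ref %in% .BASES)][1L],
                 tt$pos[!(tt$ref %in% .BASES)][1L]))
  counts <- cbind(A = tt$A_plus + tt$A_minus, C = tt$C_plus + tt$C_minus,
                  G = tt$G_plus + tt$G_minus, T = tt$T_plus + tt$T_minus)
  if (!n) counts <- matrix(integer(), 0, 4,
                           dimnames = list(NULL, .BASES))
  ref_idx <- match(tt$ref, .BASES)
  nonref <- counts
  if (n) nonref[cbind(seq_len(n), ref_idx)] <- -1L
  var_idx <- max.col(nonref, ties.method = "first")
  var_reads <- if (n) nonref[cbind(seq_len(n), var_idx)] else integer()
  var_reads <- pmax(var_reads, 0L)
  ref_reads <- if (n) counts[cbind(seq_len(n), ref_idx)] else integer()
  qdepth <- tt$counted
  var_freq <- ifelse(qdepth > 0, var_reads / qdepth, 0)
  pvals <- variantSignificance(ref_reads, var_reads)

  plus_cols <- cbind(tt$A_plus, tt$C_plus, tt$G_plus, tt$T_plus)
  minus_cols <- cbind(tt$A_minus, tt$C_minus, tt$G_minus, tt$T_minus)
  var_plus <- if (n) plus_cols[cbind(seq_len(n), var_idx)] else integer()
  var_minus <- if (n) minus_cols[cbind(seq_len(n), var_idx)] else integer()
  strand_ok <- strandCheck(var_plus, var_minus, thresholds$strandMinFraction)

  low_cov <- tt$depth < thresholds$minCoverage
  supported <- var_reads >= thresholds$minVarReads &
    var_freq >= thresholds$minVarFreq
  insignificant <- supported & !(pvals < thresholds$maxP)
  strand_fail <- supported & !strand_ok
  variant_called <- supported & !insignificant & !strand_fail & !low_cov

  iupac <- tt$ref
  if (any(variant_called)) {
    vb <- .BASES[var_idx[variant_called]]
    hom <- var_freq[variant_called] >= thresholds$homFreq
    het_code <- as.character(Biostrings::mergeIUPACLetters(
      paste0(tt$ref[variant_called], vb)))
    iupac[variant_called] <- ifelse(hom, vb, het_code)
  }
  flags <- character(n)
  flagged <- low_cov | (insignificant & !low_cov) | (strand_fail & !low_cov)
  flag_of <- function(i) {
    f <- c(if (low_cov[i]) "LOW_COVERAGE",
           if (!low_cov[i] && insignificant[i]) "INSIGNIFICANT",
           if (!low_cov[i] && strand_fail[i]) "STRAND_FAIL")
    paste(f, collapse = ",")
  }
  if (any(flagged)) {
    flags[flagged] <- vapply(which(flagged), flag_of, character(1))
    iupac[flagged] <- "N"
  }
  calls <- data.frame(transcript = tt$transcript, pos = tt$pos, ref = tt$ref,
                      iupac = iupac, depth = tt$depth, var_freq = var_freq,
                      p_value = pvals, flags = flags,
                      stringsAsFactors = FALSE)
  new("ConsensusTrack", strain = strain, calls = calls,
      thresholds = thresholds)
}
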