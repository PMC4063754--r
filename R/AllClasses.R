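#' PileupColumn: one reference position of a samtools mpileup file
#'
#' Holds the fully resolved evidence at a single transcript position: the
#' reference base, total read depth, and one row per read observation with
#' the read base (A/C/G/T/N, `"*"` for a deletion placeholder, `">"` for a
#' reference skip), its strand and its Phred base quality. Deletion
#' placeholders count towards depth but are excluded from base tallies.
#'
#' @slot transcript single transcript identifier.
#' @slot position 1-based position on the transcript.
#' @slot ref reference base at the position.
#' @slot depth total number of read observations.
#' @slot observations `data.frame` with columns `base`, `strand`
#'   (`"+"`/`"-"`), `quality` (Phred integer).
#' @seealso [parseMpileupLine()], [tallyBases()]
#' @export
setClass("PileupColumn",
  representation(
    transcript = "character",
    position   = "integer",
    ref        = "character",
    depth      = "integer",
    observations = "data.frame"
  )
)

setValidity("PileupColumn", function(object) {
  msg <- character()
  if (length(object@transcript) != 1L || !nzchar(object@transcript))
    msg <- c(msg, "'transcript' must be a single non-empty string")
  if (length(object@position) != 1L || is.na(object@position) ||
      object@position < 1L)
    msg <- c(msg, "'position' must be a single integer >= 1")
  if (object@depth < 0L)
    msg <- c(msg, "'depth' must be non-negative")
  obs <- object@observations
  if (!all(c("base", "strand", "quality") %in% names(obs)))
    msg <- c(msg, "'observations' needs columns base, strand, quality")
  else {
    if (nrow(obs) != object@depth)
      msg <- c(msg, "depth must equal the number of observations")
    if (nrow(obs) && any(obs$quality < 0L))
      msg <- c(msg, "base qualities must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Pileup: a parsed multi-position mpileup sample
#'
#' Lightweight container for one sample's mpileup text, one row per covered
#' position, with the base and quality strings kept unresolved until they
#' are tallied (see [tallyBases()]). Positions absent from the table have
#' zero coverage.
#'
#' @slot columns `data.frame` with columns `transcript`, `pos`, `ref`,
#'   `depth`, `bases`, `quals`.
#' @seealso [readMpileup()], [writeMpileup()], [tallyBases()]
#' @export
setClass("Pileup", representation(columns = "data.frame"))

setValidity("Pileup", function(object) {
  need <- c("transcript", "pos", "ref", "depth", "bases", "quals")
  if (!all(need %in% names(object@columns)))
    return(sprintf("'columns' must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(object@columns) &&
      (any(object@columns$pos < 1L) || any(object@columns$depth < 0L)))
    return("positions must be >= 1 and depths >= 0")
  TRUE
})

#' ConsensusTrack: per-position consensus calls for one strain
#'
#' Result of [callConsensus()] over one parental sample: an IUPAC consensus
#' code per evaluated position together with the statistics that justified
#' it and any filter flags. Calls with a flag (or insufficient coverage)
#' are `N`.
#'
#' @slot strain strain/sample identifier.
#' @slot calls `data.frame` with columns `transcript`, `pos`, `ref`,
#'   `iupac`, `depth`, `var_freq`, `p_value`, `flags`.
#' @slot thresholds named list of the calling thresholds used.
#' @seealso [callConsensus()], [consensusThresholds()], [findDsnps()]
#' @export
setClass("ConsensusTrack",
  representation(strain = "character", calls = "data.frame",
                 thresholds = "list"))

setValidity("ConsensusTrack", function(object) {
  need <- c("transcript", "pos", "ref", "iupac", "depth", "var_freq",
            "p_value", "flags")
  if (length(object@strain) != 1L || !nzchar(object@strain))
    return("'strain' must be a single non-empty string")
  if (!all(need %in% names(object@calls)))
    return(sprintf("'calls' must have columns %s",
                   paste(need, collapse = ", ")))
  cc <- object@calls
  if (nrow(cc)) {
    flagged <- nzchar(cc$flags)
    if (any((cc$iupac == "N") != flagged))
      return("a call must be 'N' exactly when a filter flag is set")
  }
  TRUE
})

#' @describeIn PileupColumn number of read observations at the position
#' @param x,object a `PileupColumn`, `Pileup` or `ConsensusTrack`.
#' @export
setGeneric("pileupDepth", function(x) standardGeneric("pileupDepth"))
setMethod("pileupDepth", "PileupColumn", function(x) x@depth)

#' @describeIn PileupColumn per-read observation table
#' @export
setGeneric("observations", function(x) standardGeneric("observations"))
setMethod("observations", "PileupColumn", function(x) x@observations)

#' @describeIn Pileup the per-position table of a `Pileup`
#' @export
setGeneric("pileupColumns", function(x) standardGeneric("pileupColumns"))
setMethod("pileupColumns", "Pileup", function(x) x@columns)

#' @describeIn ConsensusTrack the per-position call table
#' @export
setGeneric("consensusCalls", function(x) standardGeneric("consensusCalls"))
setMethod("consensusCalls", "ConsensusTrack", function(x) x@calls)

#' @describeIn ConsensusTrack strain identifier of a track
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))
setMethod("strainId", "ConsensusTrack", function(x) x@strain)

setMethod("show", "PileupColumn", function(object) {
  cat(sprintf("PileupColumn %s:%d ref=%s depth=%d\n", object@transcript,
              object@position, object@ref, object@depth))
})

setMethod("show", "Pileup", function(object) {
  cc <- object@columns
  cat(sprintf("Pileup with %d positions on %d transcript(s)\n",
              nrow(cc), length(unique(cc$transcript))))
  if (nrow(cc))
    cat(sprintf("  depth: min %d, median %g, max %d\n",
                min(cc$depth), stats::median(cc$depth), max(cc$depth)))
})

setMethod("show", "ConsensusTrack", function(object) {
  cc <- object@calls
  cat(sprintf("ConsensusTrack '%s': %d positions, %d flagged N\n",
              object@strain, nrow(cc), sum(cc$iupac == "N")))
})
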