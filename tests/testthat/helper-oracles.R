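# Independent oracles and fixture builders shared across the suite.

# Exact-test oracle: enumerate the hypergeometric support for the 2x2
# table [[ref, var], [ref+var, 0]] and sum P(X >= var) directly.
oracle_variant_p <- function(ref, var) {
  if (ref + var == 0) return(1)
  support <- 0:var  # X = variant reads in the observed row
  probs <- dhyper(support, m = var, n = 2 * ref + var, k = ref + var)
  sum(probs[support >= var])
}

# Threshold-chain oracle: applies the six consensus rules one by one to a
# single configuration (all reads quality-passing, ref "C", variant "T",
# variant strand split vp/vm). Returns list(iupac, flags) with flags as a
# character set.
oracle_consensus <- function(depth, var, vp, vm,
                             th = consensusThresholds()) {
  stopifnot(vp + vm == var)
  if (depth < th$minCoverage)
    return(list(iupac = "N", flags = "LOW_COVERAGE"))
  ref <- depth - var
  freq <- if (depth > 0) var / depth else 0
  if (!(var >= th$minVarReads && freq >= th$minVarFreq))
    return(list(iupac = "C", flags = character()))
  flags <- character()
  p <- oracle_variant_p(ref, var)
  if (!(p < th$maxP)) flags <- c(flags, "INSIGNIFICANT")
  strand_ok <- vp >= 1 && vm >= 1 &&
    (min(vp, vm) / var) >= th$strandMinFraction
  if (!strand_ok) flags <- c(flags, "STRAND_FAIL")
  if (length(flags)) return(list(iupac = "N", flags = flags))
  if (freq >= th$homFreq) return(list(iupac = "T", flags = character()))
  list(iupac = "Y", flags = character())  # IUPAC C/T
}

# Build a tally row (as produced by tallyBases) for the oracle scenarios:
# ref "C" reads split evenly across strands, variant "T" split vp/vm.
make_tally_row <- function(depth, var, vp, vm, transcript = "t",
                           pos = 1L) {
  ref <- depth - var
  rp <- ceiling(ref / 2)
  data.frame(transcript = transcript, pos = pos, ref = "C", depth = depth,
             A_plus = 0L, A_minus = 0L, C_plus = rp, C_minus = ref - rp,
             G_plus = 0L, G_minus = 0L, T_plus = vp, T_minus = vm,
             A_qual = NA_real_, C_qual = 40, G_qual = NA_real_,
             T_qual = 40, counted = depth, stringsAsFactors = FALSE)
}

# Serialise observations into an mpileup line (independent of the package
# writer): optional read-start/read-end markers and indel strings exercise
# the grammar.
make_mpileup_line <- function(transcript, pos, ref, obs, decorate = FALSE) {
  sym <- ifelse(obs$base == "*", "*",
         ifelse(obs$base == ref & obs$strand == "+", ".",
         ifelse(obs$base == ref & obs$strand == "-", ",",
         ifelse(obs$strand == "+", obs$base, tolower(obs$base)))))
  if (decorate && nrow(obs)) {
    first <- paste0("^!", sym[1])
    last <- if (nrow(obs) > 1) paste0(sym[nrow(obs)], "$") else NULL
    mid <- if (nrow(obs) > 2) sym[2:(nrow(obs) - 1)] else NULL
    if (nrow(obs) > 1) sym <- c(first, mid, last) else sym <- first
    if (nrow(obs) > 2) sym[2] <- paste0(sym[2], "+2AG")
  }
  if (!nrow(obs))  # samtools writes "*	*" placeholders at depth 0
    return(paste(transcript, pos, ref, 0L, "*", "*", sep = "\t"))
  quals <- intToUtf8(obs$quality + 33L, multiple = FALSE)
  paste(transcript, pos, ref, nrow(obs), paste(sym, collapse = ""),
        quals, sep = "\t")
}

random_observations <- function(n, ref) {
  obs <- data.frame(
    base = sample(c("A", "C", "G", "T", ref, ref, "*"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    quality = sample(0:60, n, replace = TRUE),
    stringsAsFactors = FALSE)
  obs$strand[obs$base == "*"] <- "+"  # deletion placeholders are strandless
  obs
}

# Consensus track data.frame from per-position IUPAC codes (helper for
# dSNP tests; flags kept consistent with the N rule).
make_track <- function(transcript, positions, ref, iupac) {
  data.frame(transcript = transcript, pos = positions, ref = ref,
             iupac = iupac, depth = 50L,
             var_freq = 0, p_value = 1,
             flags = ifelse(iupac == "N", "LOW_COVERAGE", ""),
             stringsAsFactors = FALSE)
}

# Small end-to-end scenario built from the module functions with full
# control over which strains carry variants in which transcript.
build_custom_experiment <- function(variants, transcriptLength = 600L,
                                    strains = c("HNI", "OR", "SOK"),
                                    parentFragments = 200L,
                                    polyCounts, seed = 99L) {
  set.seed(seed)
  tx_ids <- unique(variants$transcript)
  reference <- setNames(vapply(tx_ids, function(i)
    paste(sample(c("A", "C", "G", "T"), transcriptLength, replace = TRUE),
          collapse = ""), character(1)), tx_ids)
  # force variant bases to differ from the drawn reference
  for (i in seq_len(nrow(variants))) {
    rb <- substr(reference[[variants$transcript[i]]], variants$pos[i],
                 variants$pos[i])
    if (variants$base[i] == rb)
      variants$base[i] <- setdiff(c("A", "C", "G", "T"), rb)[1]
  }
  strainSeqs <- lapply(setNames(strains, strains), function(s) {
    out <- reference
    v <- variants[variants$strain == s, , drop = FALSE]
    for (tx in unique(v$transcript)) {
      vt <- v[v$transcript == tx, , drop = FALSE]
      out[[tx]] <- buildStrainReference(reference[[tx]], vt$pos, vt$base)
    }
    out
  })
  place <- function(tx, strain, n) {
    if (n == 0) return(NULL)
    cbind(data.frame(transcript = tx, strain = strain,
                     stringsAsFactors = FALSE),
          generateFragments(transcriptLength, n))
  }
  parentPileups <- lapply(setNames(strains, strains), function(s)
    placementsToPileup(do.call(rbind, lapply(tx_ids, place, strain = s,
                                             n = parentFragments)),
                       strainSeqs[s], reference))
  poly_pl <- do.call(rbind, unlist(lapply(tx_ids, function(tx)
    lapply(strains, function(s) place(tx, s, polyCounts[[tx]][[s]]))),
    recursive = FALSE))
  list(reference = reference, variants = variants,
       strainSeqs = strainSeqs, parentPileups = parentPileups,
       polyploidPileup = placementsToPileup(poly_pl, strainSeqs,
                                            reference))
}
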