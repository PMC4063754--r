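#' Draw strain-specific variant positions for a synthetic experiment
#'
#' Samples, for every transcript, `perStrain` distinct positions per
#' strain (no two strains share a position) and a substitution base
#' different from the reference at each. By construction every such site
#' is homozygous-different in exactly one strain and identical to the
#' reference elsewhere, i.e. a true discriminatory SNP.
#'
#' @param reference named character vector or `DNAStringSet` of transcript
#'   sequences.
#' @param strains strain identifiers.
#' @param perStrain variants per strain per transcript.
#' @return `data.frame`: `transcript`, `pos`, `strain`, `base` (uses the
#'   current RNG state).
#' @export
simulateStrainVariants <- function(reference, strains, perStrain = 5L) {
  seqs <- if (is.character(reference)) reference
          else setNames(as.character(reference), names(reference))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    need <- perStrain * length(strains)
    if (L < need)
      stop(sprintf("transcript '%s' too short for %d variant positions",
                   names(seqs)[i], need))
    pos <- sort(sample.int(L, need))
    strain <- sample(rep(strains, each = perStrain))
    ref_base <- substring(seqs[i], pos, pos)
    base <- vapply(ref_base, function(r)
      sample(setdiff(.BASES, r), 1L), character(1), USE.NAMES = FALSE)
    out[[i]] <- data.frame(transcript = names(seqs)[i], pos = pos,
                           strain = strain, base = base,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Substitute strain-specific variants into a reference sequence
#'
#' @param sequence a single reference transcript sequence (character or
#'   `DNAString`-like).
#' @param positions 1-based substitution positions.
#' @param bases substituted nucleotides (same length as `positions`).
#' @return the strain-specific sequence as a character scalar.
#' @export
buildStrainReference <- function(sequence, positions, bases) {
  s <- as.character(sequence)
  stopifnot(length(positions) == length(bases))
  if (!length(positions)) return(s)
  if (any(positions < 1L) || any(positions > nchar(s)))
    stop("variant position outside the transcript")
  ref <- substring(s, positions, positions)
  if (any(ref == bases))
    warning("substitution equal to the reference base (non-discriminating)")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  chars[positions] <- bases
  paste(chars, collapse = "")
}

#' Apportion a fragment total between strains by their ASE values
#'
#' Fragment counts are proportional to each strain's share of the summed
#' ASE values, integerised by the largest-remainder rule (ties broken by
#' strain order) so the counts always sum exactly to `total`.
#'
#' @param total total fragments to allocate.
#' @param ase non-negative per-strain ASE values, sum > 0 when
#'   `total > 0`.
#' @return integer vector of per-strain fragment counts.
#' @export
allocateReads <- function(total, ase) {
  stopifnot(total >= 0, all(ase >= 0))
  if (total == 0) return(setNames(rep(0L, length(ase)), names(ase)))
  if (sum(ase) <= 0) stop("cannot allocate reads: all ASE values are zero")
  exact <- total * ase / sum(ase)
  counts <- as.integer(floor(exact))
  short <- total - sum(counts)
  if (short > 0) {
    extra <- order(exact - floor(exact), decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  setNames(counts, names(ase))
}

#' Generate error-free paired-end fragment placements for one transcript
#'
#' Places `n` fragments of `fragLen` bp uniformly over the valid start
#' positions and derives the paired `readLen` bp mates in the standard
#' FR layout of an aligned proper pair: the leftmost mate on the forward
#' strand, the rightmost on the reverse strand, with the inner gap
#' uncovered. A consequence mirrored from real transcriptome alignments
#' is that positions within `fragLen - readLen` of a transcript end see
#' mostly single-strand coverage. Transcripts shorter than `fragLen`
#' yield single reads of `min(length, readLen)` bp in random orientation
#' (as unstranded cDNA fragments align either way).
#'
#' @param transcriptLength length of the (strain-specific) transcript.
#' @param n fragments to generate.
#' @param readLen,fragLen read and fragment lengths in bp.
#' @return `data.frame` of placements: `start`, `r1_start`, `r1_end`,
#'   `r1_strand`, `r2_start`, `r2_end`, `r2_strand` (`NA` mate columns
#'   for unpaired reads) — uses the current RNG state.
#' @export
generateFragments <- function(transcriptLength, n, readLen = 100L,
                              fragLen = 250L) {
  stopifnot(n >= 0, transcriptLength >= 1)
  if (n == 0)
    return(data.frame(start = integer(), r1_start = integer(),
                      r1_end = integer(), r1_strand = character(),
                      r2_start = integer(), r2_end = integer(),
                      r2_strand = character(), stringsAsFactors = FALSE))
  if (transcriptLength >= fragLen) {
    nstart <- transcriptLength - fragLen + 1L
    start <- sample.int(nstart, n, replace = TRUE)
    data.frame(start = start, r1_start = start,
               r1_end = start + readLen - 1L, r1_strand = "+",
               r2_start = start + fragLen - readLen,
               r2_end = start + fragLen - 1L, r2_strand = "-",
               stringsAsFactors = FALSE)
  } else {
    rl <- min(transcriptLength, readLen)
    nstart <- transcriptLength - rl + 1L
    start <- sample.int(nstart, n, replace = TRUE)
    data.frame(start = start, r1_start = start, r1_end = start + rl - 1L,
               r1_strand = sample(c("+", "-"), n, replace = TRUE),
               r2_start = NA_integer_, r2_end = NA_integer_,
               r2_strand = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Write placements as a FASTQ read pair
#'
#' Emits the exact substrings of the strain-specific sequences as R1 and
#' (reverse-complemented) R2 with uniform quality `I` (Phred 40).
#'
#' @param placements placement table with `transcript`, `strain` and the
#'   coordinate columns of [generateFragments()].
#' @param strainSeqs named list (by strain) of named character vectors (by
#'   transcript) of strain-specific sequences.
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and, when
#'   any placement is paired, `<prefix>_R2.fastq`.
#' @return invisible character vector of written paths.
#' @export
writeFastq <- function(placements, strainSeqs, prefix) {
  p <- placements
  seqs <- vapply(seq_len(nrow(p)), function(i)
    strainSeqs[[p$strain[i]]][[p$transcript[i]]], character(1))
  as_read <- function(seq, strand) {
    rc <- strand == "-"
    if (any(rc))
      seq[rc] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seq[rc])))
    seq
  }
  r1 <- as_read(substring(seqs, p$r1_start, p$r1_end), p$r1_strand)
  ids <- sprintf("@frag%06d_%s_%s_%d", seq_len(nrow(p)), p$transcript,
                 p$strain, p$start)
  q1 <- strrep("I", nchar(r1))
  f1 <- paste0(prefix, "_R1.fastq")
  writeLines(as.vector(rbind(paste0(ids, "/1"), r1, "+", q1)), f1)
  paths <- f1
  paired <- !is.na(p$r2_start)
  if (any(paired)) {
    r2 <- as_read(substring(seqs[paired], p$r2_start[paired],
                            p$r2_end[paired]), p$r2_strand[paired])
    f2 <- paste0(prefix, "_R2.fastq")
    writeLines(as.vector(rbind(paste0(ids[paired], "/2"), r2, "+",
                               strrep("I", nchar(r2)))), f2)
    paths <- c(paths, f2)
  }
  invisible(paths)
}

# cumulative coverage of [start, end] segments over positions 1..L
.segment_coverage <- function(starts, ends, L) {
  if (!length(starts)) return(integer(L))
  d <- integer(L + 1L)
  tab_s <- tabulate(starts, nbins = L)
  tab_e <- tabulate(pmin(ends, L) + 1L, nbins = L + 1L)
  d[seq_len(L)] <- tab_s
  d <- d - tab_e
  cumsum(d[seq_len(L)])
}

#' Build a pileup directly from known fragment placements
#'
#' Replaces the alignment step for synthetic data: since every read is an
#' exact substring of a strain-specific reference, its per-position base
#' evidence is known, and the pileup can be constructed from the truth
#' placements. Forward mates contribute plus-strand observations, reverse
#' mates minus-strand; all base qualities are `I` (Phred 40).
#'
#' @param placements placement table with columns `transcript`, `strain`,
#'   `r1_start`, `r1_end`, `r2_start`, `r2_end`.
#' @param strainSeqs named list (by strain) of named character vectors (by
#'   transcript) of strain-specific sequences.
#' @param reference named character vector (or `DNAStringSet`) of the
#'   original reference transcripts.
#' @return a [Pileup-class] over all covered positions.
#' @export
placementsToPileup <- function(placements, strainSeqs, reference) {
  ref <- if (is.character(reference)) reference
         else setNames(as.character(reference), names(reference))
  strains <- names(strainSeqs)
  tx_ids <- unique(placements$transcript)
  out <- vector("list", length(tx_ids))
  by_tx <- split(placements, factor(placements$transcript, levels = tx_ids))
  for (t in seq_along(tx_ids)) {
    tx <- tx_ids[t]
    L <- nchar(ref[[tx]])
    rchars <- strsplit(ref[[tx]], "", fixed = TRUE)[[1]]
    p <- by_tx[[t]]
    parts <- matrix(character(0), nrow = L, ncol = 0)
    depth <- integer(L)
    for (s in strains) {
      ps <- p[p$strain == s, , drop = FALSE]
      schars <- strsplit(strainSeqs[[s]][[tx]], "", fixed = TRUE)[[1]]
      if (length(schars) != L)
        stop(sprintf("strain sequence length mismatch for '%s'", tx))
      paired <- !is.na(ps$r2_start)
      plus1 <- ps$r1_strand == "+"
      plus2 <- paired & ps$r2_strand == "+"
      dp <- .segment_coverage(c(ps$r1_start[plus1], ps$r2_start[plus2]),
                              c(ps$r1_end[plus1], ps$r2_end[plus2]), L)
      dm <- .segment_coverage(c(ps$r1_start[!plus1], ps$r2_start[paired & !plus2]),
                              c(ps$r1_end[!plus1], ps$r2_end[paired & !plus2]), L)
      sym_p <- ifelse(schars == rchars, ".", schars)
      sym_m <- ifelse(schars == rchars, ",", tolower(schars))
      parts <- cbind(parts, strrep(sym_p, dp), strrep(sym_m, dm))
      depth <- depth + dp + dm
    }
    bases <- do.call(paste0, as.data.frame(parts, stringsAsFactors = FALSE))
    covered <- depth > 0L
    if (!any(covered)) next
    out[[t]] <- data.frame(transcript = tx, pos = which(covered),
                           ref = rchars[covered], depth = depth[covered],
                           bases = bases[covered],
                           quals = strrep("I", depth[covered]),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(.new_pileup(.empty_pileup_columns()))
  .new_pileup(do.call(rbind, out))
}

#' Per-transcript correlation between true and recovered ASE values
#'
#' For every transcript, Pearson's correlation between the generating
#' (true) per-strain expression values and the pipeline's estimates.
#' Transcripts where either vector is constant have no defined
#' correlation and are flagged; note that near-equal true values yield
#' correlations near zero even when the absolute recovery error is small.
#'
#' @param truth,estimates `data.frame`s with a `transcript` column and one
#'   numeric column per strain; the same transcripts and strains.
#' @param strains strain identifiers naming the value columns.
#' @return list: `per_transcript` (`transcript`, `r`, `constant` flag),
#'   `fraction_gt_0.8`, `fraction_ge_0.9` (over all transcripts; undefined
#'   correlations count as failures) and `n`.
#' @export
evaluateRecovery <- function(truth, estimates, strains) {
  if (length(setdiff(truth$transcript, estimates$transcript)) ||
      length(setdiff(estimates$transcript, truth$transcript)))
    stop("truth and estimates cover different transcript sets")
  est <- estimates[match(truth$transcript, estimates$transcript), ,
                   drop = FALSE]
  tv <- as.matrix(truth[, strains, drop = FALSE])
  ev <- as.matrix(est[, strains, drop = FALSE])
  n <- nrow(tv)
  r <- rep(NA_real_, n)
  const <- logical(n)
  for (i in seq_len(n)) {
    if (stats::sd(tv[i, ]) == 0 || stats::sd(ev[i, ]) == 0) {
      const[i] <- TRUE
    } else {
      r[i] <- cor(tv[i, ], ev[i, ])
    }
  }
  list(per_transcript = data.frame(transcript = truth$transcript, r = r,
                                   constant = const,
                                   stringsAsFactors = FALSE),
       fraction_gt_0.8 = sum(!is.na(r) & r > 0.8) / n,
       fraction_ge_0.9 = sum(!is.na(r) & r >= 0.9) / n,
       n = n)
}

#' Simulate a full polyploid ASE experiment with known truth
#'
#' Generates a random transcriptome, strain-specific variants, parental
#' RNA-seq pileups (each parent expressing only its own haplome) and a
#' polyploid pileup whose per-transcript allele fractions are drawn from
#' a Dirichlet distribution. Reads are error-free 100 bp pairs at 250 bp
#' fragment size placed uniformly; pileups are built from the truth
#' placements, so no aligner is involved.
#'
#' @param nTranscripts number of transcripts.
#' @param transcriptLength length of every transcript (bp).
#' @param strains strain identifiers (ploidy = number of strains).
#' @param dsnpsPerStrain strain-specific variants per transcript.
#' @param fragmentsRange integer range from which each transcript's total
#'   polyploid fragment count is drawn uniformly.
#' @param parentFragments fragments per transcript in each parental
#'   sample.
#' @param dirichletAlpha concentration parameters for the allele
#'   fractions (defaults to the flat Dirichlet).
#' @param readLen,fragLen read and fragment lengths (bp).
#' @param seed RNG seed; the whole simulation is reproducible from it.
#' @return list: `reference` (named character), `variants`, `strainSeqs`,
#'   `truth` (`transcript`, per-strain true fragment counts, per-strain
#'   `frac_*` fractions, `total`), `parentPileups` (named list of
#'   [Pileup-class]), `polyploidPileup`, `placements`.
#' @export
simulateTriploidExperiment <- function(nTranscripts = 300L,
                                       transcriptLength = 1500L,
                                       strains = c("HNI", "OR", "SOK"),
                                       dsnpsPerStrain = 5L,
                                       fragmentsRange = c(200L, 2000L),
                                       parentFragments = 400L,
                                       dirichletAlpha = c(1, 1, 1),
                                       readLen = 100L, fragLen = 250L,
                                       seed = 1L) {
  stopifnot(length(dirichletAlpha) == length(strains))
  set.seed(seed)
  tx_ids <- sprintf("tx%04d", seq_len(nTranscripts))
  reference <- setNames(vapply(seq_len(nTranscripts), function(i)
    paste(sample(.BASES, transcriptLength, replace = TRUE), collapse = ""),
    character(1)), tx_ids)
  variants <- simulateStrainVariants(reference, strains,
                                     perStrain = dsnpsPerStrain)
  strainSeqs <- lapply(setNames(strains, strains), function(s) {
    v <- variants[variants$strain == s, , drop = FALSE]
    out <- reference
    for (tx in unique(v$transcript)) {
      vt <- v[v$transcript == tx, , drop = FALSE]
      out[[tx]] <- buildStrainReference(reference[[tx]], vt$pos, vt$base)
    }
    out
  })

  place_one <- function(tx, strain, n) {
    if (n == 0) return(NULL)
    pl <- generateFragments(transcriptLength, n, readLen = readLen,
                            fragLen = fragLen)
    cbind(data.frame(transcript = tx, strain = strain,
                     stringsAsFactors = FALSE), pl)
  }

  parentPileups <- list()
  parent_placements <- list()
  for (s in strains) {
    pls <- lapply(tx_ids, place_one, strain = s, n = parentFragments)
    pl <- do.call(rbind, pls)
    parent_placements[[s]] <- pl
    parentPileups[[s]] <- placementsToPileup(pl, strainSeqs[s], reference)
  }

  fracs <- matrix(rgamma(nTranscripts * length(strains),
                         shape = rep(dirichletAlpha, each = nTranscripts)),
                  nrow = nTranscripts)
  fracs <- fracs / rowSums(fracs)
  totals <- sample(seq.int(fragmentsRange[1], fragmentsRange[2]),
                   nTranscripts, replace = TRUE)
  counts <- t(vapply(seq_len(nTranscripts), function(i)
    allocateReads(totals[i], fracs[i, ]), numeric(length(strains))))
  colnames(counts) <- strains
  colnames(fracs) <- paste0("frac_", strains)
  truth <- data.frame(transcript = tx_ids, counts, fracs, total = totals,
                      check.names = FALSE, stringsAsFactors = FALSE)

  poly_placements <- do.call(rbind, unlist(lapply(seq_len(nTranscripts),
    function(i) lapply(strains, function(s)
      place_one(tx_ids[i], s, counts[i, s]))), recursive = FALSE))
  polyploidPileup <- placementsToPileup(poly_placements, strainSeqs,
                                        reference)
  list(reference = reference, variants = variants, strainSeqs = strainSeqs,
       truth = truth, parentPileups = parentPileups,
       polyploidPileup = polyploidPileup,
       placements = list(parents = parent_placements,
                         polyploid = poly_placements))
}
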