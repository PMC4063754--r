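#' Configuration for an end-to-end ASE run
#'
#' @param strainPileups named list: one mpileup path or [Pileup-class] per
#'   parental strain (>= 2 strains; >= 3 for a triploid design).
#' @param polyploidPileups named list of mpileup paths or `Pileup`s for
#'   the polyploid individuals.
#' @param thresholds consensus thresholds, see [consensusThresholds()].
#' @param alpha,fold,cvThreshold imbalance-classification parameters, see
#'   [classifyImbalance()].
#' @param annotation optional transcript-to-chromosome table for
#'   [chromosomeRankTable()] (columns `transcript`, `chromosome`,
#'   `order`).
#' @param outDir optional directory for TSV outputs.
#' @return a config list for [runAsePipeline()].
#' @export
aseRunConfig <- function(strainPileups, polyploidPileups,
                         thresholds = consensusThresholds(), alpha = 0.01,
                         fold = 2, cvThreshold = sqrt(3) / 2,
                         annotation = NULL, outDir = NULL) {
  if (is.null(names(strainPileups)) || length(strainPileups) < 2L)
    stop("need a named list of at least two strain pileups")
  if (is.null(names(polyploidPileups)) || !length(polyploidPileups))
    stop("need a named list of polyploid pileups")
  list(strainPileups = strainPileups, polyploidPileups = polyploidPileups,
       thresholds = thresholds, alpha = alpha, fold = fold,
       cvThreshold = cvThreshold, annotation = annotation, outDir = outDir)
}

.as_pileup <- function(x) {
  if (is(x, "Pileup")) x else readMpileup(x)
}

#' Run the consensus - dSNP - ASE - imbalance pipeline
#'
#' Executes the full analysis chain: per-strain consensus calling,
#' discriminatory-SNP discovery restricted to transcripts informative for
#' every strain, geometric-mean expression with median-of-ratios
#' normalisation across all samples, per-polyploid ASE values, and
#' allelic-imbalance classification against the parental average (plus
#' cross-individual concordance when two or more polyploids are given).
#' Deterministic given its inputs; writes TSV reports (and a run log of
#' per-stage record counts) when `config$outDir` is set.
#'
#' @param config a list from [aseRunConfig()].
#' @return list: `consensus` (per-strain [ConsensusTrack-class]),
#'   `dsnps` (all discriminatory SNPs), `completeDsnps` and
#'   `transcripts` (after the every-strain filter), `expression`
#'   (normalised G matrix as a `data.frame`), `sizeFactors`, `ase` and
#'   `imbalance` (named lists per polyploid), `concordance` (or `NULL`),
#'   `chromosomeTable` (or `NULL`) and `funnel` (stage counts).
#' @export
runAsePipeline <- function(config) {
  strains <- names(config$strainPileups)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  consensus <- list()
  samples_G <- list()
  for (s in strains) {
    pl <- stage(paste0("read:", s), .as_pileup(config$strainPileups[[s]]))
    consensus[[s]] <- stage(paste0("consensus:", s),
      callConsensus(pl, config$thresholds, strain = s))
    samples_G[[s]] <- geometricMeanExpression(pl)
  }
  poly <- lapply(config$polyploidPileups, .as_pileup)
  for (p in names(poly))
    samples_G[[p]] <- geometricMeanExpression(poly[[p]])

  dsnps <- stage("dsnp", findDsnps(consensus))
  sel <- selectCompleteTranscripts(dsnps, strains)

  all_tx <- unique(unlist(lapply(samples_G, function(g) g$transcript)))
  Gmat <- matrix(0, nrow = length(all_tx), ncol = length(samples_G),
                 dimnames = list(all_tx, names(samples_G)))
  for (nm in names(samples_G))
    Gmat[samples_G[[nm]]$transcript, nm] <- samples_G[[nm]]$G
  if (length(all_tx)) {
    factors <- stage("normalise", coverageSizeFactors(Gmat))
    Gnorm <- sweep(Gmat, 2L, factors, "/")
  } else {
    factors <- setNames(rep(1, length(samples_G)), names(samples_G))
    Gnorm <- Gmat
  }

  parental_mean <- data.frame(
    transcript = all_tx,
    parental_mean = if (length(all_tx))
      rowMeans(Gnorm[, strains, drop = FALSE]) else numeric(),
    stringsAsFactors = FALSE)

  ase <- list()
  imbalance <- list()
  for (p in names(poly)) {
    expr_tab <- data.frame(transcript = all_tx,
                           G = if (length(all_tx)) Gnorm[, p] else numeric(),
                           stringsAsFactors = FALSE)
    obs <- stage(paste0("ase:", p),
                 dsnpReadCounts(poly[[p]], sel$dsnps))
    ase[[p]] <- stage(paste0("ase:", p),
                      computeAse(obs, expr_tab, strains))
    imbalance[[p]] <- stage(paste0("imbalance:", p),
      classifyImbalance(ase[[p]], strains,
                        parentalExpression = parental_mean,
                        alpha = config$alpha, fold = config$fold,
                        cvThreshold = config$cvThreshold))
  }

  conc <- NULL
  if (length(imbalance) >= 2L)
    conc <- stage("concordance",
                  concordance(imbalance[[1L]], imbalance[[2L]]))
  chrom <- NULL
  if (!is.null(config$annotation) && length(imbalance))
    chrom <- stage("chromosome",
                   chromosomeRankTable(imbalance[[1L]], config$annotation))

  funnel <- funnelSummary(
    dsnpCount = nrow(sel$dsnps),
    transcriptCount = length(sel$transcripts),
    sitesEvaluated = sum(vapply(consensus, function(tr)
      as.numeric(nrow(consensusCalls(tr))), numeric(1))) /
      max(length(strains), 1L),
    informationalSites = length(unique(paste(dsnps$transcript, dsnps$pos))))

  result <- list(consensus = consensus, dsnps = dsnps,
                 completeDsnps = sel$dsnps, transcripts = sel$transcripts,
                 expression = as.data.frame(Gnorm), sizeFactors = factors,
                 ase = ase, imbalance = imbalance, concordance = conc,
                 chromosomeTable = chrom, funnel = funnel)
  if (!is.null(config$outDir)) .write_pipeline_outputs(result, config)
  result
}

#' Funnel summary of a dSNP discovery run
#'
#' The per-stage record counts a run reports: positions evaluated,
#' informational (dSNP-bearing) sites, dSNPs retained in transcripts
#' informative for every strain, those transcripts, and the mean number
#' of dSNPs per retained transcript.
#'
#' @param dsnpCount dSNPs in every-strain-complete transcripts.
#' @param transcriptCount number of those transcripts.
#' @param sitesEvaluated positions with a consensus call (per strain).
#' @param informationalSites distinct sites discriminating any strain.
#' @return named list of counts, including `meanDsnpsPerTranscript`.
#' @export
funnelSummary <- function(dsnpCount, transcriptCount,
                          sitesEvaluated = NA_real_,
                          informationalSites = NA_real_) {
  list(sitesEvaluated = sitesEvaluated,
       informationalSites = informationalSites,
       dsnpCount = dsnpCount, transcriptCount = transcriptCount,
       meanDsnpsPerTranscript = if (transcriptCount > 0)
         dsnpCount / transcriptCount else NA_real_)
}

.write_pipeline_outputs <- function(result, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outDir, ...)
  for (s in names(result$consensus))
    writeReportTable(consensusCalls(result$consensus[[s]]),
                     out(sprintf("consensus_%s.tsv", s)))
  writeReportTable(result$dsnps, out("dsnps.tsv"))
  writeReportTable(result$completeDsnps, out("dsnps_complete.tsv"))
  for (p in names(result$ase))
    writeReportTable(result$ase[[p]], out(sprintf("ase_%s.tsv", p)))
  for (p in names(result$imbalance))
    writeReportTable(result$imbalance[[p]],
                     out(sprintf("imbalance_%s.tsv", p)))
  f <- result$funnel
  log_lines <- c(
    sprintf("sites_evaluated\t%s", f$sitesEvaluated),
    sprintf("informational_sites\t%s", f$informationalSites),
    sprintf("dsnps_complete\t%s", f$dsnpCount),
    sprintf("transcripts_complete\t%s", f$transcriptCount),
    sprintf("mean_dsnps_per_transcript\t%s",
            formatC(f$meanDsnpsPerTranscript, digits = 6, format = "g")),
    sprintf("ase_records_%s\t%d", names(result$ase),
            vapply(result$ase, nrow, integer(1))))
  writeLines(log_lines, out("run_log.tsv"))
  invisible(NULL)
}
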