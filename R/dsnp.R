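# 4-bit expansion masks (A=1, C=2, G=4, T=8) for the 15 IUPAC codes + N
.iupac_masks <- local({
  map <- Biostrings::IUPAC_CODE_MAP
  masks <- vapply(strsplit(unname(map), ""), function(b)
    sum(c(A = 1L, C = 2L, G = 4L, T = 8L)[b]), integer(1))
  names(masks) <- names(map)
  masks
})

.iupac_mask <- function(code) {
  m <- .iupac_masks[code]
  if (any(is.na(m)))
    stop(sprintf("not an IUPAC nucleotide code: '%s'",
                 code[is.na(m)][1L]))
  unname(m)
}

.mask_to_bases <- function(mask) {
  vapply(mask, function(m)
    paste(.BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L], collapse = ""),
    character(1))
}

#' Classify one site's consensus calls for discriminatory SNPs
#'
#' A strain is discriminated at a site (verdict `DSNP`) when its consensus
#' call is a single unambiguous nucleotide, every other strain's call is
#' not `N`, and that nucleotide is absent from the IUPAC expansion of every
#' other strain's call — so every read carrying it is attributable to that
#' strain. Sites where a strain is only partially different (overlap
#' through heterozygosity) give `HETEROZYGOUS_OVERLAP`; an `N` anywhere
#' gives `LOW_CONFIDENCE_N`; identical calls give `NO_DIFFERENCE` when they
#' match the reference and `ALL_AGREE_VS_REF` when they jointly disagree
#' with it. One site may discriminate several strains independently.
#'
#' @param calls named character vector (or list of IUPAC codes) with one
#'   consensus call per strain; at least two strains.
#' @param refBase the reference base at the site.
#' @return `data.frame` with one row per strain: `strain`, `verdict`,
#'   `base` (the discriminating nucleotide for `DSNP` rows, else `NA`).
#' @export
classifySite <- function(calls, refBase) {
  calls <- unlist(calls)
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop("'calls' must be named by strain")
  if (length(calls) < 2L)
    stop("site classification needs at least two strains")
  if (anyNA(calls)) stop("missing strain call")
  strains <- names(calls)
  k <- length(calls)
  verdict <- rep(NA_character_, k)
  base <- rep(NA_character_, k)
  if (all(calls == calls[1L]) && calls[1L] %in% .BASES) {
    verdict[] <- if (calls[1L] == toupper(refBase)) "NO_DIFFERENCE"
                 else "ALL_AGREE_VS_REF"
  } else {
    masks <- .iupac_mask(calls)
    is_n <- calls == "N"
    single <- calls %in% .BASES
    for (i in seq_len(k)) {
      others <- masks[-i]
      if (is_n[i] || any(is_n[-i])) {
        verdict[i] <- "LOW_CONFIDENCE_N"
      } else if (single[i] &&
                 !any(bitwAnd(masks[i], others) > 0L)) {
        verdict[i] <- "DSNP"
        base[i] <- calls[i]
      } else {
        verdict[i] <- "HETEROZYGOUS_OVERLAP"
      }
    }
  }
  data.frame(strain = strains, verdict = verdict, base = base,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Find discriminatory SNPs across per-strain consensus tracks
#'
#' Compares aligned consensus tracks position by position and emits one
#' record per (site, discriminated strain) satisfying the [classifySite()]
#' rule. Positions absent from a strain's track are treated as `N`
#' (insufficient data) and therefore never yield dSNPs.
#'
#' @param tracks named list of [ConsensusTrack-class] objects (or their
#'   call `data.frame`s), one per strain; all tracks must cover the same
#'   transcript set.
#' @return `data.frame` with columns `transcript`, `pos`, `ref`, `strain`,
#'   `base` and `others` (comma-separated `strain=expansion` of the other
#'   strains' calls), ordered by transcript appearance then position.
#' @export
findDsnps <- function(tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop("'tracks' must be a named list (one consensus track per strain)")
  strains <- names(tracks)
  if (length(strains) < 2L) stop("need at least two strain tracks")
  calls <- lapply(tracks, function(t)
    if (is(t, "ConsensusTrack")) consensusCalls(t) else t)
  tx_sets <- lapply(calls, function(cc) unique(cc$transcript))
  universe <- tx_sets[[1L]]
  for (i in seq_along(tx_sets)[-1L]) {
    extra <- c(setdiff(tx_sets[[i]], universe), setdiff(universe, tx_sets[[i]]))
    if (length(extra))
      stop(sprintf("consensus tracks cover different transcript sets (%s: %s)",
                   strains[i], paste(head(extra, 5L), collapse = ", ")))
  }

  dts <- lapply(seq_along(calls), function(i) {
    dt <- data.table::as.data.table(
      calls[[i]][, c("transcript", "pos", "ref", "iupac")])
    data.table::setnames(dt, "iupac", paste0("call_", i))
    dt
  })
  merged <- Reduce(function(a, b)
    merge(a, b, by = c("transcript", "pos", "ref"), all = TRUE), dts)
  call_cols <- paste0("call_", seq_along(strains))
  for (col in call_cols)
    data.table::set(merged, which(is.na(merged[[col]])), col, "N")

  call_mat <- as.matrix(merged[, call_cols, with = FALSE])
  # candidate sites: at least two distinct calls among the strains
  varying <- rowSums(call_mat != call_mat[, 1L]) > 0L
  if (!any(varying)) {
    return(data.frame(transcript = character(), pos = integer(),
                      ref = character(), strain = character(),
                      base = character(), others = character(),
                      stringsAsFactors = FALSE))
  }
  sub <- merged[varying]
  cm <- call_mat[varying, , drop = FALSE]
  masks <- matrix(.iupac_mask(cm), nrow = nrow(cm))
  is_n <- cm == "N"
  any_n <- rowSums(is_n) > 0L
  out <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    single <- cm[, i] %in% .BASES
    overlap <- rep(FALSE, nrow(cm))
    for (j in seq_along(strains)[-i])
      overlap <- overlap | bitwAnd(masks[, i], masks[, j]) > 0L
    hit <- single & !any_n & !overlap
    if (!any(hit)) next
    others <- vapply(which(hit), function(r)
      paste(sprintf("%s=%s", strains[-i],
                    .mask_to_bases(masks[r, -i])), collapse = ","),
      character(1))
    out[[i]] <- data.frame(transcript = sub$transcript[hit],
                           pos = sub$pos[hit], ref = sub$ref[hit],
                           strain = strains[i], base = cm[hit, i],
                           others = others, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    return(data.frame(transcript = character(), pos = integer(),
                      ref = character(), strain = character(),
                      base = character(), others = character(),
                      stringsAsFactors = FALSE))
  res <- res[order(match(res$transcript, universe), res$pos,
                   match(res$strain, strains)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Restrict dSNPs to transcripts informative for every strain
#'
#' An allele-specific expression value can only be computed for every
#' allele of a transcript when each strain contributes at least one dSNP;
#' transcripts missing any strain are dropped together with their dSNPs.
#'
#' @param dsnps dSNP table from [findDsnps()].
#' @param strains character vector of all strain identifiers.
#' @return list with `transcripts` (kept identifiers, in input order) and
#'   `dsnps` (the table restricted to kept transcripts).
#' @export
selectCompleteTranscripts <- function(dsnps, strains) {
  if (!nrow(dsnps))
    return(list(transcripts = character(), dsnps = dsnps))
  per_tx <- split(dsnps$strain, dsnps$transcript)
  complete <- names(per_tx)[vapply(per_tx, function(s)
    all(strains %in% s), logical(1))]
  keep <- unique(dsnps$transcript)
  keep <- keep[keep %in% complete]
  list(transcripts = keep,
       dsnps = dsnps[dsnps$transcript %in% keep, , drop = FALSE])
}
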