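#' Read a transcriptome reference from FASTA
#'
#' Reads transcript sequences into a [Biostrings::DNAStringSet], validating
#' the layout first so that malformed input is reported with a line number.
#' Sequences are uppercased; record order is preserved; identifiers are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a plain-text FASTA file.
#' @return a named `DNAStringSet` (possibly empty).
#' @export
readTranscripts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(Biostrings::DNAStringSet())
  is_header <- startsWith(lines, ">")
  first <- nonblank[1L]
  if (!is_header[first])
    stop(sprintf("FASTA format error at line %d: expected '>' header", first))
  headers <- which(is_header)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[headers]))
  if (any(!nzchar(ids))) {
    bad <- headers[!nzchar(ids)][1L]
    stop(sprintf("FASTA format error at line %d: empty record identifier", bad))
  }
  if (anyDuplicated(ids))
    stop(sprintf("duplicate transcript identifier '%s'",
                 ids[duplicated(ids)][1L]))
  # an empty record is a header followed by a header (or end of file)
  ends <- c(headers[-1L] - 1L, length(lines))
  seq_len_per <- vapply(seq_along(headers), function(i) {
    if (ends[i] < headers[i] + 1L) 0L
    else sum(nchar(trimws(lines[(headers[i] + 1L):ends[i]])))
  }, integer(1L))
  if (any(seq_len_per == 0L)) {
    bad <- headers[seq_len_per == 0L][1L]
    stop(sprintf("FASTA format error at line %d: record '%s' has no sequence",
                 bad, ids[which(headers == bad)]))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write transcript sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
writeTranscripts <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

.new_pileup <- function(columns) {
  rownames(columns) <- NULL
  new("Pileup", columns = columns)
}

.empty_pileup_columns <- function() {
  data.frame(transcript = character(), pos = integer(), ref = character(),
             depth = integer(), bases = character(), quals = character(),
             stringsAsFactors = FALSE)
}

#' Read a samtools mpileup text file
#'
#' Reads the 6-column single-sample mpileup dialect (transcript, 1-based
#' position, reference base, depth, read bases, base qualities). The read
#' base strings are kept verbatim; resolution of the pileup grammar happens
#' in [tallyBases()] or [parseMpileupLine()]. A trailing mapping-quality
#' column, if present, is ignored.
#'
#' @param path path to a plain-text mpileup file.
#' @return a [Pileup-class] object.
#' @export
readMpileup <- function(path) {
  if (file.exists(path) && file.size(path) == 0)
    return(.new_pileup(.empty_pileup_columns()))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          colClasses = list(character = c(1, 3, 5, 6)),
                          fill = TRUE, showProgress = FALSE)
  if (!nrow(dt)) return(.new_pileup(.empty_pileup_columns()))
  if (ncol(dt) < 6L)
    stop("mpileup format error: fewer than 6 tab-separated columns")
  columns <- data.frame(
    transcript = as.character(dt[[1]]),
    pos   = as.integer(dt[[2]]),
    ref   = toupper(as.character(dt[[3]])),
    depth = as.integer(dt[[4]]),
    bases = as.character(dt[[5]]),
    quals = as.character(dt[[6]]),
    stringsAsFactors = FALSE)
  zero <- columns$depth == 0L
  columns$bases[zero] <- ""
  columns$quals[zero] <- ""
  .new_pileup(columns)
}

#' Write a [Pileup-class] object as mpileup text
#'
#' @param pileup a `Pileup`.
#' @param path output path.
#' @export
writeMpileup <- function(pileup, path) {
  stopifnot(is(pileup, "Pileup"))
  cc <- pileupColumns(pileup)
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s", cc$transcript, cc$pos, cc$ref,
                   cc$depth, cc$bases, cc$quals)
  writeLines(lines, path)
  invisible(path)
}

#' Parse one mpileup line into a [PileupColumn-class]
#'
#' Fully resolves the read-base grammar: `.`/`,` become the reference base
#' on the plus/minus strand, letter case encodes strand for mismatches,
#' `^X` read-start markers (with their mapping-quality character), `$`
#' read-ends and `+n`/`-n` indel strings are consumed without producing
#' observations, and `*` deletion placeholders are retained as depth-bearing
#' observations without a base call.
#'
#' @param line one tab-separated mpileup line.
#' @return a [PileupColumn-class].
#' @export
parseMpileupLine <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 6L)
    stop("mpileup format error: fewer than 6 tab-separated columns")
  depth <- suppressWarnings(as.integer(fields[4]))
  if (is.na(depth)) stop("mpileup format error: non-integer depth field")
  ref <- toupper(trimws(fields[3]))
  bases <- if (depth == 0L && fields[5] == "*") "" else fields[5]
  quals <- if (depth == 0L && fields[6] == "*") "" else fields[6]
  obs <- .pileupExpand(bases, quals, ref)
  obs <- data.frame(base = obs$base, strand = obs$strand,
                    quality = obs$quality, stringsAsFactors = FALSE)
  if (nrow(obs) != depth)
    stop(sprintf(
      "mpileup format error: depth field %d but %d observations parsed",
      depth, nrow(obs)))
  new("PileupColumn", transcript = fields[1],
      position = as.integer(fields[2]), ref = ref, depth = depth,
      observations = obs)
}

#' Write a homogeneous set of records as a TSV report table
#'
#' Writes a tab-separated table with a header row and a deterministic
#' column order given by `columns`. Numeric fields are rendered with fixed
#' significant precision so written tables round-trip through
#' [readReportTable()] to rendered precision.
#'
#' @param records a `data.frame` of records.
#' @param path output path.
#' @param columns character vector naming (and ordering) the columns to
#'   write; defaults to all columns of `records`.
#' @param digits significant digits for numeric fields.
#' @export
writeReportTable <- function(records, path, columns = names(records),
                             digits = 8L) {
  missing_cols <- setdiff(columns, names(records))
  if (length(missing_cols))
    stop(sprintf("record schema error: missing field(s) %s",
                 paste(missing_cols, collapse = ", ")))
  out <- records[, columns, drop = FALSE]
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- trimws(formatC(out[[j]], digits = digits, format = "g"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV report table written by [writeReportTable()]
#'
#' @param path path to the table.
#' @return a `data.frame`.
#' @export
readReportTable <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}
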