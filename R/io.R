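## Readers/writers for the plain-text formats every stage touches.
## FASTA via Biostrings, GFF3 via rtracklayer on GRanges; tables are TSV.

#' Read a nucleotide FASTA file with alphabet normalization
#'
#' Residues are uppercased, U is mapped to T, and any character outside
#' \{A, C, G, T, N\} is mapped to N with a single warning summarizing the
#' replacements. Sequence ids are the first whitespace-delimited token of each
#' header; the remainder is kept as a \code{description} metadata column.
#'
#' @param path path to a FASTA file.
#' @return a \link[Biostrings]{DNAStringSet}; \code{mcols(x)$description}
#'   holds the header remainders.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 a contig", "acgtr", ">s2", "GGTT"), tf)
#' suppressWarnings(readFasta(tf))
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .ervStop(sprintf("file not found: %s", path), "ioError")
  raw <- tryCatch(readBStringSet(path),
                  error = function(e) .ervStop(
                    sprintf("not readable as FASTA: %s (%s)", path,
                            conditionMessage(e)), "ioError"))
  if (length(raw) == 0L)
    .ervStop(sprintf("empty FASTA file: %s", path), "emptyFileError")
  hdr <- names(raw)
  ids <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), NA_character_)
  if (any(!nzchar(ids)))
    .ervStop("record with empty id", "ioError")
  if (anyDuplicated(ids))
    .ervStop(sprintf("duplicate sequence ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "duplicateIdError")
  if (any(width(raw) == 0L))
    .ervStop(sprintf("zero-length record(s): %s",
                     paste(ids[width(raw) == 0L], collapse = ", ")),
             "zeroLengthError")
  chr <- toupper(as.character(raw))
  chr <- gsub("U", "T", chr, fixed = TRUE)
  nBad <- sum(nchar(chr)) - sum(nchar(gsub("[^ACGTN]", "", chr)))
  if (nBad > 0L) {
    chr <- gsub("[^ACGTN]", "N", chr)
    warning(sprintf("%d residue(s) outside {A,C,G,T,N} replaced by N", nBad))
  }
  out <- DNAStringSet(chr)
  names(out) <- ids
  mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param records a \link[Biostrings]{DNAStringSet} or
#'   \link[Biostrings]{AAStringSet} (non-empty, named).
#' @param path output path.
#' @param width line-wrap width in residues.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
  if (length(records) == 0L)
    .ervStop("refusing to write an empty FASTA", "emptyCollectionError")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    .ervStop("all records must be named", "ioError")
  ok <- tryCatch({
    writeXStringSet(records, filepath = path, width = as.integer(width))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .ervStop(sprintf("cannot write to %s", path), "ioError")
  invisible(path)
}

#' Export provirus calls as GFF3
#'
#' Emits one parent feature per provirus (type \code{mobile_element}) with
#' child features for the two LTRs (\code{long_terminal_repeat}) and every
#' internal ORF (\code{open_reading_frame}). Coordinates are the package's
#' 1-based closed intervals, which is also the GFF3 convention, so no shift
#' is applied.
#'
#' @param calls list of \linkS4class{ProvirusCall} (may be empty).
#' @param contigLengths named integer vector of contig lengths, used for
#'   bounds checking (e.g. \code{setNames(width(x), names(x))}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGFF3 <- function(calls, contigLengths, path) {
  stopifnot(is.list(calls))
  if (length(calls) == 0L) {
    rtracklayer::export.gff3(GRanges(), path)
    return(invisible(path))
  }
  grl <- lapply(seq_along(calls), function(i) {
    call <- calls[[i]]
    stopifnot(is(call, "ProvirusCall"))
    p <- call@ltrPair
    len <- contigLengths[[p@contig]]
    if (is.null(len) || is.na(len))
      .ervStop(sprintf("unknown contig length for %s", p@contig), "ioError")
    span <- IRanges(start(p@left), end(p@right))
    feats <- c(span, p@left, p@right, call@orfs)
    if (max(end(feats)) > len || min(start(feats)) < 1L)
      .ervStop(sprintf("interval out of bounds on %s (length %d)", p@contig, len),
               "boundsError")
    pid <- sprintf("provirus%02d", i)
    nOrf <- length(call@orfs)
    gr <- GRanges(p@contig, feats, strand = p@strand)
    mcols(gr)$type <- c("mobile_element", "long_terminal_repeat",
                        "long_terminal_repeat",
                        rep("open_reading_frame", nOrf))
    mcols(gr)$ID <- c(pid, paste0(pid, ".ltr5"), paste0(pid, ".ltr3"),
                      if (nOrf) paste0(pid, ".orf", seq_len(nOrf)))
    mcols(gr)$Parent <- c(NA_character_, rep(pid, 2L + nOrf))
    mcols(gr)$ltr_identity <- c(round(p@identity, 4), rep(NA_real_, 2L + nOrf))
    mcols(gr)$k2p_divergence <- c(round(call@divergence@value, 5),
                                  rep(NA_real_, 2L + nOrf))
    gr
  })
  gr <- suppressWarnings(do.call(c, grl))  # contigs carry disjoint seqlevels
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Read a homology-hit table
#'
#' Expects a TSV with header columns \code{query_id}, \code{subject_id},
#' \code{identity}, \code{coverage}, \code{e_value}, \code{species}
#' (percent identities/coverages in [0, 100], e-values non-negative).
#' Malformed rows are reported with their line numbers.
#'
#' @param path path to the TSV.
#' @return a data.frame of validated hit records.
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) .ervStop(sprintf("file not found: %s", path), "ioError")
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("query_id", "subject_id", "identity", "coverage", "e_value", "species")
  if (!all(need %in% names(x)))
    .ervStop(sprintf("hit table must have columns: %s", paste(need, collapse = ", ")),
             "ioError")
  x <- x[, need]
  bad <- which(!is.finite(x$identity) | x$identity < 0 | x$identity > 100 |
               !is.finite(x$coverage) | x$coverage < 0 | x$coverage > 100 |
               !is.finite(x$e_value) | x$e_value < 0)
  if (length(bad))
    .ervStop(sprintf("malformed hit row(s) at line(s): %s",
                     paste(bad + 1L, collapse = ", ")), "malformedRowError")
  x
}

#' @rdname readHitTable
#' @param hits a hit-record data.frame.
#' @export
writeHitTable <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as square TSV or PHYLIP
#'
#' @param dm a \linkS4class{DistanceMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDistanceTSV <- function(dm, path) {
  stopifnot(is(dm, "DistanceMatrix"))
  m <- distValue(dm)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceTSV
#' @export
writePhylip <- function(dm, path) {
  stopifnot(is(dm, "DistanceMatrix"))
  m <- distValue(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  invisible(path)
}
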