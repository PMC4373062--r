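## Coding-decay scoring: nonsense and frameshift counts of a proviral gene
## region relative to an intact reference protein, via the frameshift-aware
## codon alignment in src/defect_align.cpp.

#' Count nonsense and frameshift mutations against an intact reference
#'
#' Aligns the nucleotide query to the reference protein in codon space with
#' frameshift-aware moves (codons consuming 1, 2, 4 or 5 nt carry a single
#' frameshift penalty and emit a frameshift event; only such moves can
#' change the reading frame, so every net frame disruption is counted).
#' Each aligned codon translating to a stop is a nonsense event. Query end
#' gaps are free, so the scored gene may sit inside a larger region (e.g.
#' the whole internal cassette). Consecutive frameshift events with no
#' intact codon between them (a compensated double shift) are merged into
#' one flagged event; events separated by at least one intact codon stay
#' separate. Stops downstream of a frameshift are counted in the frame the
#' alignment assigns, keeping the two counts independent.
#'
#' @param query nucleotide sequence (DNAString or character), non-empty.
#' @param referenceProtein intact reference protein (AAString or character),
#'   at least 30 residues, no stop character.
#' @param referenceId identifier recorded in the report.
#' @param fsPenalty,gapPenalty,match,mismatch alignment scores; the
#'   frameshift penalty exceeds the codon-gap penalty so in-frame indels are
#'   never miscounted as frameshifts.
#' @return an \linkS4class{ORFIntactnessReport}.
#' @examples
#' ref <- "MKLVINTREQWAGHDSAPLMKLVINTREQWAGHDS"
#' # an exact back-translation has no defects
#' bt <- paste(c("ATG","AAA","CTG","GTG","ATT","AAT","ACC","CGT","GAA","CAG",
#'               "TGG","GCG","GGC","CAT","GAT","AGC","GCG","CCG","CTG","ATG",
#'               "AAA","CTG","GTG","ATT","AAT","ACC","CGT","GAA","CAG","TGG",
#'               "GCG","GGC","CAT","GAT","AGC"), collapse = "")
#' intactness(countDefects(bt, ref))
#' @export
countDefects <- function(query, referenceProtein, referenceId = "reference",
                         fsPenalty = -12, gapPenalty = -9, match = 3,
                         mismatch = -1) {
  q <- .asSingleString(query)
  ref <- .asSingleString(referenceProtein)
  if (!nzchar(q)) .ervStop("empty query", "emptySequenceError")
  if (nchar(ref) < 30L)
    .ervStop("reference protein must be at least 30 aa", "paramError")
  if (grepl("*", ref, fixed = TRUE))
    .ervStop("reference protein must not contain stop characters", "paramError")
  if (nchar(q) < 3L)
    .ervStop("query too short to translate in any frame", "untranslatableError")
  res <- .defectAlignCpp(q, ref, matchScore = match, mismatchScore = mismatch,
                         fsPen = fsPenalty, gapPen = gapPenalty)
  ev <- data.frame(kind = as.character(res$kind),
                   position = as.integer(res$position),
                   refPos = as.integer(res$refPos),
                   detail = as.character(res$detail),
                   stringsAsFactors = FALSE)
  ev$merged <- logical(nrow(ev))
  if (nrow(ev)) {
    # merge compensated shifts: an fs event with zero intact codons since the
    # previous fs event collapses into it
    gap <- as.integer(res$mSincePrevFs)
    drop <- which(ev$kind == "frameshift" & !is.na(gap) & gap == 0L)
    drop <- drop[drop > 1L]
    if (length(drop)) {
      for (d in drop) {
        prevFs <- max(which(ev$kind == "frameshift" & seq_len(nrow(ev)) < d))
        ev$merged[prevFs] <- TRUE
        ev$detail[prevFs] <- paste(ev$detail[prevFs], ev$detail[d], sep = "+")
      }
      ev <- ev[-drop, , drop = FALSE]
    }
    ev <- ev[order(ev$position), , drop = FALSE]
    ev <- ev[!duplicated(ev$position), , drop = FALSE]
    rownames(ev) <- NULL
  }
  new("ORFIntactnessReport",
      nNonsense = sum(ev$kind == "nonsense"),
      nFrameshift = sum(ev$kind == "frameshift"),
      events = ev, reference = referenceId)
}

#' Per-lineage medians and ranges of defect counts
#'
#' Summarizes intactness reports the way decay is conventionally tabulated:
#' the integer median (lower median for even n) and [min-max] range of the
#' combined nonsense + frameshift count per lineage.
#'
#' @param reports list of \linkS4class{ORFIntactnessReport}.
#' @param lineages character/factor of lineage labels, one per report.
#' @return data.frame with columns lineage, n, median, min, max.
#' @export
summarizeDefects <- function(reports, lineages) {
  stopifnot(length(reports) == length(lineages), length(reports) > 0L)
  counts <- vapply(reports, function(r) {
    stopifnot(is(r, "ORFIntactnessReport"))
    r@nNonsense + r@nFrameshift
  }, integer(1))
  lowerMedian <- function(x) sort(x)[ceiling(length(x) / 2)]
  out <- do.call(rbind, lapply(split(counts, lineages), function(x)
    data.frame(n = length(x), median = lowerMedian(x),
               min = min(x), max = max(x))))
  data.frame(lineage = rownames(out), out, row.names = NULL)
}
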