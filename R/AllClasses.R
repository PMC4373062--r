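## Central S4 value classes. Coordinates are 1-based closed IRanges throughout;
## GFF3 emission is therefore an identity mapping on coordinates.

#' Transition/transversion site tallies from a pairwise alignment
#'
#' Compared-site counts feeding the distance estimators: \code{n} is the
#' number of gap- and N-free columns (pairwise deletion), \code{ts} the
#' transition differences (A<->G, C<->T) and \code{tv} the transversion
#' differences. P = ts/n and Q = tv/n are the inputs of the Kimura
#' two-parameter correction.
#'
#' @slot n integer, comparable sites.
#' @slot ts integer, transition differences.
#' @slot tv integer, transversion differences.
#' @exportClass SiteCounts
setClass("SiteCounts",
  representation(n = "integer", ts = "integer", tv = "integer"))

setValidity("SiteCounts", function(object) {
  if (length(object@n) != 1L || length(object@ts) != 1L || length(object@tv) != 1L)
    return("n, ts, tv must be scalars")
  if (any(c(object@n, object@ts, object@tv) < 0L))
    return("counts must be non-negative")
  if (object@ts + object@tv > object@n)
    return("ts + tv must not exceed n")
  TRUE
})

#' Model-corrected pairwise divergence with its standard error
#'
#' @slot model character, one of \code{"p"}, \code{"K2P"}, \code{"amino_p"}.
#' @slot value numeric, substitutions per site (the D of T = D/(2R)).
#' @slot se numeric, standard error of \code{value}.
#' @slot nSites integer, compared sites.
#' @slot nDiff integer, observed differences.
#' @exportClass DistanceEstimate
setClass("DistanceEstimate",
  representation(model = "character", value = "numeric", se = "numeric",
                 nSites = "integer", nDiff = "integer"))

setValidity("DistanceEstimate", function(object) {
  if (!object@model %in% c("p", "K2P", "amino_p"))
    return("model must be 'p', 'K2P' or 'amino_p'")
  if (object@value < 0) return("value must be non-negative")
  if (object@se < 0) return("se must be non-negative")
  if (object@model %in% c("p", "amino_p") && object@nSites > 0L &&
      abs(object@value - object@nDiff / object@nSites) > 1e-12)
    return("for p-type models value must equal nDiff/nSites")
  TRUE
})

#' Symmetric matrix of pairwise distance estimates
#'
#' @slot labels character, sequence identifiers (row/column order).
#' @slot values numeric matrix, model-corrected distances.
#' @slot se numeric matrix, standard errors (NA where not computed).
#' @slot model character, estimator used for every pair.
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(labels = "character", values = "matrix", se = "matrix",
                 model = "character"))

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (nrow(v) != length(object@labels)) return("labels must match matrix dimension")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  if (any(abs(v - t(v)) > 1e-9, na.rm = TRUE)) return("matrix must be symmetric")
  if (any(v < 0, na.rm = TRUE)) return("distances must be non-negative")
  TRUE
})

#' Pairwise global alignment of two sequences
#'
#' Thin value object around an optimal affine-gap Needleman-Wunsch alignment:
#' the two gapped strings, the optimal score, and the scoring scheme
#' (match, mismatch, gapOpen, gapExtend; a gap of length L costs
#' gapOpen + L * gapExtend).
#'
#' @slot gappedA,gappedB character, aligned strings of equal length.
#' @slot score numeric, optimal alignment score.
#' @slot scheme numeric named vector with elements match, mismatch, gapOpen,
#'   gapExtend.
#' @exportClass PairwiseAlignment
setClass("PairwiseAlignment",
  representation(gappedA = "character", gappedB = "character",
                 score = "numeric", scheme = "numeric"))

setValidity("PairwiseAlignment", function(object) {
  if (nchar(object@gappedA) != nchar(object@gappedB))
    return("gapped strings must have equal length")
  a <- strsplit(object@gappedA, "")[[1]]
  b <- strsplit(object@gappedB, "")[[1]]
  if (any(a == "-" & b == "-")) return("gap/gap columns are not allowed")
  TRUE
})

#' Coding-decay report for a proviral gene region
#'
#' Counts of nonsense (premature in-frame stop) and frameshift (indel with
#' length not divisible by 3) events detected by frameshift-aware codon
#' alignment of a nucleotide query against an intact reference protein.
#'
#' @slot nNonsense integer, premature stop codons.
#' @slot nFrameshift integer, frame-disrupting indel events (a maximal run of
#'   frame disruption counts once; merged compensated shifts are flagged).
#' @slot events data.frame with columns kind, position (query, nt, 1-based),
#'   detail, merged.
#' @slot reference character, identifier of the reference protein used.
#' @exportClass ORFIntactnessReport
setClass("ORFIntactnessReport",
  representation(nNonsense = "integer", nFrameshift = "integer",
                 events = "data.frame", reference = "character"))

setValidity("ORFIntactnessReport", function(object) {
  ev <- object@events
  if (sum(ev$kind == "nonsense") != object@nNonsense)
    return("nNonsense must equal the number of nonsense events")
  if (sum(ev$kind == "frameshift") != object@nFrameshift)
    return("nFrameshift must equal the number of frameshift events")
  if (nrow(ev) > 1L && is.unsorted(ev$position, strictly = TRUE))
    return("event positions must be strictly increasing")
  TRUE
})

setClassUnion("ORFIntactnessReportOrNULL", c("ORFIntactnessReport", "NULL"))

#' A candidate LTR pair found by repeat scanning
#'
#' @slot contig character, contig identifier.
#' @slot left,right \link[IRanges]{IRanges} of the 5' and 3' repeat copies
#'   (1-based closed, forward-strand coordinates).
#' @slot strand character, "+" or "-" (coordinates are always reported on +).
#' @slot identity numeric in [0,1], identity of the pair's global alignment.
#' @slot motifs list with elements \code{left} and \code{right}, each the
#'   motif flag list of \code{\link{annotateLTRMotifs}}.
#' @slot flags character, quality flags (e.g. boundary-convention disagreement).
#' @exportClass LTRCandidate
setClass("LTRCandidate",
  representation(contig = "character", left = "IRanges", right = "IRanges",
                 strand = "character", identity = "numeric", motifs = "list",
                 flags = "character"))

setValidity("LTRCandidate", function(object) {
  if (end(object@left) >= start(object@right))
    return("left repeat must end before right repeat starts")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  if (object@identity < 0 || object@identity > 1)
    return("identity must lie in [0, 1]")
  TRUE
})

#' A detected provirus: LTR pair, internal region, decay and age estimates
#'
#' @slot ltrPair \linkS4class{LTRCandidate}.
#' @slot internal IRanges, the internal (gag-pol-env) region.
#' @slot orfs IRanges, internal ORFs (metadata columns frame, role).
#' @slot orfOrderOk logical, gag-pol-env order detected.
#' @slot tsd IRanges of length 0 or 2, target-site duplication evidence.
#' @slot intactness \linkS4class{ORFIntactnessReport} or NULL.
#' @slot divergence \linkS4class{DistanceEstimate}, K2P LTR-LTR divergence.
#' @slot ages data.frame, one row per rate of the panel (label, R, D,
#'   T_years, T_MY, T_se_MY).
#' @exportClass ProvirusCall
setClass("ProvirusCall",
  representation(ltrPair = "LTRCandidate", internal = "IRanges",
                 orfs = "IRanges", orfOrderOk = "logical", tsd = "IRanges",
                 intactness = "ORFIntactnessReportOrNULL",
                 divergence = "DistanceEstimate", ages = "data.frame"))

setValidity("ProvirusCall", function(object) {
  p <- object@ltrPair
  if (start(object@internal) <= end(p@left) ||
      end(object@internal) >= start(p@right))
    return("internal region must lie strictly between the LTRs")
  TRUE
})

#' A simulated provirus with full ground truth
#'
#' @slot contig \link[Biostrings]{DNAStringSet} of length 1, the host contig
#'   carrying the provirus.
#' @slot ltr5,ltr3,internal IRanges, true coordinates on the contig.
#' @slot tsd IRanges of length 2, the target-site duplication copies.
#' @slot trueAge numeric, years since integration.
#' @slot rate numeric, substitutions/site/year used on each LTR branch.
#' @slot expectedDivergence numeric, 2 * rate * trueAge.
#' @slot defects data.frame of injected pol defects (kind, position codon/nt).
#' @slot polReference \link[Biostrings]{AAString}, the intact pol protein.
#' @slot params list, the resolved \code{\link{simulationParams}}.
#' @exportClass SimulatedProvirus
setClass("SimulatedProvirus",
  representation(contig = "DNAStringSet", ltr5 = "IRanges", ltr3 = "IRanges",
                 internal = "IRanges", tsd = "IRanges", trueAge = "numeric",
                 rate = "numeric", expectedDivergence = "numeric",
                 defects = "data.frame", polReference = "AAString",
                 params = "list"))

setValidity("SimulatedProvirus", function(object) {
  if (length(object@contig) != 1L) return("contig must hold exactly one sequence")
  if (width(object@ltr5) != width(object@ltr3))
    return("the two LTRs must have equal ancestral length")
  if (abs(object@expectedDivergence - 2 * object@rate * object@trueAge) > 1e-12)
    return("expectedDivergence must equal 2 * rate * trueAge")
  if (!(end(object@ltr5) < start(object@internal) &&
        end(object@internal) < start(object@ltr3)))
    return("intervals must be ordered ltr5 < internal < ltr3 without overlap")
  TRUE
})

#' Block-trimmed multiple alignment
#'
#' @slot source character matrix, the input alignment (rows = sequences).
#' @slot keptColumns IRanges, kept column intervals (1-based closed).
#' @slot params list, trimming parameters used.
#' @exportClass TrimmedAlignment
setClass("TrimmedAlignment",
  representation(source = "matrix", keptColumns = "IRanges", params = "list"))

setValidity("TrimmedAlignment", function(object) {
  kc <- object@keptColumns
  if (length(kc)) {
    if (min(start(kc)) < 1L || max(end(kc)) > ncol(object@source))
      return("kept intervals must lie within the alignment")
    if (is.unsorted(start(kc), strictly = TRUE))
      return("kept intervals must be sorted")
    if (length(kc) > 1L && any(start(kc)[-1] <= end(kc)[-length(kc)]))
      return("kept intervals must be disjoint")
    if (any(width(kc) < object@params$minBlock))
      return("every kept block must reach the minimum block length")
  }
  TRUE
})

#' Partition of sequences into lineages
#'
#' @slot membership named integer, lineage label per sequence id.
#' @slot threshold numeric, distance threshold used.
#' @slot minInter numeric, smallest between-lineage distance.
#' @slot maxIntra numeric, largest within-lineage distance.
#' @exportClass LineagePartition
setClass("LineagePartition",
  representation(membership = "integer", threshold = "numeric",
                 minInter = "numeric", maxIntra = "numeric"))

setValidity("LineagePartition", function(object) {
  if (is.null(names(object@membership))) return("membership must be named")
  if (anyDuplicated(names(object@membership)))
    return("each id must appear exactly once")
  if (length(unique(object@membership)) > 1L &&
      is.finite(object@minInter) && object@minInter <= object@threshold)
    return("min inter-lineage distance must exceed the threshold")
  TRUE
})

## ---- show methods -----------------------------------------------------------

setMethod("show", "SiteCounts", function(object) {
  cat(sprintf("SiteCounts: n=%d compared sites, ts=%d, tv=%d (P=%.4g, Q=%.4g)\n",
              object@n, object@ts, object@tv,
              if (object@n) object@ts / object@n else NA_real_,
              if (object@n) object@tv / object@n else NA_real_))
})

setMethod("show", "DistanceEstimate", function(object) {
  cat(sprintf("DistanceEstimate [%s]: %.5f (SE %.5f), %d/%d differing/compared sites\n",
              object@model, object@value, object@se, object@nDiff, object@nSites))
})

setMethod("show", "DistanceMatrix", function(object) {
  cat(sprintf("DistanceMatrix [%s]: %d sequences\n", object@model,
              length(object@labels)))
  print(round(object@values, 4))
})

setMethod("show", "PairwiseAlignment", function(object) {
  cat(sprintf("PairwiseAlignment: score %.1f over %d columns\n",
              object@score, nchar(object@gappedA)))
})

setMethod("show", "ORFIntactnessReport", function(object) {
  cat(sprintf("ORFIntactnessReport vs '%s': %d nonsense, %d frameshift\n",
              object@reference, object@nNonsense, object@nFrameshift))
})

setMethod("show", "LTRCandidate", function(object) {
  cat(sprintf("LTRCandidate on %s(%s): left %d-%d, right %d-%d, identity %.3f\n",
              object@contig, object@strand,
              start(object@left), end(object@left),
              start(object@right), end(object@right), object@identity))
})

setMethod("show", "ProvirusCall", function(object) {
  p <- object@ltrPair
  cat(sprintf("ProvirusCall on %s: %d-%d (LTRs %d bp/%d bp, identity %.3f)\n",
              p@contig, start(p@left), end(p@right),
              width(p@left), width(p@right), p@identity))
  cat(sprintf("  K2P divergence D = %.4f (SE %.4f); gag-pol-env order: %s\n",
              object@divergence@value, object@divergence@se,
              ifelse(object@orfOrderOk, "yes", "no")))
  if (nrow(object@ages))
    cat(sprintf("  ages: %s\n", paste(sprintf("%.3g MY @ %.2g", object@ages$T_MY,
                                              object@ages$R), collapse = ", ")))
})

setMethod("show", "SimulatedProvirus", function(object) {
  cat(sprintf("SimulatedProvirus '%s': %d bp contig; provirus %d-%d\n",
              names(object@contig), width(object@contig)[1],
              start(object@ltr5), end(object@ltr3)))
  cat(sprintf("  true age %.3g yr at rate %.3g => expected divergence %.4f\n",
              object@trueAge, object@rate, object@expectedDivergence))
  cat(sprintf("  injected defects: %d nonsense, %d frameshift\n",
              sum(object@defects$kind == "nonsense"),
              sum(object@defects$kind == "frameshift")))
})

setMethod("show", "TrimmedAlignment", function(object) {
  cat(sprintf("TrimmedAlignment: %d of %d columns kept in %d block(s)\n",
              sum(width(object@keptColumns)), ncol(object@source),
              length(object@keptColumns)))
})

setMethod("show", "LineagePartition", function(object) {
  k <- length(unique(object@membership))
  cat(sprintf("LineagePartition: %d sequences in %d lineage(s) at threshold %.3g\n",
              length(object@membership), k, object@threshold))
})
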