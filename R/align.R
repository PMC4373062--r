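## Pairwise alignment and the distance estimators feeding dating and
## clustering. The alignment engine is Biostrings' affine Needleman-Wunsch;
## the estimators (p-distance, Kimura two-parameter with delta-method SE)
## are implemented here.

#' Default affine alignment scheme
#'
#' Match +1, mismatch -1, gap open -5, gap extend -1; a gap of length L costs
#' gapOpen + L * gapExtend. The scheme is deliberately mild so that diverged
#' LTR copies still align end to end.
#'
#' @param match,mismatch,gapOpen,gapExtend scalar scores (gap scores
#'   non-positive).
#' @return named numeric vector.
#' @export
alignScheme <- function(match = 1, mismatch = -1, gapOpen = -5, gapExtend = -1) {
  if (gapOpen > 0 || gapExtend > 0)
    .ervStop("gap scores must be non-positive", "schemeError")
  c(match = match, mismatch = mismatch, gapOpen = gapOpen, gapExtend = gapExtend)
}

.asSingleString <- function(x) {
  if (is(x, "XString")) return(as.character(x))
  if (is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x)[[1]])
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' Optimal global alignment of two sequences
#'
#' Affine-gap Needleman-Wunsch via \link[Biostrings]{pairwiseAlignment},
#' wrapped into a plain value object. Works for nucleotide or amino-acid
#' input; by default the substitution matrix is the flat match/mismatch
#' matrix of \code{scheme}, and any matrix accepted by Biostrings (e.g.
#' BLOSUM62) can be supplied instead.
#'
#' @param a,b sequences (XString, length-1 XStringSet, or character).
#' @param scheme an \code{\link{alignScheme}}.
#' @param substitutionMatrix optional substitution matrix overriding the
#'   match/mismatch part of \code{scheme}.
#' @return a \linkS4class{PairwiseAlignment}.
#' @examples
#' globalAlign("ACGT", "ACGT")
#' @export
globalAlign <- function(a, b, scheme = alignScheme(), substitutionMatrix = NULL) {
  sa <- .asSingleString(a)
  sb <- .asSingleString(b)
  if (!nzchar(sa) || !nzchar(sb))
    .ervStop("cannot align empty sequences", "emptySequenceError")
  isNuc <- !grepl("[^ACGTNU-]", paste0(sa, sb))
  if (is.null(substitutionMatrix)) {
    alpha <- if (isNuc) c("A", "C", "G", "T", "N") else
      strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]]
    substitutionMatrix <- matrix(scheme[["mismatch"]], length(alpha), length(alpha),
                                 dimnames = list(alpha, alpha))
    diag(substitutionMatrix) <- scheme[["match"]]
  }
  pa <- if (isNuc) DNAString(sa) else AAString(sa)
  su <- if (isNuc) DNAString(sb) else AAString(sb)
  aln <- pairwiseAlignment(pattern = pa, subject = su, type = "global",
                           substitutionMatrix = substitutionMatrix,
                           gapOpening = -scheme[["gapOpen"]],
                           gapExtension = -scheme[["gapExtend"]])
  new("PairwiseAlignment",
      gappedA = as.character(alignedPattern(aln)),
      gappedB = as.character(alignedSubject(aln)),
      score = score(aln), scheme = scheme)
}

#' Fraction of identical columns in a pairwise alignment
#'
#' @param aln a \linkS4class{PairwiseAlignment}.
#' @return identical columns / total columns, in [0, 1].
#' @export
alignmentIdentity <- function(aln) {
  stopifnot(is(aln, "PairwiseAlignment"))
  a <- strsplit(aln@gappedA, "")[[1]]
  b <- strsplit(aln@gappedB, "")[[1]]
  mean(a == b & a != "-")
}

#' Tally transitions and transversions across alignment columns
#'
#' Columns containing a gap or N in either sequence are excluded from the
#' compared-site count (pairwise deletion). Transitions are A<->G and C<->T;
#' every other difference between unambiguous bases is a transversion.
#'
#' @param aln a \linkS4class{PairwiseAlignment} of nucleotide sequences.
#' @return a \linkS4class{SiteCounts}.
#' @export
countSitePatterns <- function(aln) {
  stopifnot(is(aln, "PairwiseAlignment"))
  a <- strsplit(aln@gappedA, "")[[1]]
  b <- strsplit(aln@gappedB, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  diffs <- a != b
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- diffs & (pur[a] == pur[b])   # both purines or both pyrimidines
  new("SiteCounts", n = length(a), ts = sum(ts), tv = sum(diffs & !ts))
}

.countsFromAA <- function(aln) {
  # amino-acid p-distance reuses SiteCounts with every difference held in tv
  a <- strsplit(aln@gappedA, "")[[1]]
  b <- strsplit(aln@gappedB, "")[[1]]
  ok <- !(a %in% c("-", "X", "*")) & !(b %in% c("-", "X", "*"))
  new("SiteCounts", n = sum(ok), ts = 0L, tv = sum(a[ok] != b[ok]))
}

#' Uncorrected p-distance with analytic or bootstrap standard error
#'
#' \code{value = (ts + tv)/n}. The analytic SE is the binomial
#' \code{sqrt(p(1-p)/n)}; the bootstrap SE resamples the n compared sites
#' (multinomially over same/transition/transversion classes) under a seed.
#'
#' @param counts a \linkS4class{SiteCounts} with \code{n > 0}.
#' @param seMethod \code{"analytic"} or \code{"bootstrap"}.
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (NULL = current stream).
#' @param model reported model label, \code{"p"} or \code{"amino_p"}.
#' @return a \linkS4class{DistanceEstimate}.
#' @examples
#' pDistance(new("SiteCounts", n = 100L, ts = 6L, tv = 4L))
#' @export
pDistance <- function(counts, seMethod = c("analytic", "bootstrap"),
                      nBoot = 1000L, seed = NULL, model = "p") {
  stopifnot(is(counts, "SiteCounts"))
  seMethod <- match.arg(seMethod)
  n <- counts@n
  if (n == 0L) .ervStop("no comparable sites (n = 0)", "noSitesError")
  nd <- counts@ts + counts@tv
  p <- nd / n
  se <- if (seMethod == "analytic") {
    sqrt(p * (1 - p) / n)
  } else {
    withSeed(seed, {
      cls <- stats::rmultinom(nBoot, n, prob = c(n - nd, counts@ts, counts@tv) / n)
      sd((cls[2, ] + cls[3, ]) / n)
    })
  }
  new("DistanceEstimate", model = model, value = p, se = se,
      nSites = n, nDiff = as.integer(nd))
}

#' Kimura two-parameter distance with delta-method standard error
#'
#' With P = ts/n and Q = tv/n, the corrected divergence is
#' \deqn{D = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q),}
#' defined when both log arguments are positive; saturation raises an
#' explicit error rather than returning NaN. The SE is the standard
#' delta-method form \eqn{\sqrt{(c_1^2 P + c_3^2 Q - (c_1 P + c_3 Q)^2)/n}}
#' with \eqn{c_1 = 1/(1-2P-Q)}, \eqn{c_2 = 1/(1-2Q)}, \eqn{c_3 = (c_1+c_2)/2}.
#'
#' @param counts a \linkS4class{SiteCounts} with \code{n > 0}.
#' @return a \linkS4class{DistanceEstimate} with model \code{"K2P"}.
#' @examples
#' # P = 0.1, Q = 0.05 over 1000 sites
#' k2pDistance(new("SiteCounts", n = 1000L, ts = 100L, tv = 50L))
#' @export
k2pDistance <- function(counts) {
  stopifnot(is(counts, "SiteCounts"))
  n <- counts@n
  if (n == 0L) .ervStop("no comparable sites (n = 0)", "noSitesError")
  P <- counts@ts / n
  Q <- counts@tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    .ervStop(sprintf("K2P distance undefined: saturation (P=%.3f, Q=%.3f)", P, Q),
             "saturationError")
  D <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c3 <- (c1 + 1 / w2) / 2
  v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n
  new("DistanceEstimate", model = "K2P", value = D, se = sqrt(max(v, 0)),
      nSites = n, nDiff = as.integer(counts@ts + counts@tv))
}

#' All-pairs distance matrix
#'
#' Aligns every pair globally and applies the chosen estimator. For
#' \code{model = "amino_p"} the inputs must be amino-acid sequences and
#' every difference over gap-/X-free columns counts. Pairs for which the
#' estimator is undefined (K2P saturation) are reported with their ids.
#'
#' @param seqs a named \link[Biostrings]{DNAStringSet},
#'   \link[Biostrings]{AAStringSet}, or named character vector, length >= 2.
#' @param model \code{"K2P"}, \code{"p"} or \code{"amino_p"}.
#' @param scheme an \code{\link{alignScheme}}.
#' @param substitutionMatrix optional substitution matrix for the alignments.
#' @return a \linkS4class{DistanceMatrix}.
#' @export
distanceMatrix <- function(seqs, model = c("K2P", "p", "amino_p"),
                           scheme = alignScheme(), substitutionMatrix = NULL) {
  model <- match.arg(model)
  ids <- names(seqs)
  if (is.null(ids) || anyDuplicated(ids))
    .ervStop("sequences must carry unique names", "labelError")
  k <- length(seqs)
  if (k < 2L) .ervStop("need at least 2 sequences", "tooFewSequencesError")
  ss <- vapply(seq_len(k), function(i) .asSingleString(seqs[i]), character(1))
  vals <- matrix(0, k, k)
  ses <- matrix(NA_real_, k, k)
  diag(ses) <- 0
  failed <- character(0)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    est <- tryCatch({
      aln <- globalAlign(ss[i], ss[j], scheme, substitutionMatrix)
      cnt <- if (model == "amino_p") .countsFromAA(aln) else countSitePatterns(aln)
      switch(model,
             K2P = k2pDistance(cnt),
             p = pDistance(cnt),
             amino_p = pDistance(cnt, model = "amino_p"))
    }, ervclockError = function(e) e)
    if (inherits(est, "error")) {
      failed <- c(failed, sprintf("%s/%s (%s)", ids[i], ids[j],
                                  conditionMessage(est)))
    } else {
      vals[i, j] <- vals[j, i] <- est@value
      ses[i, j] <- ses[j, i] <- est@se
    }
  }
  if (length(failed))
    .ervStop(paste("distance undefined for pair(s):",
                   paste(failed, collapse = "; ")), "undefinedPairError")
  new("DistanceMatrix", labels = ids, values = vals, se = ses, model = model)
}
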