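## LTR-pair detection, hallmark-motif annotation, provirus assembly and the
## dating relation T = D/(2R). Detection is seeded k-mer self-matching on the
## contig, anchor clusters are chained per diagonal, extended along the
## diagonal to the repeat boundaries and validated by global alignment
## identity; boundaries are trimmed to terminal TG...CA when both copies
## carry the motif nearby.

#' Configuration for LTR-pair scanning
#'
#' @param k seed k-mer size for self-matching.
#' @param minLtr,maxLtr accepted repeat lengths, bp.
#' @param minInternal,maxInternal accepted inter-repeat span, bp (the default
#'   3-12 kb widens the canonical ~7-11 kb provirus window so degraded
#'   elements are not silently missed; \code{strict = TRUE} restores it).
#' @param minIdentity minimum global-alignment identity of the pair (0.70
#'   keeps elements up to divergence ~0.4 detectable).
#' @param minSpan minimum contig length worth scanning.
#' @param diagTol anchor chaining tolerance on the repeat separation, bp.
#' @param scanWindow,scanIdentity smoothing window (bp) and identity floor
#'   used while extending a diagonal to the repeat boundaries.
#' @param maxKmerHits k-mers occurring more often are treated as
#'   low-complexity and skipped.
#' @param endSlack,atWindow,atMin motif-annotation settings, see
#'   \code{\link{annotateLTRMotifs}}.
#' @param minOrfAA minimum internal ORF length, amino acids.
#' @param strict if TRUE, restrict the internal span to 7-11 kb.
#' @return named list of settings.
#' @export
ltrScanConfig <- function(k = 15L, minLtr = 100L, maxLtr = 1500L,
                          minInternal = 3000L, maxInternal = 12000L,
                          minIdentity = 0.70, minSpan = 3200L, diagTol = 50L,
                          scanWindow = 31L, scanIdentity = 0.55,
                          maxKmerHits = 10L, endSlack = 2L, atWindow = 20L,
                          atMin = 0.7, minOrfAA = 80L, strict = FALSE) {
  cfg <- list(k = as.integer(k), minLtr = as.integer(minLtr),
              maxLtr = as.integer(maxLtr), minInternal = as.integer(minInternal),
              maxInternal = as.integer(maxInternal),
              minIdentity = minIdentity, minSpan = as.integer(minSpan),
              diagTol = as.integer(diagTol), scanWindow = as.integer(scanWindow),
              scanIdentity = scanIdentity, maxKmerHits = as.integer(maxKmerHits),
              endSlack = as.integer(endSlack), atWindow = as.integer(atWindow),
              atMin = atMin, minOrfAA = as.integer(minOrfAA))
  if (isTRUE(strict)) {
    cfg$minInternal <- 7000L
    cfg$maxInternal <- 11000L
  }
  cfg
}

#' The neutral substitution-rate panel used for dating
#'
#' Two rates estimated from human ERVs (2.3e-9 and 5e-9 substitutions per
#' site per year) and a general felid nuclear rate (1.2e-8), each applied to
#' every divergence so that ages are bracketed rather than pinned to one
#' uncertain clock.
#'
#' @return data.frame with columns \code{label} and \code{rate}.
#' @export
defaultRatePanel <- function() {
  data.frame(label = c("huERV.slow", "huERV.fast", "felid.nuclear"),
             rate = c(2.3e-9, 5e-9, 1.2e-8))
}

#' Date one insertion from its LTR divergence
#'
#' Post-integration divergence accumulates on both LTR copies, so the age is
#' \code{T = D/(2R)} for divergence D and neutral rate R. The arithmetic is
#' exact; rounding happens only in report output. The divergence SE maps
#' through the same linear relation.
#'
#' @param D LTR-LTR divergence, substitutions/site (>= 0).
#' @param R substitution rate, substitutions/site/year (> 0).
#' @param seD optional SE of D, propagated to \code{T_se_MY}.
#' @param label optional rate label.
#' @return one-row data.frame with columns label, R, D, T_years, T_MY,
#'   T_se_MY.
#' @examples
#' dateInsertion(0.084, 2.3e-9)   # 18.26 million years
#' @export
dateInsertion <- function(D, R, seD = NA_real_, label = NA_character_) {
  if (!is.finite(D) || D < 0) .ervStop("D must be >= 0", "paramError")
  if (!is.finite(R) || R <= 0) .ervStop("R must be > 0", "paramError")
  Ty <- D / (2 * R)
  data.frame(label = label, R = R, D = D, T_years = Ty, T_MY = Ty / 1e6,
             T_se_MY = if (is.na(seD)) NA_real_ else seD / (2 * R) / 1e6)
}

#' Date one divergence under a panel of rates
#'
#' @param D LTR-LTR divergence, substitutions/site.
#' @param panel data.frame with columns \code{label}, \code{rate}
#'   (default \code{\link{defaultRatePanel}}).
#' @param seD optional SE of D.
#' @return data.frame with one row per rate, panel order preserved.
#' @examples
#' dateWithRatePanel(0.064)   # 13.9 / 6.4 / 2.7 million years
#' @export
dateWithRatePanel <- function(D, panel = defaultRatePanel(), seD = NA_real_) {
  if (is.null(panel) || nrow(panel) == 0L)
    .ervStop("rate panel is empty", "paramError")
  if (any(panel$rate <= 0)) .ervStop("all panel rates must be > 0", "paramError")
  out <- do.call(rbind, lapply(seq_len(nrow(panel)), function(i)
    dateInsertion(D, panel$rate[i], seD, panel$label[i])))
  rownames(out) <- NULL
  out
}

#' Annotate the hallmark motifs of one LTR sequence
#'
#' Checks the short inverted-repeat dinucleotides TG (start) and CA (end)
#' within \code{endSlack} bp of the termini, the exact AATAAA
#' polyadenylation signal in the 3' half, and an AT-rich (TATA-like) window
#' of \code{atWindow} bp with A+T fraction >= \code{atMin} in the 5' half.
#'
#' @param ltr LTR sequence (DNAString or character).
#' @param endSlack terminal slack in bp.
#' @param atWindow,atMin AT-rich window length and A+T floor.
#' @return list with elements \code{startsTG}, \code{endsCA} (logical) and
#'   \code{polyA}, \code{atRich} (1-based start position or NA).
#' @export
annotateLTRMotifs <- function(ltr, endSlack = 2L, atWindow = 20L, atMin = 0.7) {
  s <- .asSingleString(ltr)
  n <- nchar(s)
  if (n == 0L) .ervStop("empty LTR sequence", "emptySequenceError")
  ch <- strsplit(s, "")[[1]]
  startsTG <- any(vapply(1:min(1L + endSlack, n - 1L), function(p)
    ch[p] == "T" && ch[p + 1L] == "G", logical(1)))
  endsCA <- any(vapply(max(n - endSlack, 2L):n, function(p)
    ch[p - 1L] == "C" && ch[p] == "A", logical(1)))
  half <- n %/% 2L
  pa <- gregexpr("AATAAA", s, fixed = TRUE)[[1]]
  pa <- pa[pa >= half + 1L]
  at <- NA_integer_
  if (half >= atWindow) {
    isAT <- cumsum(c(0L, as.integer(ch %in% c("A", "T"))))
    for (p in 1:(half - atWindow + 1L)) {
      if ((isAT[p + atWindow] - isAT[p]) / atWindow >= atMin) { at <- p; break }
    }
  }
  list(startsTG = startsTG, endsCA = endsCA,
       polyA = if (length(pa) && pa[1] > 0L) as.integer(pa[1]) else NA_integer_,
       atRich = at)
}

.motifScore <- function(m)
  sum(m$startsTG, m$endsCA, !is.na(m$polyA), !is.na(m$atRich))

## k-mer anchor pairs at provirus-like separations
.kmerPairs <- function(s, cfg) {
  n <- nchar(s)
  k <- cfg$k
  starts <- seq_len(n - k + 1L)
  km <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  grp <- split(starts[ok], km[ok])
  grp <- grp[lengths(grp) >= 2L & lengths(grp) <= cfg$maxKmerHits]
  minS <- cfg$minInternal + cfg$minLtr
  maxS <- cfg$maxInternal + cfg$maxLtr
  ii <- integer(0); jj <- integer(0)
  for (pos in grp) {
    cp <- combn(pos, 2L)
    sep <- cp[2L, ] - cp[1L, ]
    sel <- sep >= minS & sep <= maxS
    ii <- c(ii, cp[1L, sel]); jj <- c(jj, cp[2L, sel])
  }
  if (!length(ii)) return(NULL)
  o <- order(jj - ii, ii)
  data.frame(i = ii[o], j = jj[o], s = (jj - ii)[o])
}

## group anchors into diagonal clusters (similar separation, nearby starts)
.anchorClusters <- function(pairs, cfg) {
  brk <- c(0L, which(diff(pairs$s) > cfg$diagTol), nrow(pairs))
  out <- list()
  for (b in seq_len(length(brk) - 1L)) {
    blk <- pairs[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
    blk <- blk[order(blk$i), , drop = FALSE]
    cut <- c(0L, which(diff(blk$i) > cfg$maxLtr), nrow(blk))
    for (cc in seq_len(length(cut) - 1L)) {
      sub <- blk[(cut[cc] + 1L):cut[cc + 1L], , drop = FALSE]
      out[[length(out) + 1L]] <-
        list(i0 = min(sub$i), i1 = max(sub$i) + cfg$k - 1L,
             s = as.integer(round(median(sub$s))))
    }
  }
  out
}

## extend an anchor cluster along its diagonal to the repeat boundaries
.extendDiagonal <- function(ch, cl, cfg) {
  n <- length(ch)
  lo <- max(1L, cl$i0 - cfg$maxLtr)
  hi <- min(n - cl$s, cl$i1 + cfg$maxLtr)
  if (hi <= lo) return(NULL)
  x <- lo:hi
  m <- ch[x] == ch[x + cl$s] & ch[x] != "N"
  w <- min(cfg$scanWindow, length(m))
  sm <- as.numeric(stats::filter(as.numeric(m), rep(1 / w, w), sides = 2))
  ok <- !is.na(sm) & sm >= cfg$scanIdentity
  # anchors sit w/2 from the edges, where the smoother is defined
  mid <- cl$i0 - lo + 1L
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  startsR <- ends - r$lengths + 1L
  hit <- which(r$values & startsR <= mid + (cl$i1 - cl$i0) & ends >= mid)
  if (!length(hit)) return(NULL)
  ra <- startsR[hit[1]]; rb <- ends[hit[length(hit)]]
  seg <- ra:rb
  inTrue <- seg[m[seg]]
  if (!length(inTrue)) return(NULL)
  c(lo + min(inTrue) - 1L, lo + max(inTrue) - 1L)
}

## snap boundaries to terminal TG...CA present in both copies near the ends
.trimToMotifs <- function(ch, la, lb, S, cfg) {
  n <- length(ch)
  snap <- function(target, test) {
    cand <- (target - 12L):(target + 12L)
    cand <- cand[cand >= 1L & cand + S + 1L <= n & cand + 1L <= n]
    hit <- cand[vapply(cand, test, logical(1))]
    if (!length(hit)) return(NA_integer_)
    hit[which.min(abs(hit - target))]
  }
  qs <- snap(la, function(p) ch[p] == "T" && ch[p + 1L] == "G" &&
               ch[p + S] == "T" && ch[p + S + 1L] == "G")
  qe <- snap(lb, function(p) p > 1L && ch[p - 1L] == "C" && ch[p] == "A" &&
               ch[p + S - 1L] == "C" && ch[p + S] == "A")
  flag <- character(0)
  if ((!is.na(qs) && abs(qs - la) > 10L) || (!is.na(qe) && abs(qe - lb) > 10L))
    flag <- "boundary_convention_disagreement"
  list(start = if (is.na(qs)) la else qs, end = if (is.na(qe)) lb else qe,
       flags = flag)
}

#' Find candidate LTR pairs in one contig
#'
#' Seeded k-mer self-matching finds direct-repeat anchors; anchors are
#' chained per diagonal, extended along the diagonal to the repeat
#' boundaries, snapped to terminal TG...CA when both copies carry the motif,
#' and validated by affine global alignment of the two copies. A pair is
#' reported iff the repeat length, the inter-repeat span and the alignment
#' identity fall inside the configured windows; overlapping candidates are
#' resolved by highest identity, then longest repeat. Strand is inferred
#' from hallmark-motif evidence on the two orientations; coordinates are
#' always reported on the forward strand.
#'
#' @param contig a named length-1 \link[Biostrings]{DNAStringSet}, a
#'   \link[Biostrings]{DNAString}, or a character string (optionally named
#'   via \code{contigId}).
#' @param cfg an \code{\link{ltrScanConfig}}.
#' @param contigId identifier used when \code{contig} carries no name.
#' @return list of \linkS4class{LTRCandidate} (possibly empty).
#' @export
findLTRPairs <- function(contig, cfg = ltrScanConfig(), contigId = "contig") {
  if (is(contig, "DNAStringSet") && !is.null(names(contig)))
    contigId <- names(contig)[1]
  s <- .asSingleString(contig)
  n <- nchar(s)
  if (n < cfg$minSpan) return(list())
  ch <- strsplit(s, "")[[1]]
  pairs <- .kmerPairs(s, cfg)
  clusters <- if (is.null(pairs)) list() else .anchorClusters(pairs, cfg)
  cands <- .clustersToCandidates(clusters, s, ch, cfg, contigId)
  if (!length(cands)) {
    # diverged repeat pairs can share no exact k-mer seed; fall back to the
    # exhaustive windowed self-comparison over all plausible separations
    cands <- .clustersToCandidates(.diagonalClusters(ch, cfg), s, ch, cfg,
                                   contigId)
  }
  .resolveOverlaps(cands)
}

.diagonalClusters <- function(ch, cfg) {
  enc <- match(ch, c("A", "C", "G", "T")) - 1L
  enc[is.na(enc)] <- -1L
  runs <- .diagonalScanCpp(enc, cfg$minInternal + cfg$minLtr,
                           cfg$maxInternal + cfg$maxLtr,
                           window = 100L, minFrac = 0.55)
  lapply(seq_len(nrow(runs)), function(r)
    list(i0 = runs$start[r], i1 = runs$end[r], s = runs$s[r]))
}

.clustersToCandidates <- function(clusters, s, ch, cfg, contigId) {
  cands <- list()
  for (cl in clusters) {
    ext <- .extendDiagonal(ch, cl, cfg)
    if (is.null(ext)) next
    tm <- .trimToMotifs(ch, ext[1], ext[2], cl$s, cfg)
    la <- tm$start; lb <- tm$end
    len <- lb - la + 1L
    if (len < cfg$minLtr || len > cfg$maxLtr) next
    span <- cl$s - len                       # inter-repeat distance
    if (span < cfg$minInternal || span > cfg$maxInternal) next
    leftSeq <- substr(s, la, lb)
    rightSeq <- substr(s, la + cl$s, lb + cl$s)
    idn <- alignmentIdentity(globalAlign(leftSeq, rightSeq))
    if (idn < cfg$minIdentity) next
    mL <- annotateLTRMotifs(leftSeq, cfg$endSlack, cfg$atWindow, cfg$atMin)
    mR <- annotateLTRMotifs(rightSeq, cfg$endSlack, cfg$atWindow, cfg$atMin)
    mLrc <- annotateLTRMotifs(as.character(reverseComplement(DNAString(rightSeq))),
                              cfg$endSlack, cfg$atWindow, cfg$atMin)
    mRrc <- annotateLTRMotifs(as.character(reverseComplement(DNAString(leftSeq))),
                              cfg$endSlack, cfg$atWindow, cfg$atMin)
    minus <- (.motifScore(mLrc) + .motifScore(mRrc)) >
      (.motifScore(mL) + .motifScore(mR))
    cands[[length(cands) + 1L]] <- new("LTRCandidate",
      contig = contigId,
      left = IRanges(la, lb), right = IRanges(la + cl$s, lb + cl$s),
      strand = if (minus) "-" else "+", identity = idn,
      motifs = if (minus) list(left = mLrc, right = mRrc)
               else list(left = mL, right = mR),
      flags = tm$flags)
  }
  .resolveOverlaps(cands)
}

.rangesOverlap <- function(a, b) start(a) <= end(b) && start(b) <= end(a)

## keep non-overlapping candidates by highest identity, then longest repeat
.resolveOverlaps <- function(cands) {
  if (length(cands) <= 1L) return(cands)
  o <- order(-vapply(cands, function(x) x@identity, numeric(1)),
             -vapply(cands, function(x) width(x@left), integer(1)))
  kept <- list()
  for (idx in o) {
    cand <- cands[[idx]]
    clash <- any(vapply(kept, function(kp)
      .rangesOverlap(kp@left, cand@left) || .rangesOverlap(kp@right, cand@right) ||
      .rangesOverlap(IRanges(start(kp@left), end(kp@right)),
                     IRanges(start(cand@left), end(cand@right))), logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- cand
  }
  kept[order(vapply(kept, function(x) start(x@left), integer(1)))]
}

## stop-to-stop ORFs of >= minAA codons, six frames, coordinates on the
## forward strand of 'sq'
.findORFs <- function(sq, minAA) {
  s <- .asSingleString(sq)
  n <- nchar(s)
  res <- data.frame(start = integer(0), end = integer(0), frame = integer(0))
  scanStrand <- function(str, sign) {
    for (f in 0:2) {
      nc <- (nchar(str) - f) %/% 3L
      if (nc < minAA) next
      cods <- substring(str, f + 1L + 3L * (0:(nc - 1L)), f + 3L + 3L * (0:(nc - 1L)))
      isStop <- cods %in% .STOPS
      r <- rle(!isStop)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- which(r$values & r$lengths >= minAA)
      for (kk in keep) {
        a <- f + 3L * (starts[kk] - 1L) + 1L
        b <- f + 3L * ends[kk]
        if (sign > 0) {
          res <<- rbind(res, data.frame(start = a, end = b, frame = f + 1L))
        } else {
          res <<- rbind(res, data.frame(start = n - b + 1L, end = n - a + 1L,
                                        frame = -(f + 1L)))
        }
      }
    }
  }
  scanStrand(s, 1L)
  scanStrand(as.character(reverseComplement(DNAString(s))), -1L)
  res[order(res$start), , drop = FALSE]
}

#' Assemble a provirus call from a validated LTR pair
#'
#' Extracts the internal region, finds six-frame ORFs of at least
#' \code{cfg$minOrfAA} codons, checks gag-pol-env order (assignment by best
#' translated similarity to \code{polReference} when given, else purely
#' positional), computes the K2P divergence of the two LTR copies, converts
#' it to ages under the rate panel, scores pol intactness via
#' \code{\link{countDefects}}, and records target-site-duplication evidence
#' (identical 4-6 bp flanks; evidence only, never required).
#'
#' @param contig the contig sequence carrying the pair.
#' @param pair an \linkS4class{LTRCandidate} on that contig.
#' @param polReference optional intact pol protein
#'   (\link[Biostrings]{AAString} or character) for defect scoring and
#'   ORF-role assignment.
#' @param cfg an \code{\link{ltrScanConfig}}.
#' @param panel rate panel for dating.
#' @return a \linkS4class{ProvirusCall}.
#' @export
callProvirus <- function(contig, pair, polReference = NULL,
                         cfg = ltrScanConfig(), panel = defaultRatePanel()) {
  stopifnot(is(pair, "LTRCandidate"))
  s <- .asSingleString(contig)
  intStart <- end(pair@left) + 1L
  intEnd <- start(pair@right) - 1L
  if (intEnd - intStart + 1L < 3L * cfg$minOrfAA)
    .ervStop("internal region shorter than the minimum ORF", "internalTooShortError")
  internalSeq <- substr(s, intStart, intEnd)
  orient <- function(x) if (pair@strand == "-")
    as.character(reverseComplement(DNAString(x))) else x

  orfTab <- .findORFs(orient(internalSeq), cfg$minOrfAA)
  # report ORFs in forward-contig coordinates
  toContig <- function(a, b) {
    if (pair@strand == "-") {
      L <- nchar(internalSeq)
      c(intStart + (L - b), intStart + (L - a))
    } else c(intStart + a - 1L, intStart + b - 1L)
  }
  roles <- rep(NA_character_, nrow(orfTab))
  if (nrow(orfTab) > 0L && !is.null(polReference)) {
    ref <- AAString(.asSingleString(polReference))
    sc <- vapply(seq_len(nrow(orfTab)), function(r) {
      aa <- translate(DNAString(substr(orient(internalSeq),
                                       orfTab$start[r], orfTab$end[r] - 3L)),
                      if.fuzzy.codon = "X")
      as.numeric(score(pairwiseAlignment(aa, ref, type = "local",
                                         substitutionMatrix = "BLOSUM62",
                                         gapOpening = 10, gapExtension = 4)))
    }, numeric(1))
    polIdx <- which.max(sc)
    roles[polIdx] <- "pol"
    before <- which(orfTab$end < orfTab$start[polIdx])
    after <- which(orfTab$start > orfTab$end[polIdx])
    if (length(before)) roles[before[1]] <- "gag"
    if (length(after)) roles[after[length(after)]] <- "env"
  } else if (nrow(orfTab) >= 3L) {
    roles[1] <- "gag"; roles[nrow(orfTab)] <- "env"
    mid <- setdiff(seq_len(nrow(orfTab)), c(1L, nrow(orfTab)))
    roles[mid[which.max(orfTab$end[mid] - orfTab$start[mid])]] <- "pol"
  }
  orfCoords <- if (nrow(orfTab)) t(vapply(seq_len(nrow(orfTab)), function(r)
    toContig(orfTab$start[r], orfTab$end[r]), numeric(2))) else
    matrix(numeric(0), 0, 2)
  orfs <- IRanges(start = orfCoords[, 1], end = orfCoords[, 2])
  mcols(orfs)$frame <- orfTab$frame
  mcols(orfs)$role <- roles
  gi <- which(roles == "gag"); pi <- which(roles == "pol"); ei <- which(roles == "env")
  orderOk <- length(gi) == 1L && length(pi) == 1L && length(ei) == 1L &&
    (if (pair@strand == "-") start(orfs)[gi] > end(orfs)[pi] &&
       start(orfs)[pi] > end(orfs)[ei]
     else end(orfs)[gi] < start(orfs)[pi] && end(orfs)[pi] < start(orfs)[ei])

  ltr5Seq <- substr(s, start(pair@left), end(pair@left))
  ltr3Seq <- substr(s, start(pair@right), end(pair@right))
  div <- k2pDistance(countSitePatterns(globalAlign(ltr5Seq, ltr3Seq)))
  ageTab <- dateWithRatePanel(div@value, panel, div@se)

  report <- if (!is.null(polReference))
    countDefects(orient(internalSeq), polReference) else NULL

  tsd <- IRanges()
  for (t in 6:4) {
    a <- start(pair@left) - t; b <- end(pair@right)
    if (a >= 1L && b + t <= nchar(s) &&
        substr(s, a, a + t - 1L) == substr(s, b + 1L, b + t)) {
      tsd <- IRanges(c(a, b + 1L), width = t)
      break
    }
  }

  new("ProvirusCall", ltrPair = pair, internal = IRanges(intStart, intEnd),
      orfs = orfs, orfOrderOk = orderOk, tsd = tsd, intactness = report,
      divergence = div, ages = ageTab)
}

#' Scan contigs and assemble all provirus calls
#'
#' Convenience composition of \code{\link{findLTRPairs}} and
#' \code{\link{callProvirus}} over a sequence set.
#'
#' @param contigs a named \link[Biostrings]{DNAStringSet}.
#' @param polReference optional intact pol protein for defect scoring.
#' @param cfg an \code{\link{ltrScanConfig}}.
#' @param panel rate panel for dating.
#' @return list of \linkS4class{ProvirusCall}.
#' @export
scanContigs <- function(contigs, polReference = NULL, cfg = ltrScanConfig(),
                        panel = defaultRatePanel()) {
  stopifnot(is(contigs, "DNAStringSet"))
  out <- list()
  for (i in seq_along(contigs)) {
    for (pair in findLTRPairs(contigs[i], cfg)) {
      call <- tryCatch(
        callProvirus(contigs[i], pair, polReference, cfg, panel),
        ervclockError = function(e) NULL)
      if (!is.null(call)) out[[length(out) + 1L]] <- call
    }
  }
  out
}
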