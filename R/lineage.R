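## Lineage delimitation: Saitou-Nei neighbor joining (implemented here, with
## ape used only for the newick plumbing), single-linkage threshold
## clustering, conserved-block trimming of multiple alignments, and curation
## of homology-hit tables.

.asPlainMatrix <- function(m) {
  if (is(m, "DistanceMatrix")) return(distValue(m))
  stopifnot(is.matrix(m))
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' The classical Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i,j) = (r-2) d(i,j) - R_i - R_j is joined, with branch lengths
#' d(i,j)/2 +/- (R_i - R_j)/(2(r-2)) and the reduced matrix
#' d(u,k) = (d(i,k) + d(j,k) - d(i,j))/2. Ties on Q are broken by the
#' lexicographically smallest label pair (an internal node carries the
#' smallest leaf label of its subtree). Negative branch-length estimates are
#' clamped to zero and flagged. For any additive matrix the generating tree
#' is recovered exactly.
#'
#' @param m a \linkS4class{DistanceMatrix} or a labelled symmetric numeric
#'   matrix with at least 3 taxa and finite entries.
#' @return an unrooted \link[ape]{read.tree} \code{phylo} object (basal
#'   trifurcation); \code{attr(tree, "clamped")} lists edges whose negative
#'   length estimate was clamped to zero.
#' @export
neighborJoining <- function(m) {
  D <- .asPlainMatrix(m)
  n <- nrow(D)
  if (n < 3L) .ervStop("neighbor joining needs at least 3 taxa", "paramError")
  if (any(!is.finite(D))) .ervStop("non-finite distance entry", "nonFiniteError")
  labels <- rownames(D)
  frag <- labels                 # newick fragment per active node
  rep_ <- labels                 # tie-break label (min leaf label of subtree)
  clamped <- character(0)
  bl <- function(x, a, b) {
    if (x < 0) {
      clamped <<- c(clamped, sprintf("%s|%s", a, b))
      0
    } else x
  }
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    Rs <- rowSums(D)
    Q <- (r - 2) * D - outer(Rs, Rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      p <- sort(c(rep_[cand[k, 1]], rep_[cand[k, 2]]))
      paste(p, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[[1]]; j <- pick[[2]]
    li <- bl(D[i, j] / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2)), rep_[i], "u")
    lj <- bl(D[i, j] - (D[i, j] / 2 + (Rs[i] - Rs[j]) / (2 * (r - 2))),
             rep_[j], "u")
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(li), frag[j], fmt(lj))
    newRep <- min(rep_[i], rep_[j])
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    rep_ <- c(rep_[keep], newRep)
    rownames(D) <- colnames(D) <- rep_
  }
  la <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2, rep_[1], "v")
  lb2 <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2, rep_[2], "v")
  lc <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2, rep_[3], "v")
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(la), frag[2], fmt(lb2),
                 frag[3], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Delimit lineages by single-linkage threshold clustering
#'
#' Two sequences belong to one lineage iff they are connected by a chain of
#' pairwise distances <= \code{threshold} (single linkage) -- the unique
#' linkage for which "no between-lineage pair below the divergence
#' threshold" is guaranteed. Lineage labels are assigned by order of each
#' lineage's first member in the input.
#'
#' @param m a \linkS4class{DistanceMatrix} or labelled symmetric matrix.
#' @param threshold divergence cut, in (0, 1); the conventional cut for
#'   gamma-like ERV lineages is 0.15 (>15\% divergence between lineages).
#' @return a \linkS4class{LineagePartition}.
#' @export
cutLineages <- function(m, threshold = 0.15) {
  if (threshold <= 0 || threshold >= 1)
    .ervStop("threshold must lie in (0, 1)", "paramError")
  D <- .asPlainMatrix(m)
  n <- nrow(D)
  adj <- D <= threshold
  comp <- integer(n)
  cur <- 0L
  for (sd0 in seq_len(n)) {
    if (comp[sd0] != 0L) next
    cur <- cur + 1L
    queue <- sd0
    comp[sd0] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  names(comp) <- rownames(D)
  inter <- Inf; intra <- -Inf
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (comp[i] == comp[j]) intra <- max(intra, D[i, j])
    else inter <- min(inter, D[i, j])
  }
  new("LineagePartition", membership = comp, threshold = threshold,
      minInter = inter, maxIntra = if (is.finite(intra)) intra else 0)
}

.asAlnMatrix <- function(msa) {
  if (is(msa, "XStringSet")) {
    if (length(unique(width(msa))) != 1L)
      .ervStop("ragged alignment", "raggedAlignmentError")
    msa <- as.character(msa)
  }
  if (is.character(msa) && !is.matrix(msa)) {
    if (length(unique(nchar(msa))) != 1L)
      .ervStop("ragged alignment", "raggedAlignmentError")
    nm <- if (is.null(names(msa))) paste0("seq", seq_along(msa)) else names(msa)
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
    rownames(msa) <- nm
  }
  stopifnot(is.matrix(msa))
  msa
}

#' Remove poorly aligned blocks from a multiple alignment
#'
#' Column classification and block assembly in the style of conserved-block
#' trimming: a column where at least half the sequences carry a gap is
#' always excluded ("gap allowed with half"); a gap-free-enough column is
#' conserved when its modal residue reaches \code{minFlankSeqs} of the
#' sequences, else nonconserved. Runs of more than
#' \code{maxContigNonconserved} contiguous nonconserved columns are removed;
#' the surviving stretches are trimmed to conserved flanking columns; blocks
#' shorter than \code{minBlock} are dropped.
#'
#' @param msa a rectangular alignment: character matrix (rows = sequences),
#'   equal-length character vector, or \link[Biostrings]{XStringSet}.
#' @param minBlock minimum kept-block length, columns.
#' @param maxContigNonconserved longest tolerated run of nonconserved
#'   columns.
#' @param minFlankSeqs conservation threshold: a fraction of the sequence
#'   count when < 1, else an absolute sequence count.
#' @param gapMode \code{"half"} (exclude columns with >= 50\% gaps),
#'   \code{"none"} (exclude any gapped column) or \code{"all"} (never
#'   exclude on gaps).
#' @return a \linkS4class{TrimmedAlignment}.
#' @export
trimBlocks <- function(msa, minBlock = 5L, maxContigNonconserved = 8L,
                       minFlankSeqs = 0.85, gapMode = c("half", "none", "all")) {
  gapMode <- match.arg(gapMode)
  mat <- .asAlnMatrix(msa)
  if (nrow(mat) < 2L) .ervStop("need at least 2 sequences", "paramError")
  n <- nrow(mat); L <- ncol(mat)
  thr <- if (minFlankSeqs < 1) ceiling(minFlankSeqs * n) else minFlankSeqs
  isGapChar <- mat == "-" | mat == "."
  gapCount <- colSums(isGapChar)
  gapExcl <- switch(gapMode,
                    half = gapCount >= ceiling(n / 2),
                    none = gapCount > 0L,
                    all = rep(FALSE, L))
  modal <- vapply(seq_len(L), function(cix) {
    col <- mat[!isGapChar[, cix], cix]
    if (!length(col)) 0L else max(tabulate(factor(col)))
  }, integer(1))
  status <- ifelse(gapExcl, "gap", ifelse(modal >= thr, "cons", "noncons"))

  removed <- status == "gap"
  # long runs of contiguous nonconserved columns (contiguity among surviving)
  surv <- which(!removed)
  if (length(surv)) {
    r <- rle(status[surv] == "noncons")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths > maxContigNonconserved))
      removed[surv[starts[k]:ends[k]]] <- TRUE
  }
  # stretch assembly: surviving columns split at removed ones, trimmed to
  # conserved flanks, minimum block length enforced
  kept <- IRanges()
  surv <- which(!removed)
  if (length(surv)) {
    brk <- c(0L, which(diff(surv) > 1L), length(surv))
    for (b in seq_len(length(brk) - 1L)) {
      cols <- surv[(brk[b] + 1L):brk[b + 1L]]
      consIn <- which(status[cols] == "cons")
      if (!length(consIn)) next
      cols <- cols[min(consIn):max(consIn)]
      if (length(cols) >= minBlock)
        kept <- c(kept, IRanges(cols[1], cols[length(cols)]))
    }
  }
  new("TrimmedAlignment", source = mat, keptColumns = kept,
      params = list(minBlock = as.integer(minBlock),
                    maxContigNonconserved = as.integer(maxContigNonconserved),
                    minFlankSeqs = minFlankSeqs, gapMode = gapMode))
}

#' Extract the kept columns of a trimmed alignment
#'
#' @param x a \linkS4class{TrimmedAlignment}.
#' @param as \code{"matrix"} or \code{"character"} (one string per sequence).
#' @return the trimmed alignment in the requested form.
#' @export
trimmedSequences <- function(x, as = c("character", "matrix")) {
  as <- match.arg(as)
  stopifnot(is(x, "TrimmedAlignment"))
  cols <- unlist(lapply(seq_along(x@keptColumns), function(i)
    seq(start(x@keptColumns)[i], end(x@keptColumns)[i])))
  sub <- x@source[, cols, drop = FALSE]
  if (as == "matrix") sub else apply(sub, 1L, paste, collapse = "")
}

#' Curate a homology-hit table
#'
#' Removes rows failing any of the identity / coverage / e-value thresholds,
#' then collapses near-duplicate hits: rows sharing species and query whose
#' reported identity reaches \code{dedupIdentity} are treated as mutually
#' redundant and only the lowest-e-value representative is kept. The filter
#' is idempotent.
#'
#' @param hits data.frame with columns query_id, subject_id, identity,
#'   coverage, e_value, species (see \code{\link{readHitTable}}).
#' @param minIdentity,minCoverage percent floors.
#' @param maxEvalue e-value ceiling.
#' @param dedupIdentity percent identity above which same-species hits are
#'   collapsed.
#' @return the curated data.frame.
#' @export
hitFilter <- function(hits, minIdentity = 30, minCoverage = 70,
                      maxEvalue = 0.001, dedupIdentity = 95) {
  need <- c("query_id", "subject_id", "identity", "coverage", "e_value", "species")
  if (!all(need %in% names(hits)))
    .ervStop(paste("hit table must have columns:", paste(need, collapse = ", ")),
             "malformedRowError")
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$identity >= minIdentity & hits$coverage >= minCoverage &
    hits$e_value <= maxEvalue
  x <- hits[keep, , drop = FALSE]
  if (nrow(x) == 0L) return(x)
  grp <- paste(x$species, x$query_id, sep = "\r")
  drop <- logical(nrow(x))
  for (g in unique(grp)) {
    idx <- which(grp == g & x$identity >= dedupIdentity)
    if (length(idx) > 1L) {
      best <- idx[order(x$e_value[idx], x$subject_id[idx])][1]
      drop[setdiff(idx, best)] <- TRUE
    }
  }
  out <- x[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
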