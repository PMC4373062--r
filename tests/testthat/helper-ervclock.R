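suppressPackageStartupMessages({
  library(Biostrings)   # also attaches IRanges/S4Vectors generics
})

randomDNA <- function(n, seed = NULL, letters = c("A", "C", "G", "T")) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# one deterministic codon per amino acid, for exact back-translations
.BT <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
         E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
         M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
         Y = "TAT", V = "GTT")

backTranslate <- function(aa) {
  paste(.BT[strsplit(aa, "")[[1]]], collapse = "")
}

# a compact simulation for fast tests (still a realistic provirus layout)
smallSimParams <- function(...) {
  args <- list(ltrLength = 200L, internalLength = 3500L,
               backboneLength = 9000L, trueAge = 3e6, rate = 5e-9)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulationParams, args)
}

# manual PairwiseAlignment construction for site-pattern fixtures
mkAln <- function(a, b) {
  new("PairwiseAlignment", gappedA = a, gappedB = b, score = 0,
      scheme = alignScheme())
}

# independent exhaustive alignment oracle: enumerates every gapped alignment
# (no gap/gap columns) and scores it with affine gap costs
bruteForceAlignScore <- function(a, b, scheme = alignScheme()) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: ia, ib, last move (0 none, 1 diag, 2 gap-in-b, 3 gap-in-a)
  rec <- function(ia, ib, last, sc) {
    if (ia > length(ca) && ib > length(cb)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (ia <= length(ca) && ib <= length(cb)) {
      m <- if (ca[ia] == cb[ib]) scheme[["match"]] else scheme[["mismatch"]]
      rec(ia + 1L, ib + 1L, 1L, sc + m)
    }
    if (ia <= length(ca)) {   # ca[ia] against a gap in b
      open <- if (last != 2L) scheme[["gapOpen"]] else 0
      rec(ia + 1L, ib, 2L, sc + open + scheme[["gapExtend"]])
    }
    if (ib <= length(cb)) {   # cb[ib] against a gap in a
      open <- if (last != 3L) scheme[["gapOpen"]] else 0
      rec(ia, ib + 1L, 3L, sc + open + scheme[["gapExtend"]])
    }
  }
  rec(1L, 1L, 0L, 0)
  best
}
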