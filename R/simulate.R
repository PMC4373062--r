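## Ground-truth provirus simulator. A single ancestral LTR is duplicated and
## each copy evolves independently for rate * trueAge expected
## substitutions/site under K2P, so the expected pairwise LTR divergence is
## 2 * rate * trueAge -- exactly the model the dating relation T = D/(2R)
## assumes. The internal gag-pol-env cassette is built from designed ORFs;
## coding decay is represented solely by injected nonsense/frameshift events
## so that defect ground truth stays exact.

.DNA4 <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
# 12-mer with a stop codon in all three reading frames, used between ORFs
.SPACER <- "TAAATAAATAAA"

.randomDNA <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(.DNA4, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.nonStopCodons <- function() {
  all3 <- as.vector(outer(outer(.DNA4, .DNA4, paste0), .DNA4, paste0))
  setdiff(all3, .STOPS)
}

#' Simulation parameters for a synthetic provirus
#'
#' Defaults describe a typical gammaretrovirus-like felid provirus: 450 bp
#' LTRs (observed LTR lengths span roughly 166-632 bp), a 7 kb internal
#' gag-pol-env cassette (whole provirus ~7.9 kb, inside the ~7-11 kb window
#' of full-length elements), integration 10 million years ago (the basal
#' diversification of modern felids) at 5e-9 substitutions/site/year (the
#' middle of the neutral-rate panel), transition/transversion rate ratio
#' kappa = 2, a 5 bp target-site duplication and a 20 kb host backbone at
#' 42\% GC.
#'
#' @param ltrLength ancestral LTR length, bp (>= 50).
#' @param internalLength internal cassette length, bp (>= 300).
#' @param trueAge integration age, years (>= 0).
#' @param rate neutral substitution rate, substitutions/site/year (> 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param nNonsense in-frame stop codons injected into pol.
#' @param nFrameshift single-base indels injected into pol.
#' @param tsdLength target-site duplication length, bp.
#' @param backboneLength host contig length, bp
#'   (> 2 * ltrLength + internalLength).
#' @param gcContent backbone/LTR GC fraction, in (0, 1).
#' @param seed integer seed; all randomness of one simulation flows from it.
#' @param id contig identifier.
#' @return validated parameter list.
#' @export
simulationParams <- function(ltrLength = 450L, internalLength = 7000L,
                             trueAge = 1e7, rate = 5e-9, kappa = 2,
                             nNonsense = 2L, nFrameshift = 1L, tsdLength = 5L,
                             backboneLength = 20000L, gcContent = 0.42,
                             seed = 1L, id = "sim1") {
  p <- list(ltrLength = as.integer(ltrLength),
            internalLength = as.integer(internalLength),
            trueAge = as.numeric(trueAge), rate = as.numeric(rate),
            kappa = as.numeric(kappa), nNonsense = as.integer(nNonsense),
            nFrameshift = as.integer(nFrameshift),
            tsdLength = as.integer(tsdLength),
            backboneLength = as.integer(backboneLength),
            gcContent = as.numeric(gcContent), seed = as.integer(seed),
            id = as.character(id))
  if (p$ltrLength < 50L) .ervStop("ltrLength must be >= 50", "paramError")
  if (p$internalLength < 300L) .ervStop("internalLength must be >= 300", "paramError")
  if (p$trueAge < 0) .ervStop("trueAge must be >= 0", "paramError")
  if (p$rate <= 0) .ervStop("rate must be > 0", "paramError")
  if (p$kappa <= 0) .ervStop("kappa must be > 0", "paramError")
  if (p$nNonsense < 0L || p$nFrameshift < 0L)
    .ervStop("defect counts must be >= 0", "paramError")
  if (p$tsdLength < 0L || p$tsdLength > 20L)
    .ervStop("tsdLength must lie in [0, 20]", "paramError")
  if (p$backboneLength <= 2L * p$ltrLength + p$internalLength)
    .ervStop("backboneLength must exceed 2*ltrLength + internalLength", "paramError")
  if (p$gcContent <= 0 || p$gcContent >= 1)
    .ervStop("gcContent must lie in (0, 1)", "paramError")
  p
}

#' Construct an ancestral LTR carrying the canonical hallmarks
#'
#' The sequence begins with the inverted-repeat dinucleotide TG and ends
#' with CA, carries an exact AATAAA polyadenylation signal in its 3' half
#' and a 20 bp window with >= 70\% A+T (a TATA-like stretch) in its 5' half;
#' all remaining positions are drawn i.i.d. at the requested GC content.
#'
#' @param ltrLength LTR length in bp (>= 50, so all motifs fit).
#' @param gcContent GC fraction for non-motif positions.
#' @param seed optional integer seed.
#' @param detail if TRUE, return a list with the sequence and the motif
#'   placements instead of the bare sequence.
#' @return a \link[Biostrings]{DNAString} (or a list when \code{detail}).
#' @examples
#' makeAncestralLTR(300, seed = 7)
#' @export
makeAncestralLTR <- function(ltrLength, gcContent = 0.42, seed = NULL,
                             detail = FALSE) {
  n <- as.integer(ltrLength)
  if (n < 50L)
    .ervStop("LTR length below 50 bp cannot host all hallmark motifs",
             "paramError")
  withSeed(seed, {
    ch <- strsplit(.randomDNA(n, gcContent), "")[[1]]
    ch[1:2] <- c("T", "G")
    ch[(n - 1):n] <- c("C", "A")
    # TATA-like AT-rich 20-mer in the 5' half
    atStart <- sample(3:(n %/% 2 - 19L), 1L)
    win <- sample(.DNA4, 20L, replace = TRUE, prob = c(.45, .05, .05, .45))
    while (sum(win %in% c("A", "T")) < 14L)
      win[sample(which(!win %in% c("A", "T")), 1L)] <- sample(c("A", "T"), 1L)
    ch[atStart:(atStart + 19L)] <- win
    # polyadenylation signal in the 3' half, clear of the terminal CA
    paStart <- sample((n %/% 2 + 1L):(n - 7L), 1L)
    ch[paStart:(paStart + 5L)] <- c("A", "A", "T", "A", "A", "A")
    out <- DNAString(paste(ch, collapse = ""))
    if (detail)
      list(seq = out, atWindowStart = atStart, polyAStart = paStart)
    else out
  })
}

#' Evolve a sequence under the Kimura two-parameter substitution process
#'
#' Applies per-site K2P transition probabilities for a branch of
#' \code{branchLength} expected substitutions/site with transition rate
#' alpha and (total) transversion rate 2*beta, alpha/beta = kappa. The
#' process is indel-free and length preserving; N positions are left
#' untouched.
#'
#' @param seq a \link[Biostrings]{DNAString} (or character) to mutate.
#' @param branchLength expected substitutions/site (>= 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param seed optional integer seed.
#' @return mutated sequence of the same length and class.
#' @export
mutateK2P <- function(seq, branchLength, kappa = 2, seed = NULL) {
  if (branchLength < 0) .ervStop("branchLength must be >= 0", "paramError")
  if (kappa <= 0) .ervStop("kappa must be > 0", "paramError")
  s <- .asSingleString(seq)
  if (branchLength == 0) return(DNAString(s))
  bt <- branchLength / (kappa + 2)          # beta * t
  at <- kappa * bt                          # alpha * t
  pTs <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  pTv <- 0.5 - 0.5 * exp(-4 * bt)           # both transversion targets
  withSeed(seed, {
    ch <- strsplit(s, "")[[1]]
    base <- ch %in% .DNA4
    u <- runif(length(ch))
    pick <- runif(length(ch)) < 0.5         # which transversion target
    tsOf <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    isTs <- base & u < pTs
    isTv <- base & u >= pTs & u < pTs + pTv
    ch[isTs] <- tsOf[ch[isTs]]
    ch[isTv] <- ifelse(pick[isTv], tv1[ch[isTv]], tv2[ch[isTv]])
    DNAString(paste(ch, collapse = ""))
  })
}

# Designed ORF: ATG + uniform non-stop codons + TAA, total length nNt (3 | nNt)
.makeORF <- function(nNt) {
  nc <- nNt %/% 3L
  stopifnot(nc >= 3L)
  paste(c("ATG", sample(.nonStopCodons(), nc - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

# choose k positions from 'pool' pairwise separated by >= minSep
.spacedSample <- function(pool, k, minSep) {
  chosen <- integer(0)
  pool <- sample(pool)
  for (p in pool) {
    if (length(chosen) == k) break
    if (all(abs(chosen - p) >= minSep)) chosen <- c(chosen, p)
  }
  if (length(chosen) < k)
    .ervStop("pol too short for the requested number of well-separated defects",
             "paramError")
  sort(chosen)
}

#' Simulate a host contig containing one provirus with known ground truth
#'
#' One ancestral LTR is generated and duplicated; each copy evolves
#' independently through \code{\link{mutateK2P}} at branch length
#' \code{rate * trueAge}, so the two copies' expected pairwise divergence is
#' \code{2 * rate * trueAge}. The internal region carries designed ORFs in
#' gag-pol-env order (separated by spacers holding stop codons in all three
#' frames); \code{nNonsense} in-frame stops and \code{nFrameshift}
#' single-base indels are injected into pol at recorded positions. The
#' cassette is flanked by identical target-site duplications and embedded at
#' a seeded position in a random backbone.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @return a \linkS4class{SimulatedProvirus}.
#' @examples
#' sim <- simulateProvirus(simulationParams(trueAge = 5e6, seed = 42))
#' expectedDivergence(sim)
#' @export
simulateProvirus <- function(params = simulationParams()) {
  p <- do.call(simulationParams, params)    # re-validate
  withSeed(p$seed, {
    anc <- makeAncestralLTR(p$ltrLength, p$gcContent)
    bl <- p$rate * p$trueAge
    ltr5 <- as.character(mutateK2P(anc, bl, p$kappa))
    ltr3 <- as.character(mutateK2P(anc, bl, p$kappa))

    # internal layout: leader | gag | sp | pol | sp | env | trailer
    iL <- p$internalLength
    leadLen <- max(30L, as.integer(round(0.02 * iL)))
    gagLen <- 3L * max(3L, (as.integer(0.22 * iL) %/% 3L))
    polLen <- 3L * max(10L, (as.integer(0.40 * iL) %/% 3L))
    envLen <- 3L * max(3L, (as.integer(0.25 * iL) %/% 3L))
    spLen <- nchar(.SPACER)
    trailLen <- iL - leadLen - gagLen - polLen - envLen - 2L * spLen
    if (trailLen < 0L) {                     # shrink the leader to fit
      leadLen <- leadLen + trailLen
      trailLen <- 0L
    }
    if (leadLen < 0L) .ervStop("internalLength too small for the ORF layout",
                               "paramError")
    gag <- .makeORF(gagLen)
    pol <- .makeORF(polLen)
    env <- .makeORF(envLen)
    polProt <- as.character(translate(DNAString(substr(pol, 1L, polLen - 3L))))

    # inject defects into pol (positions recorded in intact-pol coordinates)
    nCodon <- polLen %/% 3L
    defects <- data.frame(kind = character(0), codon = integer(0),
                          polNt = integer(0), detail = character(0))
    usable <- 3:(nCodon - 2L)               # keep start/stop codons intact
    if (p$nNonsense + p$nFrameshift > 0L) {
      # >= 10 codons apart so nearby compensating indels cannot masquerade
      # as substitution runs in the downstream codon alignment
      at <- .spacedSample(usable, p$nNonsense + p$nFrameshift, 10L)
      kinds <- sample(rep(c("nonsense", "frameshift"),
                          c(p$nNonsense, p$nFrameshift)))
      polCh <- strsplit(pol, "")[[1]]
      edits <- data.frame(codon = at, kind = kinds)
      edits <- edits[order(-edits$codon), ]  # right-to-left keeps positions valid
      for (r in seq_len(nrow(edits))) {
        cd <- edits$codon[r]
        nt <- 3L * (cd - 1L) + 1L
        if (edits$kind[r] == "nonsense") {
          stopCd <- sample(.STOPS, 1L)
          polCh[nt:(nt + 2L)] <- strsplit(stopCd, "")[[1]]
          defects <- rbind(defects, data.frame(kind = "nonsense", codon = cd,
                                               polNt = nt, detail = stopCd))
        } else {
          if (runif(1) < 0.5) {             # deletion of one base
            polCh <- polCh[-(nt + 1L)]
            defects <- rbind(defects, data.frame(kind = "frameshift", codon = cd,
                                                 polNt = nt + 1L, detail = "del1"))
          } else {                          # insertion of one base
            polCh <- append(polCh, sample(.DNA4, 1L), after = nt)
            defects <- rbind(defects, data.frame(kind = "frameshift", codon = cd,
                                                 polNt = nt + 1L, detail = "ins1"))
          }
        }
      }
      pol <- paste(polCh, collapse = "")
    }
    defects <- defects[order(defects$polNt), , drop = FALSE]
    rownames(defects) <- NULL

    internal <- paste0(.randomDNA(leadLen, p$gcContent), gag, .SPACER, pol,
                       .SPACER, env, .randomDNA(max(trailLen, 0L), p$gcContent))
    cassette <- paste0(ltr5, internal, ltr3)

    backbone <- .randomDNA(p$backboneLength, p$gcContent)
    margin <- 200L + p$tsdLength
    site <- sample(margin:(p$backboneLength - margin), 1L)
    tsdSeq <- substr(backbone, site, site + p$tsdLength - 1L)
    contigChr <- paste0(substr(backbone, 1L, site + p$tsdLength - 1L), cassette,
                        substring(backbone, site))
    ltr5Start <- site + p$tsdLength
    intStart <- ltr5Start + nchar(ltr5)
    ltr3Start <- intStart + nchar(internal)
    rtsdStart <- ltr3Start + nchar(ltr3)

    contig <- DNAStringSet(contigChr)
    names(contig) <- p$id
    new("SimulatedProvirus",
        contig = contig,
        ltr5 = IRanges(ltr5Start, width = nchar(ltr5)),
        ltr3 = IRanges(ltr3Start, width = nchar(ltr3)),
        internal = IRanges(intStart, width = nchar(internal)),
        tsd = if (p$tsdLength > 0L)
          IRanges(c(site, rtsdStart), width = p$tsdLength) else IRanges(),
        trueAge = p$trueAge, rate = p$rate,
        expectedDivergence = 2 * p$rate * p$trueAge,
        defects = defects,
        polReference = AAString(polProt),
        params = p)
  })
}

#' Generate a benchmark dataset over a grid of simulation parameters
#'
#' One contig per grid row; every row overrides the defaults of
#' \code{\link{simulationParams}}. Per-row seeds are drawn deterministically
#' from the master seed, so the whole dataset (FASTA and truth table) is
#' byte-reproducible.
#'
#' @param grid data.frame whose columns are \code{\link{simulationParams}}
#'   argument names (missing columns take the defaults); one simulation per
#'   row. An \code{id} column, if absent, is filled with sim001, sim002, ...
#' @param seed master seed.
#' @param fastaPath,truthPath optional output paths for the contig FASTA and
#'   the ground-truth TSV.
#' @return list with \code{simulations} (list of
#'   \linkS4class{SimulatedProvirus}), \code{sequences}
#'   (\link[Biostrings]{DNAStringSet}) and \code{truth} (data.frame).
#' @export
generateDataset <- function(grid, seed = 1L, fastaPath = NULL, truthPath = NULL) {
  grid <- as.data.frame(grid)
  if (nrow(grid) == 0L) .ervStop("parameter grid is empty", "paramError")
  if (!"id" %in% names(grid))
    grid$id <- sprintf("sim%03d", seq_len(nrow(grid)))
  if (anyDuplicated(grid$id))
    .ervStop("duplicate contig ids in grid", "duplicateIdError")
  bad <- setdiff(names(grid), names(formals(simulationParams)))
  if (length(bad))
    .ervStop(paste("unknown grid column(s):", paste(bad, collapse = ", ")),
             "paramError")
  sims <- withSeed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
    lapply(seq_len(nrow(grid)), function(i) {
      args <- as.list(grid[i, , drop = FALSE])
      args$seed <- seeds[i]
      simulateProvirus(do.call(simulationParams, args))
    })
  })
  seqs <- do.call(c, lapply(sims, contigSeq))
  truth <- do.call(rbind, lapply(sims, function(s) {
    p <- s@params
    data.frame(id = p$id, contig_length = width(s@contig)[1],
               ltr5_start = start(s@ltr5), ltr5_end = end(s@ltr5),
               internal_start = start(s@internal), internal_end = end(s@internal),
               ltr3_start = start(s@ltr3), ltr3_end = end(s@ltr3),
               tsd_length = p$tsdLength, true_age = s@trueAge, rate = s@rate,
               expected_divergence = s@expectedDivergence,
               n_nonsense = sum(s@defects$kind == "nonsense"),
               n_frameshift = sum(s@defects$kind == "frameshift"),
               seed = p$seed)
  }))
  if (!is.null(fastaPath)) writeFasta(seqs, fastaPath)
  if (!is.null(truthPath))
    write.table(truth, truthPath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(simulations = sims, sequences = seqs, truth = truth)
}
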