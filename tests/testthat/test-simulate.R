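test_that("ancestral LTRs carry all hallmark motifs and are seed-deterministic", {
  for (len in c(60L, 160L, 450L, 640L)) {
    ltr <- makeAncestralLTR(len, seed = len)
    m <- annotateLTRMotifs(ltr)
    expect_true(m$startsTG)
    expect_true(m$endsCA)
    expect_false(is.na(m$polyA))
    expect_false(is.na(m$atRich))
    expect_equal(length(ltr), len)
  }
  expect_equal(as.character(makeAncestralLTR(300, seed = 5)),
               as.character(makeAncestralLTR(300, seed = 5)))
  expect_error(makeAncestralLTR(40), class = "paramError")
})

test_that("non-motif LTR positions hit the requested GC content", {
  nRep <- 300L
  len <- 300L
  gcTarget <- 0.4
  gcCount <- 0L
  nPos <- 0L
  for (i in seq_len(nRep)) {
    d <- makeAncestralLTR(len, gcContent = gcTarget, seed = i, detail = TRUE)
    ch <- strsplit(as.character(d$seq), "")[[1]]
    motif <- c(1:2, (len - 1):len, d$atWindowStart:(d$atWindowStart + 19L),
               d$polyAStart:(d$polyAStart + 5L))
    free <- ch[-motif]
    gcCount <- gcCount + sum(free %in% c("G", "C"))
    nPos <- nPos + length(free)
  }
  se <- sqrt(gcTarget * (1 - gcTarget) / nPos)
  expect_lt(abs(gcCount / nPos - gcTarget), 3 * se)
})

test_that("the K2P mutator is consistent with the K2P estimator", {
  anc <- DNAString(randomDNA(10000, seed = 2))
  # zero branch leaves the sequence untouched
  expect_equal(as.character(mutateK2P(anc, 0)), as.character(anc))
  # mean estimated distance over replicates matches the branch length
  ests <- vapply(1:200, function(i) {
    mut <- mutateK2P(anc, 0.1, kappa = 2, seed = i)
    distValue(k2pDistance(countSitePatterns(
      mkAln(as.character(anc), as.character(mut)))))
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.1), 3 * se)
  expect_error(mutateK2P(anc, -0.1), class = "paramError")
  expect_error(mutateK2P(anc, 0.1, kappa = 0), class = "paramError")
})

test_that("large kappa suppresses transversions", {
  anc <- DNAString(randomDNA(20000, seed = 4))
  mut <- mutateK2P(anc, 0.1, kappa = 1e6, seed = 9)
  cnt <- siteCounts(countSitePatterns(mkAln(as.character(anc), as.character(mut))))
  expect_gt(cnt[["ts"]], 100L)
  expect_lt(cnt[["tv"]] / cnt[["ts"]], 0.01)
})

test_that("simulated proviruses satisfy their own ground-truth contract", {
  # age zero: identical LTR copies, fully flagged motifs
  sim0 <- simulateProvirus(smallSimParams(trueAge = 0, nNonsense = 0L,
                                          nFrameshift = 0L, seed = 8))
  s <- as.character(contigSeq(sim0))[[1]]
  tr <- ltrPair(sim0)
  l5 <- substr(s, IRanges::start(tr$ltr5), IRanges::end(tr$ltr5))
  l3 <- substr(s, IRanges::start(tr$ltr3), IRanges::end(tr$ltr3))
  expect_identical(l5, l3)
  m <- annotateLTRMotifs(l5)
  expect_true(m$startsTG && m$endsCA && !is.na(m$polyA) && !is.na(m$atRich))
  # TSD copies are identical and flank the element
  expect_identical(substr(s, IRanges::start(tr$tsd)[1], IRanges::end(tr$tsd)[1]),
                   substr(s, IRanges::start(tr$tsd)[2], IRanges::end(tr$tsd)[2]))

  # expected divergence is exactly 2 R T
  sim <- simulateProvirus(simulationParams(rate = 2.3e-9, trueAge = 1e7, seed = 3))
  expect_equal(expectedDivergence(sim), 0.046)

  # injected frameshifts are recovered against the intact pol reference
  simF <- simulateProvirus(smallSimParams(nNonsense = 0L, nFrameshift = 2L,
                                          trueAge = 0, seed = 12))
  sF <- as.character(contigSeq(simF))[[1]]
  int <- internalRange(simF)
  rep <- countDefects(substr(sF, IRanges::start(int), IRanges::end(int)),
                      polReference(simF))
  expect_equal(unname(intactness(rep)), c(0L, 2L))
})

test_that("realized LTR divergence tracks 2RT across ages at the fast felid rate", {
  for (ageMY in c(5, 30)) {
    anc <- makeAncestralLTR(600, seed = ageMY)
    target <- 2 * 1.2e-8 * ageMY * 1e6
    ests <- vapply(1:100, function(i) {
      a <- mutateK2P(anc, target / 2, seed = 2 * i)
      b <- mutateK2P(anc, target / 2, seed = 2 * i + 1)
      distValue(k2pDistance(countSitePatterns(
        mkAln(as.character(a), as.character(b)))))
    }, numeric(1))
    se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - target), 3 * se)
  }
})

test_that("dataset generation is grid-faithful and byte-reproducible", {
  grid <- data.frame(trueAge = c(1e6, 5e6, 1e7), rate = 5e-9,
                     ltrLength = 120L, internalLength = 3200L,
                     backboneLength = 7500L)
  f1 <- tempfile(fileext = ".fa"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fa"); t2 <- tempfile(fileext = ".tsv")
  d1 <- generateDataset(grid, seed = 99, fastaPath = f1, truthPath = t1)
  d2 <- generateDataset(grid, seed = 99, fastaPath = f2, truthPath = t2)
  expect_length(d1$simulations, 3L)
  expect_equal(nrow(d1$truth), 3L)
  expect_equal(d1$truth$expected_divergence, c(0.01, 0.05, 0.10))
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  # duplicate ids refused
  gridDup <- grid; gridDup$id <- c("x", "x", "y")
  expect_error(generateDataset(gridDup), class = "duplicateIdError")
})
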