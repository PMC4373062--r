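test_that("the dating relation is exact, linear in D and inverse in R", {
  expect_equal(dateInsertion(0, 2.3e-9)$T_years, 0)
  d1 <- dateInsertion(0.05, 5e-9)
  expect_equal(d1$T_years, 0.05 / (2 * 5e-9))
  expect_equal(dateInsertion(0.10, 5e-9)$T_MY, 2 * d1$T_MY)
  expect_equal(dateInsertion(0.05, 1e-8)$T_MY, d1$T_MY / 2)
  # SE maps through the same linear relation
  expect_equal(dateInsertion(0.05, 5e-9, seD = 0.01)$T_se_MY,
               0.01 / (2 * 5e-9) / 1e6)
  expect_error(dateInsertion(-0.1, 5e-9), class = "paramError")
  expect_error(dateInsertion(0.1, 0), class = "paramError")
})

test_that("the rate panel defaults to the three published neutral rates in order", {
  panel <- defaultRatePanel()
  expect_equal(panel$rate, c(2.3e-9, 5e-9, 1.2e-8))
  ages <- dateWithRatePanel(0, panel)
  expect_equal(ages$T_MY, c(0, 0, 0))
  expect_equal(ages$label, panel$label)
  expect_error(dateWithRatePanel(0.1, data.frame(label = "x", rate = -1)),
               class = "paramError")
})

test_that("LTR motif annotation honors slack, halves and windows", {
  # TG/CA termini only: GC-rich core defeats polyA and the AT window
  gcCore <- paste(rep(c("G", "C"), 148), collapse = "")
  m <- annotateLTRMotifs(paste0("TG", gcCore, "CA"))
  expect_true(m$startsTG)
  expect_true(m$endsCA)
  expect_true(is.na(m$polyA))
  expect_true(is.na(m$atRich))

  # no TG within the slack
  m2 <- annotateLTRMotifs(paste0("CCCC", gcCore, "CA"), endSlack = 2)
  expect_false(m2$startsTG)

  # AATAAA counts only in the 3' half
  left <- paste0("TG", "AATAAA", paste(rep("G", 92), collapse = ""))
  right <- paste(rep("C", 98), collapse = "")
  m3 <- annotateLTRMotifs(paste0(left, right, "CA"))
  expect_true(is.na(m3$polyA))
})

test_that("LTR pairs are recovered from simulated proviruses with tight boundaries", {
  recOverlap <- function(est, tru) {
    inter <- max(0L, min(IRanges::end(est), IRanges::end(tru)) -
                   max(IRanges::start(est), IRanges::start(tru)) + 1L)
    min(inter / IRanges::width(est), inter / IRanges::width(tru))
  }
  sim <- simulateProvirus(simulationParams(trueAge = 5e6, rate = 5e-9, seed = 31))
  pairs <- findLTRPairs(contigSeq(sim))
  expect_length(pairs, 1L)
  tr <- ltrPair(sim)
  expect_gte(recOverlap(pairs[[1]]@left, tr$ltr5), 0.95)
  expect_gte(recOverlap(pairs[[1]]@right, tr$ltr3), 0.95)

  # a short contig is silently empty
  expect_equal(findLTRPairs(randomDNA(1000, seed = 1)), list())
})

test_that("detection recall is complete inside the identity floor's margin", {
  # 200 bp LTRs at expected divergence 0.20: realized pair identity stays
  # well above the 0.70 floor, so every replicate must be found
  for (i in 1:10) {
    sim <- simulateProvirus(simulationParams(
      ltrLength = 200L, rate = 1e-8, trueAge = 1e7, internalLength = 4000L,
      backboneLength = 10000L, seed = 600L + i))
    expect_length(findLTRPairs(contigSeq(sim)), 1L)
  }
})

test_that("insert-free backbones yield no calls", {
  set.seed(17)
  fp <- 0L
  for (i in 1:20) fp <- fp + length(findLTRPairs(randomDNA(50000)))
  expect_equal(fp, 0L)
})

test_that("provirus calls carry ORF order, defect truth and reproducible divergence", {
  sim <- simulateProvirus(simulationParams(trueAge = 4e6, rate = 5e-9, seed = 55,
                                           nNonsense = 0L, nFrameshift = 2L))
  s <- contigSeq(sim)
  pairs <- findLTRPairs(s)
  call <- callProvirus(s, pairs[[1]], polReference(sim))
  expect_true(call@orfOrderOk)
  expect_equal(unname(intactness(intactness(call))), c(0L, 2L))
  expect_equal(nrow(ages(call)), 3L)
  # re-extracting the reported LTR substrings reproduces the divergence exactly
  chr <- as.character(s)[[1]]
  p <- ltrPair(call)
  l5 <- substr(chr, IRanges::start(p@left), IRanges::end(p@left))
  l3 <- substr(chr, IRanges::start(p@right), IRanges::end(p@right))
  redo <- k2pDistance(countSitePatterns(globalAlign(l5, l3)))
  expect_identical(distValue(redo), distValue(divergence(call)))
  # TSD evidence is recorded when the repeat boundaries are exact (age 0)
  sim0 <- simulateProvirus(simulationParams(trueAge = 0, seed = 56))
  call0 <- callProvirus(contigSeq(sim0), findLTRPairs(contigSeq(sim0))[[1]])
  expect_equal(IRanges::width(call0@tsd), c(5L, 5L))

  # an LTR pair with no internal room is rejected
  fake <- new("LTRCandidate", contig = "c", left = IRanges::IRanges(1, 200),
              right = IRanges::IRanges(260, 459), strand = "+", identity = 1,
              motifs = list(left = list(), right = list()), flags = character(0))
  expect_error(callProvirus(strrep("A", 600), fake),
               class = "internalTooShortError")
})

test_that("calls on the reverse strand are reported on forward coordinates", {
  sim <- simulateProvirus(simulationParams(trueAge = 3e6, rate = 5e-9, seed = 77))
  fwd <- contigSeq(sim)
  rcSeq <- Biostrings::reverseComplement(fwd[[1]])
  rc <- Biostrings::DNAStringSet(rcSeq)
  names(rc) <- "rc_contig"
  pairs <- findLTRPairs(rc)
  expect_length(pairs, 1L)
  expect_equal(pairs[[1]]@strand, "-")
  n <- length(rcSeq)
  tr <- ltrPair(sim)
  # truth ltr3 maps to the left repeat on the reverse-complemented contig
  expect_equal(IRanges::start(pairs[[1]]@left), n - IRanges::end(tr$ltr3) + 1L,
               tolerance = 0, ignore_attr = TRUE)
  call <- callProvirus(rc, pairs[[1]], polReference(sim))
  expect_true(call@orfOrderOk)
  expect_equal(distValue(divergence(call)),
               distValue(divergence(callProvirus(fwd, findLTRPairs(fwd)[[1]],
                                                 polReference(sim)))),
               tolerance = 1e-12)
})
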