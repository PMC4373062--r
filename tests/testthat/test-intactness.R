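test_that("an exact back-translation of the reference has no defects", {
  ref <- "MKLVINTREQWAGHDSAPLYFCMKLVINTREQWAGHDSAPLYFC"
  rep <- countDefects(backTranslate(ref), ref)
  expect_equal(unname(intactness(rep)), c(0L, 0L))
})

test_that("a constructed deletion and premature stop are counted once each", {
  ref <- paste(rep("MKLVINTREQWAGHDSAPLYF", 3), collapse = "")  # 63 aa
  q <- backTranslate(ref)
  # one base deleted inside codon 10, codon 20 turned into TGA
  qCh <- strsplit(q, "")[[1]]
  qCh <- qCh[-29]                           # delete 2nd base of codon 10
  qCh[57:59] <- c("T", "G", "A")            # codon 20 in the shifted frame
  rep <- countDefects(paste(qCh, collapse = ""), ref)
  expect_equal(rep@nFrameshift, 1L)
  expect_equal(rep@nNonsense, 1L)
  expect_true(all(diff(defectEvents(rep)$position) > 0))
})

test_that("compensating frameshifts count by how much intact frame separates them", {
  ref <- paste(rep("MKLVINTREQWAGHDSAPLYF", 4), collapse = "")
  q <- backTranslate(ref)
  qCh <- strsplit(q, "")[[1]]
  # del at codon 15, ins at codon 40: well separated -> 2 events
  qCh2 <- append(qCh[-(3 * 14 + 2)], "G", after = 3 * 39)
  rep2 <- countDefects(paste(qCh2, collapse = ""), ref)
  expect_equal(rep2@nFrameshift, 2L)
  # del then compensating ins in the adjacent codon: the frame is intact
  # outside a two-codon window, so the region reads as substitutions and no
  # frameshift survives
  qCh1 <- append(qCh[-(3 * 14 + 2)], "G", after = 3 * 15)
  rep1 <- countDefects(paste(qCh1, collapse = ""), ref)
  expect_equal(rep1@nFrameshift, 0L)
  expect_equal(rep1@nNonsense, 0L)
})

test_that("defect reports are invariant to synonymous substitutions", {
  ref <- paste(rep("MKLVINTREQWAGHDSAPLYF", 3), collapse = "")
  q <- backTranslate(ref)
  # swap some codons for synonyms (L: CTG->CTA, V: GTT->GTC, S: TCT->AGC)
  qSyn <- sub("CTG", "CTA", q, fixed = TRUE)
  qSyn <- sub("GTT", "GTC", qSyn, fixed = TRUE)
  qSyn <- sub("TCT", "AGC", qSyn, fixed = TRUE)
  expect_false(identical(q, qSyn))
  expect_equal(unname(intactness(countDefects(qSyn, ref))), c(0L, 0L))
})

test_that("the scanner locates pol inside a larger region and preconditions hold", {
  ref <- paste(rep("MKLVINTREQWAGHDSAPLYF", 3), collapse = "")
  flanked <- paste0(randomDNA(200, seed = 6), backTranslate(ref),
                    randomDNA(150, seed = 7))
  expect_equal(unname(intactness(countDefects(flanked, ref))), c(0L, 0L))
  expect_error(countDefects("", ref), class = "emptySequenceError")
  expect_error(countDefects("AC", ref), class = "untranslatableError")
  expect_error(countDefects("ACGACG", "MKL"), class = "paramError")
})

test_that("injected defects in simulated pol are recovered almost always, off-by-one at worst", {
  set.seed(23)
  nCase <- 40L
  exact <- 0L
  offByOne <- 0L
  for (i in seq_len(nCase)) {
    nn <- sample(0:6, 1)
    nf <- sample(0:4, 1)
    sim <- simulateProvirus(simulationParams(
      ltrLength = 150L, internalLength = 4000L, backboneLength = 8500L,
      trueAge = 0, nNonsense = nn, nFrameshift = nf, seed = 1000L + i))
    s <- as.character(contigSeq(sim))[[1]]
    int <- internalRange(sim)
    rep <- countDefects(substr(s, IRanges::start(int), IRanges::end(int)),
                        polReference(sim))
    got <- unname(intactness(rep))
    if (identical(got, c(nn, nf))) exact <- exact + 1L
    else if (sum(abs(got - c(nn, nf))) <= 1L) offByOne <- offByOne + 1L
  }
  expect_gte(exact / nCase, 0.95)
  expect_equal(exact + offByOne, nCase)
})

test_that("defect summaries use the lower median and the full range", {
  mkRep <- function(k) new("ORFIntactnessReport", nNonsense = as.integer(k),
                           nFrameshift = 0L,
                           events = data.frame(kind = rep("nonsense", k),
                                               position = seq_len(k),
                                               detail = rep("", k),
                                               merged = rep(FALSE, k)),
                           reference = "ref")
  s1 <- summarizeDefects(lapply(c(0, 1, 5), mkRep), rep("L1", 3))
  expect_equal(s1$median, 1)
  expect_equal(c(s1$min, s1$max), c(0, 5))
  s2 <- summarizeDefects(lapply(c(2, 4), mkRep), rep("L2", 2))
  expect_equal(s2$median, 2)
  s3 <- summarizeDefects(list(mkRep(7)), "L3")
  expect_equal(c(s3$median, s3$min, s3$max), c(7, 7, 7))
})
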