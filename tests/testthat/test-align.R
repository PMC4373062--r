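test_that("global alignment handles identity, length forcing and its invariants", {
  aln <- globalAlign("ACGT", "ACGT")
  expect_equal(aln@score, 4)
  expect_equal(aln@gappedA, "ACGT")

  aln2 <- globalAlign("AAAA", "AAA")
  gapCols <- sum(strsplit(aln2@gappedB, "")[[1]] == "-")
  expect_equal(gapCols, 1L)
  expect_equal(nchar(aln2@gappedA), nchar(aln2@gappedB))

  set.seed(7)
  for (i in 1:20) {
    a <- randomDNA(sample(5:40, 1))
    b <- randomDNA(sample(5:40, 1))
    al <- globalAlign(a, b)
    ga <- strsplit(al@gappedA, "")[[1]]
    gb <- strsplit(al@gappedB, "")[[1]]
    expect_equal(length(ga), length(gb))
    expect_false(any(ga == "-" & gb == "-"))
    expect_equal(paste(ga[ga != "-"], collapse = ""), a)
    expect_equal(paste(gb[gb != "-"], collapse = ""), b)
  }
  expect_error(globalAlign("", "ACGT"), class = "emptySequenceError")
})

test_that("alignment scores match exhaustive enumeration on small strings", {
  strs <- unlist(lapply(1:4, function(L)
    apply(expand.grid(rep(list(c("A", "C")), L)), 1, paste, collapse = "")))
  set.seed(11)
  pairs <- cbind(sample(strs, 40, replace = TRUE), sample(strs, 40, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    expect_equal(globalAlign(pairs[r, 1], pairs[r, 2])@score,
                 bruteForceAlignScore(pairs[r, 1], pairs[r, 2]),
                 info = paste(pairs[r, ], collapse = " vs "))
  }
})

test_that("site patterns exclude gaps and Ns and split ts/tv correctly", {
  ident <- mkAln(strrep("A", 50), strrep("A", 50))
  c0 <- siteCounts(countSitePatterns(ident))
  expect_equal(unname(c0), c(50L, 0L, 0L))

  # columns: A/G (ts), C/T (ts), A/C (tv), A/- (excluded)
  c1 <- siteCounts(countSitePatterns(mkAln("ACAA", "GTC-")))
  expect_equal(unname(c1), c(3L, 2L, 1L))

  cN <- siteCounts(countSitePatterns(mkAln("NNNN", "ACGT")))
  expect_equal(cN[["n"]], 0L)
})

test_that("p-distance matches its closed form and bootstrap agrees with analytic SE", {
  z <- pDistance(new("SiteCounts", n = 100L, ts = 0L, tv = 0L))
  expect_equal(distValue(z), 0)
  expect_equal(distSE(z), 0)

  d <- pDistance(new("SiteCounts", n = 100L, ts = 6L, tv = 4L))
  expect_equal(distValue(d), 0.10)
  expect_equal(distSE(d), sqrt(0.1 * 0.9 / 100))

  b <- pDistance(new("SiteCounts", n = 100L, ts = 6L, tv = 4L),
                 seMethod = "bootstrap", nBoot = 10000L, seed = 1)
  expect_lt(abs(distSE(b) - 0.03) / 0.03, 0.10)

  expect_error(pDistance(new("SiteCounts", n = 0L, ts = 0L, tv = 0L)),
               class = "noSitesError")
})

test_that("K2P matches its closed form, reduces to Jukes-Cantor, and flags saturation", {
  expect_equal(distValue(k2pDistance(new("SiteCounts", n = 100L, ts = 0L, tv = 0L))), 0)

  d <- k2pDistance(new("SiteCounts", n = 1000L, ts = 100L, tv = 50L))
  expect_equal(distValue(d), -0.5 * log(0.75) - 0.25 * log(0.90), tolerance = 1e-12)
  expect_equal(distValue(d), 0.17018, tolerance = 1e-4)

  # with ts/tv in ratio 1:2, K2P collapses to Jukes-Cantor
  n <- 300L
  for (p in seq(0.03, 0.72, by = 0.03)) {
    ts <- as.integer(round(p * n / 3))
    tv <- 2L * ts
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_equal(distValue(k2pDistance(new("SiteCounts", n = n, ts = ts, tv = tv))),
                 jc, tolerance = 1e-9, info = paste("p =", p))
  }

  expect_error(k2pDistance(new("SiteCounts", n = 10L, ts = 5L, tv = 1L)),
               class = "saturationError")
  expect_error(k2pDistance(new("SiteCounts", n = 10L, ts = 5L, tv = 1L)), "saturation")
})

test_that("K2P dominates p-distance and grows monotonically in P and Q", {
  n <- 1000L
  set.seed(3)
  for (i in 1:30) {
    ts <- sample(0:200, 1); tv <- sample(0:150, 1)
    cnt <- new("SiteCounts", n = n, ts = as.integer(ts), tv = as.integer(tv))
    k <- distValue(k2pDistance(cnt))
    p <- distValue(pDistance(cnt))
    if (ts + tv == 0) expect_equal(k, p) else expect_gt(k, p)
  }
  base <- distValue(k2pDistance(new("SiteCounts", n = n, ts = 50L, tv = 50L)))
  expect_gt(distValue(k2pDistance(new("SiteCounts", n = n, ts = 60L, tv = 50L))), base)
  expect_gt(distValue(k2pDistance(new("SiteCounts", n = n, ts = 50L, tv = 60L))), base)
})

test_that("p-distance is unbiased on simulated site counts", {
  set.seed(42)
  truth <- 0.08
  n <- 500L
  ests <- vapply(1:1000, function(i) {
    nd <- rbinom(1, n, truth)
    distValue(pDistance(new("SiteCounts", n = n, ts = as.integer(nd), tv = 0L)))
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - truth), 3 * se)
})

test_that("distance matrices are symmetric, label-invariant and compositional", {
  seqs <- DNAStringSet(c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "ACGTACGTAC"))
  dm <- distanceMatrix(seqs, model = "p")
  expect_true(all(distValue(dm) == 0))

  s2 <- DNAStringSet(c(a = "ACGTACGTACGTACGTACGT", b = "ACGTACGAACGTACTTACGT"))
  dm2 <- distanceMatrix(s2, model = "p")
  direct <- pDistance(countSitePatterns(globalAlign(s2[[1]], s2[[2]])))
  expect_equal(distValue(dm2)["a", "b"], distValue(direct))

  s3 <- DNAStringSet(c(a = randomDNA(200, 1), b = randomDNA(200, 2),
                       c = randomDNA(200, 3)))
  m1 <- distValue(distanceMatrix(s3, model = "p"))
  m2 <- distValue(distanceMatrix(rev(s3), model = "p"))
  expect_equal(m1[c("a", "b", "c"), c("a", "b", "c")],
               m2[c("a", "b", "c"), c("a", "b", "c")])

  # saturated pairs are reported with their ids
  sat <- DNAStringSet(c(p = strrep("A", 60), q = strrep("G", 60)))
  expect_error(distanceMatrix(sat, model = "K2P"), class = "undefinedPairError")
  expect_error(distanceMatrix(sat, model = "K2P"), "p/q")
})

test_that("amino-acid p-distance counts differences over unambiguous columns", {
  aa <- AAStringSet(c(u = "MKLVINTREQW", v = "MKLVINTREQW", w = "MKLVINSREQW"))
  dm <- distanceMatrix(aa, model = "amino_p")
  expect_equal(distValue(dm)["u", "v"], 0)
  expect_equal(distValue(dm)["u", "w"], 1 / 11)
})
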