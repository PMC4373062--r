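test_that("NJ resolves the classic additive four-taxon matrix exactly", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(labs, labs))
  tree <- neighborJoining(D)
  # path distances reproduce the input exactly (topology AB|CD, lengths
  # 1, 2, 3, 4 with internal edge 1)
  expect_equal(ape::cophenetic.phylo(tree)[labs, labs], D, tolerance = 1e-9)
  expect_equal(sort(tree$edge.length), c(1, 1, 2, 3, 4), tolerance = 1e-9)
  expect_length(attr(tree, "clamped"), 0L)
})

test_that("three taxa get the closed-form star resolution", {
  labs <- c("x", "y", "z")
  D <- matrix(c(0, 0.2, 0.3,
                0.2, 0, 0.5,
                0.3, 0.5, 0), 3, 3, dimnames = list(labs, labs))
  tree <- neighborJoining(D)
  expect_equal(ape::cophenetic.phylo(tree)[labs, labs], D, tolerance = 1e-9)
  expect_equal(tree$Nnode, 1L)
  expect_error(neighborJoining(D[1:2, 1:2]), class = "paramError")
  Dbad <- D; Dbad[1, 2] <- Dbad[2, 1] <- Inf
  expect_error(neighborJoining(Dbad), class = "nonFiniteError")
})

test_that("NJ recovers random additive trees exactly up to 8 taxa", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    t0 <- ape::rtree(n, rooted = FALSE)
    t0$edge.length <- runif(length(t0$edge.length), 0.05, 1)
    D <- ape::cophenetic.phylo(t0)
    t1 <- neighborJoining(D)
    expect_equal(ape::cophenetic.phylo(t1)[rownames(D), colnames(D)], D,
                 tolerance = 1e-7)
  }
})

test_that("NJ agrees topologically with the reference implementation off additivity", {
  set.seed(202)
  for (i in 1:5) {
    n <- 7
    D <- matrix(0, n, n)
    D[upper.tri(D)] <- runif(n * (n - 1) / 2, 0.1, 1)
    D <- D + t(D)
    rownames(D) <- colnames(D) <- letters[1:n]
    mine <- neighborJoining(D)
    ref <- ape::nj(D)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("lineage cutting is single-linkage with first-member labelling", {
  labs <- paste0("s", 1:6)
  D <- matrix(0.4, 6, 6, dimnames = list(labs, labs))
  diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.05
  D[3, 4] <- D[4, 3] <- 0.05
  D[5, 6] <- D[6, 5] <- 0.05
  part <- cutLineages(D, 0.15)
  expect_equal(unname(membership(part)), c(1, 1, 2, 2, 3, 3))
  expect_gt(part@minInter, 0.15)

  # all-zero distances collapse to one lineage
  Z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(unique(membership(cutLineages(Z)))), 1L)

  # a chain of small steps links otherwise-distant members
  C <- matrix(0.4, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(C) <- 0
  C[1, 2] <- C[2, 1] <- 0.10
  C[2, 3] <- C[3, 2] <- 0.10
  expect_equal(length(unique(membership(cutLineages(C, 0.15)))), 1L)

  # permuting the input permutes labels but not the partition structure
  perm <- c(5, 3, 1, 6, 2, 4)
  p2 <- cutLineages(D[perm, perm], 0.15)
  agree <- outer(membership(part), membership(part), "==")
  agree2 <- outer(membership(p2)[labs], membership(p2)[labs], "==")
  expect_equal(unname(agree), unname(agree2))
})

test_that("block trimming keeps conserved blocks and removes divergent cores", {
  consCol <- function(ch, n = 8) rep(ch, n)
  nonconsCol <- function(n = 8) rep(c("A", "C", "G", "T"), length.out = n)
  mkAlnMat <- function(cols) do.call(cbind, cols)

  # perfectly conserved alignment survives whole
  m0 <- mkAlnMat(rep(list(consCol("A")), 50))
  t0 <- trimBlocks(m0)
  expect_equal(sum(IRanges::width(keptColumns(t0))), 50L)
  expect_length(keptColumns(t0), 1L)

  # a 12-column divergent core between conserved flanks is removed at
  # maxContigNonconserved = 10
  m1 <- mkAlnMat(c(rep(list(consCol("A")), 10), rep(list(nonconsCol()), 12),
                   rep(list(consCol("G")), 10)))
  t1 <- trimBlocks(m1, maxContigNonconserved = 10)
  kept <- keptColumns(t1)
  expect_equal(IRanges::start(kept), c(1L, 23L))
  expect_equal(IRanges::end(kept), c(10L, 32L))

  # a conserved island shorter than minBlock is dropped
  m2 <- mkAlnMat(c(rep(list(consCol("A")), 4), rep(list(nonconsCol()), 12),
                   rep(list(consCol("G")), 10)))
  t2 <- trimBlocks(m2, maxContigNonconserved = 10, minBlock = 5)
  expect_equal(IRanges::start(keptColumns(t2)), 17L)   # 4-col island dropped

  # columns where half the sequences gap out are always excluded
  gapCol <- c(rep("-", 4), rep("A", 4))
  m3 <- mkAlnMat(c(rep(list(consCol("A")), 6), list(gapCol),
                   rep(list(consCol("G")), 6)))
  t3 <- trimBlocks(m3)
  expect_false(7L %in% unlist(lapply(seq_along(keptColumns(t3)), function(i)
    seq(IRanges::start(keptColumns(t3))[i], IRanges::end(keptColumns(t3))[i]))))

  # re-trimming a trimmed alignment is a no-op
  re <- trimBlocks(trimmedSequences(t1), maxContigNonconserved = 10)
  expect_equal(sum(IRanges::width(keptColumns(re))),
               sum(IRanges::width(keptColumns(t1))))
  expect_length(keptColumns(re), 1L)

  expect_error(trimBlocks(c("ACGT", "ACG")), class = "raggedAlignmentError")
})

test_that("hit curation applies the stated thresholds and is idempotent", {
  hits <- data.frame(
    query_id = "q",
    subject_id = paste0("h", 1:6),
    identity = c(25, 28, 97, 97, 80, 60),   # h1, h2 fail identity
    coverage = c(90, 95, 92, 91, 88, 85),
    e_value = c(1e-20, 1e-10, 1e-50, 1e-40, 0.1, 1e-5),  # h5 fails e-value
    species = c("F", "F", "T", "T", "T", "L"))
  out <- hitFilter(hits)
  # h3/h4 are same-species near-duplicates at 97%: lowest e-value survives
  expect_equal(nrow(out), 2L)
  expect_setequal(out$subject_id, c("h3", "h6"))
  expect_identical(hitFilter(out), out)
  expect_identical(hitFilter(hits[0, ]), hits[0, ])
})
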