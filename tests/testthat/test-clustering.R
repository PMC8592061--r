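test_that("pairwise Euclidean distances match brute force", {
  expect_equal(as.vector(pairwiseEuclidean(rbind(c(0, 0), c(3, 4)))), 5)
  expect_equal(as.vector(pairwiseEuclidean(rbind(1:3, 1:3)))[1], 0)

  set.seed(2)
  m <- matrix(rnorm(5 * 7), 5)
  D <- as.matrix(pairwiseEuclidean(m))
  for (i in 1:5) for (j in 1:5)
    expect_equal(D[i, j], sqrt(sum((m[i, ] - m[j, ])^2)), tolerance = 1e-12)

  expect_error(pairwiseEuclidean(rbind(c(1, NA), c(0, 0))),
               class = "invalidDataError")
})

test_that("average-linkage dendrogram follows the UPGMA update", {
  # 1-D points {0, 1, 5}: first merge {0,1} at 1, then at (5+4)/2 = 4.5
  tree <- buildDendrogram(pairwiseEuclidean(matrix(c(0, 1, 5))))
  expect_equal(tree$height, c(1, 4.5))

  # N = 2: a single merge at the pair distance
  t2 <- buildDendrogram(pairwiseEuclidean(matrix(c(2, 7))))
  expect_equal(t2$height, 5)

  # duplicates: first merge at height 0
  t3 <- buildDendrogram(pairwiseEuclidean(matrix(c(3, 3, 9))))
  expect_equal(t3$height[1], 0)

  # monotone merge heights on random data
  set.seed(5)
  t4 <- buildDendrogram(pairwiseEuclidean(matrix(rnorm(40 * 6), 40)))
  expect_true(!is.unsorted(t4$height))
})

test_that("cutting at a height applies merges inclusively", {
  tree <- buildDendrogram(pairwiseEuclidean(matrix(c(0, 1, 5))))
  expect_equal(cutAtHeight(tree, 5), rep(1L, 3))       # h >= root: K = 1
  expect_equal(cutAtHeight(tree, 0.5), 1:3)            # h < min height: K = N
  expect_equal(cutAtHeight(tree, 2), c(1L, 1L, 2L))    # {{0,1},{5}}
  expect_equal(cutAtHeight(tree, 1), c(1L, 1L, 2L))    # inclusive at ties

  # nesting: lowering the cut refines the partition
  set.seed(6)
  m <- matrix(rnorm(25 * 4), 25)
  tr <- buildDendrogram(pairwiseEuclidean(m))
  hs <- sort(c(tr$height, max(tr$height) * 1.1), decreasing = TRUE)
  prevK <- 0L
  prev <- NULL
  for (h in hs) {
    labs <- cutAtHeight(tr, h)
    K <- max(labs)
    expect_gte(K, prevK)
    if (!is.null(prev)) {
      # every current block lies inside one previous block
      agree <- tapply(prev, labs, function(v) length(unique(v)))
      expect_true(all(agree == 1L))
    }
    prev <- labs; prevK <- K
  }
})

test_that("variation decomposition reproduces the worked example", {
  Z <- matrix(c(0, 1, 4, 5))
  d <- variationDecomposition(Z, c(1, 1, 2, 2))
  expect_equal(d$B, 8)
  expect_equal(d$W, 1)

  expect_equal(variationDecomposition(Z, rep(1, 4))$B, 0)   # K = 1
  expect_equal(variationDecomposition(Z, 1:4)$W, 0)         # singletons
  expect_error(variationDecomposition(Z, c(1, 1, 3, 3)),
               class = "invalidLabelsError")
})

test_that("CH index matches the explicit-loop oracle", {
  Z <- matrix(c(0, 1, 4, 5))
  expect_equal(calinskiHarabasz(Z, c(1, 1, 2, 2), variant = "printed"), 16)
  # size-weighted form doubles B here (n_k = 2 per cluster)
  expect_equal(calinskiHarabasz(Z, c(1, 1, 2, 2), variant = "weighted"), 32)
  expect_error(calinskiHarabasz(Z, rep(1, 4)), class = "undefinedIndexError")
  expect_error(calinskiHarabasz(Z, 1:4), class = "undefinedIndexError")

  # perfect separation: W = 0 with K < N
  Zp <- matrix(c(0, 0, 7, 7))
  expect_identical(calinskiHarabasz(Zp, c(1, 1, 2, 2)), Inf)

  set.seed(10)
  for (r in 1:50) {
    n <- sample(5:30, 1)
    p <- sample(2:6, 1)
    K <- sample(2:(n - 1), 1)
    Zr <- matrix(rnorm(n * p), n)
    labs <- as.integer(randomPartition(n, K)@blocks |>
                         (\(b) {v <- integer(n); for (i in seq_along(b)) v[b[[i]]] <- i; v})())
    for (variant in c("printed", "weighted")) {
      o <- chOracle(Zr, labs, variant)
      got <- calinskiHarabasz(Zr, labs, variant)
      expect_lt(abs(got - o$CH) / abs(o$CH), 1e-9)
    }
  }
})

test_that("the CH cut search recovers the hand example and degenerate cases", {
  Z <- matrix(c(0, 1, 4, 5))
  tree <- buildDendrogram(pairwiseEuclidean(Z))
  sol <- optimizeCut(tree, Z)
  expect_equal(clusterCount(sol), 2L)
  expect_equal(clusterLabels(sol), c(1L, 1L, 2L, 2L))
  # exhaustive check: no dendrogram cut has a larger CH
  chAll <- vapply(tree$height[tree$height < max(tree$height)] + 1e-9,
                  function(h) {
                    labs <- cutAtHeight(tree, h)
                    K <- max(labs)
                    if (K < 2 || K > 3) -Inf else calinskiHarabasz(Z, labs)
                  }, 1)
  expect_gte(chValue(sol), max(chAll))

  # identical rows: no stable solution
  Zc <- matrix(1, 5, 3)
  treeC <- buildDendrogram(pairwiseEuclidean(Zc))
  expect_error(optimizeCut(treeC, Zc), class = "unstableSolutionError")
})

test_that("the search trace is internally consistent", {
  set.seed(11)
  m <- matrix(rnorm(30 * 8), 30)
  tree <- buildDendrogram(pairwiseEuclidean(m))
  sol <- optimizeCut(tree, m)
  tr <- searchTrace(sol)
  expect_true(all(diff(tr$height) < 0))
  expect_true(all(tr$K >= 2 & tr$K <= 29))
  expect_gte(min(tr$height), mean(tree$height) * 0.99)
  # chValue equals CH recomputed from (Z, labels)
  expect_equal(chValue(sol),
               calinskiHarabasz(m, clusterLabels(sol)), tolerance = 1e-9)
  # the reported optimum is the trace maximum, tie broken to larger height
  expect_equal(chValue(sol), max(tr$CH))
  expect_equal(cutHeight(sol), max(tr$height[tr$CH == max(tr$CH)]))
})

test_that("cut optimization is invariant to row order up to renumbering", {
  set.seed(12)
  gt <- makeGroundTruth(c(8, 6, 6), 3, "longitudinal")
  ser <- makeSeriesCohort(gt, M = 2, nT = 40, snr = 5, seed = 77)
  Z <- concatenateSubjects(lapply(ser, standardizeSeries))
  m <- groupMatrix(Z)
  sol <- optimizeCut(buildDendrogram(pairwiseEuclidean(m)), m)
  perm <- sample(nrow(m))
  mp <- m[perm, ]
  solP <- optimizeCut(buildDendrogram(pairwiseEuclidean(mp)), mp)
  expect_equal(clusterCount(solP), clusterCount(sol))
  # same partition after undoing the permutation
  back <- integer(nrow(m)); back[perm] <- clusterLabels(solP)
  expect_equal(similarityIndex(asPartition(back),
                               asPartition(clusterLabels(sol))), 1)
})

test_that("a well-separated synthetic cohort is recovered exactly", {
  gt <- makeGroundTruth(c(8, 6, 6), 3, "longitudinal")
  ser <- makeSeriesCohort(gt, M = 3, nT = 100, snr = 50, seed = 123)
  sol <- groupSolve(ser)
  expect_equal(clusterCount(sol), 3L)
  truth <- match(truthLabelVector(gt), unique(truthLabelVector(gt)))
  expect_equal(similarityIndex(asPartition(clusterLabels(sol)),
                               asPartition(truth)), 1)
})
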