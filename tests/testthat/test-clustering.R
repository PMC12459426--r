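# 5-point distance matrix with blocks {a,b} and {c,d,e}; the UPGMA merge
# sequence was traced by hand:
#   (a,b) at 0.2; (c,d) at 0.3; ((c,d),e) at (0.4+0.5)/2 = 0.45;
#   final merge at mean of all 6 cross-block distances
#   (1.4+1.5+1.3+1.4+1.6+1.5)/6 = 1.45.
fivePointMatrix <- function() {
  d <- matrix(c(
    0.0, 0.2, 1.4, 1.5, 1.6,
    0.2, 0.0, 1.3, 1.4, 1.5,
    1.4, 1.3, 0.0, 0.3, 0.4,
    1.5, 1.4, 0.3, 0.0, 0.5,
    1.6, 1.5, 0.4, 0.5, 0.0), 5, 5, byrow = TRUE)
  dimnames(d) <- list(letters[1:5], letters[1:5])
  d
}

test_that("UPGMA reproduces a hand-executed merge trace", {
  res <- upgmaCluster(fivePointMatrix(), k = 2)
  expect_equal(res$tree$height, c(0.2, 0.3, 0.45, 1.45))
  lab <- res$labels
  expect_equal(lab[["a"]], lab[["b"]])
  expect_equal(lab[["c"]], lab[["d"]])
  expect_equal(lab[["d"]], lab[["e"]])
  expect_true(lab[["a"]] != lab[["c"]])
})

test_that("UPGMA handles the trivial cuts and bad input", {
  d <- fivePointMatrix()
  expect_equal(sort(unique(upgmaCluster(d, k = 5)$labels)), 1:5)
  expect_equal(unique(upgmaCluster(d, k = 1)$labels), 1L)
  expect_error(upgmaCluster(d, k = 6), "k must lie")
  dn <- d; dn[1, 2] <- NA
  expect_error(upgmaCluster(dn, k = 2), "NA")
  ds <- d; ds[1, 2] <- 9
  expect_error(upgmaCluster(ds, k = 2), "symmetric")
})

test_that("UPGMA merge heights are non-decreasing on random matrices", {
  set.seed(12)
  for (i in 1:10) {
    x <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(paste0("t", 1:12), NULL))
    d <- cosineDistanceMatrix(x)
    res <- upgmaCluster(d, k = 3)
    expect_true(all(diff(res$tree$height) >= -1e-12))
  }
})

# Three well-separated Gaussian blobs in 5 dimensions.
blobMatrix <- function(nPer = 12, seed = 21) {
  set.seed(seed)
  centers <- rbind(c(8, 0, 0, 0, 0), c(0, 8, 0, 0, 0), c(0, 0, 8, 0, 0))
  x <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(nPer * 5, sd = 0.4), nPer, 5), 2, centers[i, ], "+")))
  rownames(x) <- sprintf("p%02d", seq_len(nrow(x)))
  attr(x, "labels") <- rep(1:3, each = nPer)
  x
}

test_that("diagnostics favor the true number of blobs", {
  x <- blobMatrix()
  diag3 <- clusterNumberDiagnostics(x, kRange = 2:6, B = 20, seed = 3)
  expect_equal(diag3$k, 2:6)
  expect_equal(diag3$k[which.max(diag3$silhouette)], 3L)
  expect_equal(diag3$k[which.max(diag3$calinski_harabasz)], 3L)
  expect_true(all(is.finite(diag3$gap)))

  diag3b <- clusterNumberDiagnostics(x, kRange = 2:6, B = 20, seed = 3)
  expect_identical(diag3, diag3b)  # seeded gap references

  expect_error(clusterNumberDiagnostics(x, kRange = c(1, 3)), "kRange")
  same <- matrix(1, 10, 3, dimnames = list(paste0("t", 1:10), NULL))
  expect_error(clusterNumberDiagnostics(same, kRange = 2:3), "degenerate")
})

test_that("unanimous methods give 0/1 consensus frequencies", {
  x <- blobMatrix(nPer = 8)
  truth <- attr(x, "labels")
  cons <- consensusCluster(x, k = 3,
                           methods = c("single", "complete", "kmeans",
                                       "gmm"),
                           seed = 5)
  expect_setequal(cons@methods,
                  c("single", "complete", "kmeans", "gmm"))
  cm <- consensusMatrix(cons)
  co <- outer(truth, truth, "==")
  expect_true(all(cm[co] == 1))
  expect_true(all(cm[!co] == 0))
  expect_true(all(consensusScores(cons) == 1))
})

test_that("a single method yields its own 0/1 co-membership matrix", {
  x <- blobMatrix(nPer = 6)
  cons <- consensusCluster(x, k = 3, methods = "upgma", seed = 2)
  lab <- cons@assignments[["upgma"]]
  cm <- consensusMatrix(cons)
  expect_equal(cm, outer(lab, lab, "==") * 1, ignore_attr = TRUE)
  expect_true(all(cm %in% c(0, 1)))
})

test_that("a 2-of-4-method flip produces exactly 0.5 frequencies", {
  terms <- c("t1", "t2", "t3", "t4", "t5")
  g1 <- setNames(c(1L, 1L, 1L, 2L, 2L), terms)   # t3 with group A
  g2 <- setNames(c(1L, 1L, 2L, 2L, 2L), terms)   # t3 with group B
  cons <- consensusFromAssignments(
    list(m1 = g1, m2 = g1, m3 = g2, m4 = g2), assignment = g1)
  cm <- consensusMatrix(cons)
  expect_equal(cm["t3", "t1"], 0.5)
  expect_equal(cm["t3", "t2"], 0.5)
  expect_equal(cm["t3", "t4"], 0.5)
  expect_equal(cm["t3", "t5"], 0.5)
  expect_equal(cm["t1", "t2"], 1)
  expect_equal(cm["t4", "t5"], 1)
  expect_equal(cm["t1", "t4"], 0)
  # hand-enumerated score: t3 sits with t1,t2 in the reference, each at 0.5
  expect_equal(consensusScores(cons)[["t3"]], 0.5)
})

test_that("consensus frequencies are invariant to label permutation", {
  terms <- paste0("t", 1:6)
  a <- setNames(c(1L, 1L, 2L, 2L, 3L, 3L), terms)
  aPerm <- setNames(c(3L, 3L, 1L, 1L, 2L, 2L), terms)  # relabeled clusters
  b <- setNames(c(1L, 2L, 2L, 1L, 3L, 3L), terms)
  c1 <- consensusFromAssignments(list(x = a, y = b))
  c2 <- consensusFromAssignments(list(x = aPerm, y = b))
  expect_equal(consensusMatrix(c1), consensusMatrix(c2))
})

test_that("planted communities receive higher within than cross consensus", {
  fx <- plantedFixture()
  lab <- fx$labels[vocabulary(fx$embedding)$token]
  cons <- consensusCluster(fx$embedding, k = 3, seed = 8)
  cm <- consensusMatrix(cons)
  same <- outer(lab, lab, "==") & upper.tri(cm)
  cross <- (!outer(lab, lab, "==")) & upper.tri(cm)
  expect_gt(mean(cm[same]), mean(cm[cross]))
})

test_that("cluster exports produce TSV and Newick", {
  d <- fivePointMatrix()
  res <- upgmaCluster(d, k = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeClusterAssignments(res, path)
  tab <- read.delim(path)
  expect_equal(tab$term, letters[1:5])
  npath <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(res, npath)
  phy <- ape::read.tree(npath)
  expect_setequal(phy$tip.label, letters[1:5])
})

test_that("rarer terms earn lower consensus scores on graded communities", {
  # frequency-graded cohort: community 1 common and tight, community 3
  # rare and weakly bound, so its cluster membership should be shakier
  spec <- exampleCohortSpec(nIndividuals = 800, seed = 303L)
  prof <- spec@ageProfiles
  comm <- attr(spec, "communityLabels")
  prof[names(comm)[comm == 1], ] <- prof[names(comm)[comm == 1], ] * 3
  prof[names(comm)[comm == 3], ] <- prof[names(comm)[comm == 3], ] * 0.2
  spec@ageProfiles <- prof
  spec@communities[[3]]$boost <- 3
  ev <- generateCohort(spec)
  corp <- buildSentences(ev, minCount = 5, seed = 9)
  emb <- trainEmbeddings(corp, dim = 10, window = 100, epochs = 1, seed = 9)
  cons <- consensusCluster(emb, k = 3, seed = 9)
  v <- vocabulary(emb)
  sc <- consensusScores(cons)[v$token]
  # asserted as a rank-correlation sign, not a magnitude
  expect_gt(cor(v$count, sc, method = "spearman"), 0)
  byComm <- tapply(sc, comm[v$token], mean)
  expect_lt(byComm[["3"]], byComm[["1"]])
})
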