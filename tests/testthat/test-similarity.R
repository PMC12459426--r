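test_that("cosine similarity follows its algebraic definition", {
  expect_equal(cosineSimilarity(c(3, -1, 2), c(3, -1, 2)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  # independent elementwise computation: dot / (|a||b|)
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  expect_equal(cosineSimilarity(a, b),
               (1 * 4 + 2 * 5 + 3 * 6) /
                 (sqrt(1 + 4 + 9) * sqrt(16 + 25 + 36)))
  expect_equal(cosineSimilarity(c(1, 1), c(-1, -1)), -1)
})

test_that("cosine similarity rejects undefined inputs", {
  expect_error(cosineSimilarity(c(0, 0), c(1, 2)), "zero-norm")
  expect_error(cosineSimilarity(c(1, 2), c(1, 2, 3)), "equal dimension")
})

test_that("cosine similarity is symmetric and scale-invariant", {
  set.seed(5)
  for (i in 1:25) {
    a <- rnorm(6); b <- rnorm(6); alpha <- runif(1, 0.1, 10)
    expect_equal(cosineSimilarity(a, b), cosineSimilarity(b, a))
    expect_equal(cosineSimilarity(alpha * a, b), cosineSimilarity(a, b))
  }
})

test_that("distance matrix is 1 - similarity with metric-like structure", {
  set.seed(6)
  m <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("t", 1:8), NULL))
  d <- cosineDistanceMatrix(m)
  s <- cosineSimilarityMatrix(m)
  expect_equal(d, 1 - s, ignore_attr = TRUE)
  expect_equal(unname(diag(d)), rep(0, 8))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("knn equals a brute-force all-pairs sort", {
  set.seed(7)
  for (rep in 1:20) {
    m <- matrix(rnorm(20 * 6), 20, 6,
                dimnames = list(sprintf("w%02d", 1:20), NULL))
    emb <- toyEmbedding(m)
    q <- sample(rownames(m), 1)
    k <- sample(1:19, 1)
    got <- nearestNeighbors(emb, q, k = k)
    # oracle: loop over all other terms, sort by similarity
    others <- setdiff(rownames(m), q)
    sims <- vapply(others, function(w) bruteCosine(m[q, ], m[w, ]),
                   numeric(1))
    want <- others[order(-sims)][seq_len(k)]
    expect_equal(got$neighbor, want)
    expect_equal(got$similarity, unname(sort(sims, decreasing = TRUE)[1:k]),
                 tolerance = 1e-12)
    expect_false(q %in% got$neighbor)
    expect_true(all(diff(got$similarity) <= 0))
  }
})

test_that("knn breaks ties by vocabulary index", {
  m <- rbind(q = c(1, 0), a = c(1, 1), b = c(1, 1), c = c(0, 1))
  emb <- toyEmbedding(m)
  nn <- nearestNeighbors(emb, "q", k = 3)
  expect_equal(nn$neighbor, c("a", "b", "c"))  # a before b: lower index
})

test_that("knn respects system restriction and validates the query", {
  m <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(c("d1", "d2", "m1", "m2", "a1"), NULL))
  emb <- toyEmbedding(m, systems = c("diagnosis", "diagnosis",
                                     "medication", "medication",
                                     "adversity"))
  nn <- nearestNeighbors(emb, "d1", k = 4, restrictTo = "medication")
  expect_setequal(nn$neighbor, c("m1", "m2"))
  expect_error(nearestNeighbors(emb, "zz", k = 1), "not in vocabulary")
  expect_error(nearestNeighbors(emb, "d1", k = 0), "k must be")
})

test_that("query term resolution expands prefixes and reports misses", {
  vocab <- data.frame(
    token = c("F510", "F515", "G473", "N05CH"),
    index = 0:3, count = 50L,
    system = c("diagnosis", "diagnosis", "diagnosis", "medication"),
    stringsAsFactors = FALSE
  )
  expect_warning(res <- resolveQueryTerms(vocab), "R06AD")
  expect_setequal(res$token[res$label == "nonorganic sleep disorders"],
                  c("F510", "F515"))
  expect_equal(res$token[res$label == "organic sleep disorders"], "G473")
  # melatonin (N05CH01) truncates onto the N05CH token
  expect_true("melatonin" %in% res$label)
  expect_true("N05CF" %in% attr(res, "missing"))
})

test_that("closest adversities maximize similarity to sleep terms", {
  # hand-built geometry: advA aligned with sleep1, advB orthogonal,
  # advC anti-aligned
  m <- rbind(
    sleep1 = c(1, 0, 0),
    sleep2 = c(0, 1, 0),
    advA = c(0.9, 0.1, 0),
    advB = c(0, 0, 1),
    advC = c(-1, -0.2, 0)
  )
  emb <- toyEmbedding(m, systems = c("diagnosis", "diagnosis",
                                     "adversity", "adversity", "adversity"))
  got <- closestAdversities(emb, sleepTokens = c("sleep1", "sleep2"), m = 2)
  # oracle: brute-force max over sleep terms
  best <- sort(vapply(c("advA", "advB", "advC"), function(a)
    max(bruteCosine(m[a, ], m["sleep1", ]),
        bruteCosine(m[a, ], m["sleep2", ])), numeric(1)),
    decreasing = TRUE)
  expect_equal(got$adversity, names(best)[1:2])
  expect_equal(got$similarity, unname(best[1:2]), tolerance = 1e-12)
  expect_equal(got$sleep_term[1], "sleep1")

  one <- closestAdversities(emb, "sleep1", adversityTokens = "advB", m = 1)
  expect_equal(one$adversity, "advB")
  expect_error(closestAdversities(emb, "sleep1", m = 4), "fewer than m")
})

test_that("mean aggregation is available as an alternative", {
  m <- rbind(s1 = c(1, 0), s2 = c(0, 1),
             a1 = c(1, 0.05), a2 = c(0.6, 0.6))
  emb <- toyEmbedding(m, systems = c("diagnosis", "diagnosis",
                                     "adversity", "adversity"))
  byMax <- closestAdversities(emb, c("s1", "s2"), m = 1)
  byMean <- closestAdversities(emb, c("s1", "s2"), m = 1,
                               aggregate = "mean")
  expect_equal(byMax$adversity, "a1")   # best single match
  expect_equal(byMean$adversity, "a2")  # best on average
})
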