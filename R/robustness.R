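# Spearman correlation of the vectorized upper triangles of two distance
# matrices over a common term set.
upperTriSpearman <- function(d1, d2, terms) {
  ut <- upper.tri(d1[terms, terms])
  stats::cor(d1[terms, terms][ut], d2[terms, terms][ut],
             method = "spearman")
}

#' Embedding stability under data subsampling
#'
#' Retrains the full sentence-to-embedding pipeline on several person-level
#' subsets of the event table (disjoint by default, bootstrap optionally),
#' each with its own seed, and reports all pairwise Spearman correlations
#' between the runs' cosine distance matrices, computed over the vectorized
#' upper triangle restricted to the vocabulary shared by all runs.
#'
#' @param events event table.
#' @param nRuns number of retrained models, default 5.
#' @param fraction fraction of persons per subset; default \code{1/nRuns}
#'   (the disjoint partition uses all persons). Must satisfy
#'   \code{fraction * nRuns <= 1} when \code{disjoint}.
#' @param disjoint if TRUE (default) subsets are disjoint samples without
#'   replacement; if FALSE, independent bootstrap samples of persons.
#' @param minCount,dim,window,epochs,learningRate pipeline settings passed
#'   to \code{\link{buildSentences}} and \code{\link{trainEmbeddings}}.
#' @param seed master seed; run i uses \code{seed + i} for its shuffle and
#'   training.
#' @return list with \code{correlations} (nRuns x nRuns symmetric matrix,
#'   unit diagonal), \code{sharedVocabulary} (character),
#'   \code{runs} (data.frame of per-run metadata) and \code{range} (min/max
#'   off-diagonal correlation).
#' @export
subsampleStability <- function(events, nRuns = 5L, fraction = 1 / nRuns,
                               disjoint = TRUE, minCount = 20L,
                               dim = 200L, window = 100L, epochs = 25L,
                               learningRate = 0.05, seed = 1L) {
  checkEventTable(events)
  if (nRuns < 2) stop("nRuns must be >= 2")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  persons <- unique(events$person_id)
  nPer <- max(1L, floor(fraction * length(persons)))
  if (disjoint && nPer * nRuns > length(persons))
    stop("disjoint subsets need fraction * nRuns <= 1")

  subsets <- withSeed(seed, {
    if (disjoint) {
      shuffled <- sample(persons)
      lapply(seq_len(nRuns), function(i)
        shuffled[seq_len(nPer) + (i - 1L) * nPer])
    } else {
      lapply(seq_len(nRuns), function(i)
        sample(persons, nPer, replace = TRUE))
    }
  })

  dists <- vector("list", nRuns)
  vocabs <- vector("list", nRuns)
  for (i in seq_len(nRuns)) {
    sub <- events[events$person_id %in% subsets[[i]], , drop = FALSE]
    corp <- buildSentences(sub, minCount = minCount, seed = seed + i)
    emb <- trainEmbeddings(corp, dim = dim, window = window,
                           epochs = epochs, learningRate = learningRate,
                           seed = seed + i)
    vocabs[[i]] <- vocabulary(emb)$token
    dists[[i]] <- cosineDistanceMatrix(emb)
  }
  shared <- Reduce(intersect, vocabs)
  if (length(shared) < 3)
    stop("shared vocabulary across runs has fewer than 3 terms")
  shared <- sort(shared)

  rho <- diag(nRuns)
  for (i in seq_len(nRuns - 1))
    for (j in seq(i + 1, nRuns)) {
      r <- upperTriSpearman(dists[[i]], dists[[j]], shared)
      rho[i, j] <- r; rho[j, i] <- r
    }
  off <- rho[upper.tri(rho)]
  list(
    correlations = rho,
    sharedVocabulary = shared,
    runs = data.frame(
      run = seq_len(nRuns),
      n_persons = nPer,
      seed = seed + seq_len(nRuns),
      vocab_size = lengths(vocabs),
      disjoint = disjoint,
      fraction = fraction
    ),
    range = range(off)
  )
}

#' Agreement between two embedding models
#'
#' Spearman correlation between the cosine distance matrices of two
#' embeddings (e.g. the skip-gram model and the alternative co-occurrence
#' backend), over the vectorized upper triangle restricted to the
#' vocabulary intersection. Invariant to row scaling and vocabulary order.
#'
#' @param embA,embB \code{EventEmbedding} objects with overlapping
#'   vocabularies.
#' @return a single Spearman correlation in [-1, 1].
#' @export
crossModelAgreement <- function(embA, embB) {
  shared <- sort(intersect(vocabulary(embA)$token, vocabulary(embB)$token))
  if (length(shared) < 3)
    stop("vocabulary intersection has fewer than 3 terms")
  upperTriSpearman(cosineDistanceMatrix(embA, shared),
                   cosineDistanceMatrix(embB, shared), shared)
}

#' Write a stability report as JSON or TSV
#'
#' @param report list from \code{\link{subsampleStability}}.
#' @param path output path; extension selects the format (\code{.json} or
#'   anything else for TSV of the correlation matrix).
#' @return \code{path}, invisibly.
#' @export
writeStabilityReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(correlations = report$correlations,
           runs = report$runs,
           shared_vocabulary = report$sharedVocabulary,
           range = report$range),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(report$correlations, path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
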