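#' Train life-course event embeddings (skip-gram, hierarchical softmax)
#'
#' Fits the skip-gram architecture on the life-course sentence corpus: each
#' event token predicts its surrounding tokens within a context window, the
#' output distribution factorized by a Huffman-tree hierarchical softmax.
#' The hidden-layer (input) vectors are returned as the embedding. Training
#' is single-threaded with a dedicated deterministic RNG, so the result is
#' bit-reproducible for a given corpus and seed. The effective window per
#' position is dynamic (uniform on 1..window) and the learning rate decays
#' linearly from \code{learningRate}, as in the reference skip-gram
#' implementation.
#'
#' @param corpus a \code{\linkS4class{LifeCourseCorpus}}.
#' @param dim embedding dimension, default 200.
#' @param window maximum one-sided context window, default 100 (covers most
#'   life-course sentence lengths).
#' @param epochs training epochs, default 25.
#' @param learningRate initial learning rate, default 0.05.
#' @param seed integer seed for initialization and window sampling.
#' @return an \code{\linkS4class{EventEmbedding}}.
#' @export
trainEmbeddings <- function(corpus, dim = 200L, window = 100L,
                            epochs = 25L, learningRate = 0.05,
                            seed = 1L) {
  vocab <- vocabulary(corpus)
  if (nrow(vocab) < 2) stop("vocabulary must contain at least 2 terms")
  if (!length(corpus@tokens) || sum(lengths(corpus@tokens)) == 0)
    stop("corpus is empty")
  idx <- stats::setNames(vocab$index, vocab$token)
  sent <- lapply(corpus@tokens, function(tk) unname(idx[tk]))
  sent <- Filter(length, sent)
  ordv <- order(vocab$index)
  vocab <- vocab[ordv, , drop = FALSE]
  rownames(vocab) <- NULL

  mat <- .skipgram_train(sent, as.numeric(vocab$count),
                         as.integer(dim), as.integer(window),
                         as.integer(epochs), learningRate,
                         as.numeric(seed))
  rownames(mat) <- vocab$token
  new("EventEmbedding",
      vectors = mat,
      vocabulary = vocab,
      config = list(dim = dim, window = window, epochs = epochs,
                    learningRate = learningRate, seed = seed,
                    backend = "skipgram-hs"))
}

#' Train embeddings with an alternative co-occurrence algorithm
#'
#' A second, independent co-occurrence-based embedding of the same
#' vocabulary, used for cross-model robustness checks
#' (\code{\link{crossModelAgreement}}). Tokens are embedded by truncated SVD
#' of the positive pointwise mutual information (PPMI) matrix of
#' within-window co-occurrence counts; rows are scaled by the square root of
#' the singular values. Deterministic (no stochastic optimization).
#'
#' @param corpus a \code{LifeCourseCorpus}.
#' @param dim embedding dimension (capped at vocabulary size - 1).
#' @param window symmetric co-occurrence window, default 100.
#' @param seed kept for interface symmetry; the method is deterministic.
#' @return an \code{EventEmbedding} over the identical vocabulary.
#' @export
trainAlternativeEmbeddings <- function(corpus, dim = 200L, window = 100L,
                                       seed = 1L) {
  vocab <- vocabulary(corpus)
  if (nrow(vocab) < 2) stop("vocabulary must contain at least 2 terms")
  if (!length(corpus@tokens) || sum(lengths(corpus@tokens)) == 0)
    stop("corpus is empty")
  ordv <- order(vocab$index)
  vocab <- vocab[ordv, , drop = FALSE]
  rownames(vocab) <- NULL
  V <- nrow(vocab)
  idx <- stats::setNames(seq_len(V), vocab$token)

  co <- matrix(0, V, V)
  for (tk in corpus@tokens) {
    if (!length(tk)) next
    ii <- unname(idx[tk])
    L <- length(ii)
    if (L >= 2) {
      if (L <= window + 1) {
        # window spans the sentence: all ordered pairs of distinct positions
        tabi <- tabulate(ii, V)
        co <- co + outer(tabi, tabi)
        diag(co) <- diag(co) - tabi  # remove self-position pairs
      } else {
        for (p in seq_len(L)) {
          lo <- max(1L, p - window); hi <- min(L, p + window)
          ctx <- ii[setdiff(lo:hi, p)]
          tabc <- tabulate(ctx, V)
          co[ii[p], ] <- co[ii[p], ] + tabc
        }
      }
    }
  }

  total <- sum(co)
  if (total == 0) stop("no co-occurrence pairs within the window")
  rowp <- rowSums(co) / total
  pij <- co / total
  pmi <- log(pij / outer(rowp, rowp))
  pmi[!is.finite(pmi)] <- 0
  ppmi <- pmax(pmi, 0)

  d <- min(dim, V - 1L)
  sv <- svd(ppmi, nu = d, nv = 0)
  emb <- sv$u %*% diag(sqrt(sv$d[seq_len(d)]), d)
  # fix sign ambiguity: largest-magnitude loading per column is positive
  for (j in seq_len(ncol(emb))) {
    m <- which.max(abs(emb[, j]))
    if (emb[m, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- vocab$token
  new("EventEmbedding",
      vectors = emb,
      vocabulary = vocab,
      config = list(dim = d, window = window, seed = seed,
                    backend = "ppmi-svd"))
}

#' Write/read embeddings in the word2vec text format
#'
#' Header line \code{"<n_terms> <dim>"}, then one line per term:
#' \code{token v1 ... vdim}. \code{writeEmbeddingTSV} writes a tab-separated
#' table with a \code{token} column plus one column per dimension.
#'
#' @param embedding an \code{EventEmbedding}.
#' @param path file path.
#' @return \code{path} (writers, invisibly) or an \code{EventEmbedding}
#'   (reader).
#' @export
writeWord2vecFormat <- function(embedding, path) {
  m <- embeddingVectors(embedding)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  body <- apply(m, 1L, function(v)
    paste(format(v, digits = 17, scientific = TRUE, trim = TRUE),
          collapse = " "))
  writeLines(paste(rownames(m), body), con)
  invisible(path)
}

#' @rdname writeWord2vecFormat
#' @export
readWord2vecFormat <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ")
  tokens <- vapply(parts, `[[`, "", 1L)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(m) <- tokens
  vocab <- data.frame(token = tokens, index = seq_along(tokens) - 1L,
                      count = NA_integer_, system = NA_character_,
                      stringsAsFactors = FALSE)
  new("EventEmbedding", vectors = m, vocabulary = vocab,
      config = list(dim = hdr[2], backend = "file"))
}

#' @rdname writeWord2vecFormat
#' @export
writeEmbeddingTSV <- function(embedding, path) {
  m <- embeddingVectors(embedding)
  df <- data.frame(token = rownames(m), m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df) <- c("token", paste0("d", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
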