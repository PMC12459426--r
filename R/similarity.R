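#' Cosine similarity between two vectors
#'
#' \code{dot(a, b) / (|a| * |b|)}; ranges over [-1, 1] with 1 meaning full
#' similarity. Undefined for zero-norm vectors (an error, never silently 0).
#'
#' @param a,b numeric vectors of equal length.
#' @return a number in [-1, 1].
#' @examples
#' cosineSimilarity(c(1, 2, 3), c(4, 5, 6))
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal dimension")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for zero-norm vectors")
  sum(a * b) / (na * nb)
}

# Row-normalize a matrix to unit L2 norm.
l2normalize <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("zero-norm embedding vector")
  m / nrm
}

#' Pairwise cosine similarity / distance matrices
#'
#' Cosine distance is \code{1 - cosine similarity}: symmetric, zero
#' diagonal, entries in [0, 2].
#'
#' @param embedding an \code{EventEmbedding} or a numeric matrix with row
#'   names.
#' @param terms optional subset of terms (row names) to restrict to.
#' @return square numeric matrix with term dimnames.
#' @export
cosineSimilarityMatrix <- function(embedding, terms = NULL) {
  m <- if (is(embedding, "EventEmbedding")) embeddingVectors(embedding)
       else embedding
  if (!is.null(terms)) {
    miss <- setdiff(terms, rownames(m))
    if (length(miss))
      stop("terms not in vocabulary: ", paste(miss, collapse = ", "))
    m <- m[terms, , drop = FALSE]
  }
  s <- tcrossprod(l2normalize(m))
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

#' @rdname cosineSimilarityMatrix
#' @export
cosineDistanceMatrix <- function(embedding, terms = NULL) {
  d <- 1 - cosineSimilarityMatrix(embedding, terms)
  diag(d) <- 0
  d
}

#' k-nearest neighbors by cosine similarity
#'
#' Top-\code{k} vocabulary terms most similar to the query term, descending,
#' with ties broken by vocabulary index for determinism. The query is never
#' its own neighbor.
#'
#' @param embedding an \code{EventEmbedding}.
#' @param query a vocabulary token.
#' @param k number of neighbors, default 10.
#' @param restrictTo optional character vector of code systems to search
#'   within (default: all systems).
#' @return data.frame with columns \code{query}, \code{rank},
#'   \code{neighbor}, \code{similarity}, \code{system}.
#' @export
nearestNeighbors <- function(embedding, query, k = 10L, restrictTo = NULL) {
  vocab <- vocabulary(embedding)
  if (!query %in% vocab$token)
    stop("query term not in vocabulary: ", query)
  if (k < 1) stop("k must be >= 1")
  m <- embeddingVectors(embedding)
  qv <- m[query, ]
  cand <- vocab[vocab$token != query, , drop = FALSE]
  if (!is.null(restrictTo))
    cand <- cand[cand$system %in% restrictTo, , drop = FALSE]
  if (!nrow(cand)) stop("no candidate terms under the given restriction")
  cm <- m[cand$token, , drop = FALSE]
  qn <- sqrt(sum(qv^2)); cn <- sqrt(rowSums(cm^2))
  if (qn == 0 || any(cn == 0)) stop("zero-norm embedding vector")
  sims <- as.vector(cm %*% qv) / (cn * qn)
  sims <- pmin(1, pmax(-1, sims))
  ord <- order(-sims, cand$index)
  kk <- min(k, nrow(cand))
  sel <- ord[seq_len(kk)]
  data.frame(
    query = query,
    rank = seq_len(kk),
    neighbor = cand$token[sel],
    similarity = sims[sel],
    system = cand$system[sel],
    stringsAsFactors = FALSE
  )
}

#' Packaged sleep-problem query terms
#'
#' The diagnoses and medications used as indicators of sleep problems:
#' nonorganic (F51.x) and organic (G47.x) sleep disorder families,
#' melatonin receptor agonists (N05CH) and melatonin itself (N05CH01),
#' benzodiazepine-related drugs (N05CF), phenothiazine derivatives (R06AD)
#' and promethazine (R06AD02). Family codes (".x") match any token sharing
#' the prefix after truncation.
#'
#' @return data.frame with columns \code{label}, \code{code}, \code{system},
#'   \code{match} (\code{"prefix"} or \code{"exact"}).
#' @export
sleepQueryTerms <- function() {
  data.frame(
    label = c("nonorganic sleep disorders", "organic sleep disorders",
              "melatonin receptor agonists", "melatonin",
              "benzodiazepine-related drugs", "phenothiazine derivatives",
              "promethazine"),
    code = c("F51", "G47", "N05CH", "N05CH01", "N05CF", "R06AD", "R06AD02"),
    system = c("diagnosis", "diagnosis", "medication", "medication",
               "medication", "medication", "medication"),
    match = c("prefix", "prefix", "exact", "exact", "exact", "exact",
              "exact"),
    stringsAsFactors = FALSE
  )
}

#' Resolve query terms against an embedding vocabulary
#'
#' Codes are truncated to token form first; prefix entries expand to every
#' vocabulary token sharing the prefix. Missing terms are reported in the
#' \code{"missing"} attribute (and a warning), never silently dropped.
#'
#' @param embedding an \code{EventEmbedding} (or a vocabulary data.frame).
#' @param queryTerms data.frame as from \code{\link{sleepQueryTerms}}.
#' @return data.frame with columns \code{label}, \code{code}, \code{token},
#'   \code{system}; attribute \code{"missing"} lists unresolved codes.
#' @export
resolveQueryTerms <- function(embedding, queryTerms = sleepQueryTerms()) {
  vocab <- if (is(embedding, "EventEmbedding")) vocabulary(embedding)
           else embedding
  out <- list(); missing <- character()
  for (r in seq_len(nrow(queryTerms))) {
    q <- queryTerms[r, ]
    tokq <- truncateCode(q$code, q$system)
    hits <- if (identical(q$match, "prefix"))
      vocab$token[startsWith(vocab$token, tokq) & vocab$system == q$system]
    else vocab$token[vocab$token == tokq]
    if (!length(hits)) {
      missing <- c(missing, q$code)
    } else {
      out[[length(out) + 1L]] <- data.frame(
        label = q$label, code = q$code, token = hits,
        system = q$system, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(label = character(), code = character(),
                         token = character(), system = character(),
                         stringsAsFactors = FALSE)
  if (length(missing))
    warning("query terms not in vocabulary: ",
            paste(missing, collapse = ", "))
  attr(res, "missing") <- missing
  res
}

#' Childhood adversities closest to sleep-related terms
#'
#' Ranks adversity terms by their association with a set of sleep-related
#' query tokens and returns the top \code{m}. Association is aggregated over
#' sleep terms by \code{max} (default; the best-matching sleep term is
#' reported) or \code{mean}.
#'
#' @param embedding an \code{EventEmbedding}.
#' @param sleepTokens character vector of sleep-related vocabulary tokens.
#' @param adversityTokens adversity tokens to rank; default: every
#'   vocabulary token with system \code{"adversity"}.
#' @param m number of adversities to return, default 3.
#' @param aggregate \code{"max"} or \code{"mean"}.
#' @return data.frame with columns \code{adversity}, \code{sleep_term}
#'   (arg-max sleep term), \code{similarity}, sorted descending.
#' @export
closestAdversities <- function(embedding, sleepTokens,
                               adversityTokens = NULL, m = 3L,
                               aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  vocab <- vocabulary(embedding)
  if (is.null(adversityTokens))
    adversityTokens <- vocab$token[vocab$system == "adversity"]
  if (length(adversityTokens) < m)
    stop("fewer than m adversity terms in the vocabulary")
  miss <- setdiff(c(sleepTokens, adversityTokens), vocab$token)
  if (length(miss))
    stop("terms not in vocabulary: ", paste(miss, collapse = ", "))
  s <- cosineSimilarityMatrix(embedding,
                              c(adversityTokens, sleepTokens))
  block <- s[adversityTokens, sleepTokens, drop = FALSE]
  score <- if (aggregate == "max") apply(block, 1, max)
           else rowMeans(block)
  best <- sleepTokens[apply(block, 1, which.max)]
  ord <- order(-score, adversityTokens)
  sel <- ord[seq_len(m)]
  data.frame(
    adversity = adversityTokens[sel],
    sleep_term = best[sel],
    similarity = unname(score[sel]),
    stringsAsFactors = FALSE
  )
}
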