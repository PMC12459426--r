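#' UPGMA hierarchical clustering on a cosine distance matrix
#'
#' Agglomerative clustering with average linkage (unweighted pair group
#' method with arithmetic mean) on a symmetric distance matrix, cut into
#' \code{k} flat clusters.
#'
#' @param distance symmetric numeric matrix of cosine distances (zero
#'   diagonal, no NAs) with term dimnames, as from
#'   \code{\link{cosineDistanceMatrix}}.
#' @param k number of clusters, 1 <= k <= n.
#' @return list with elements \code{labels} (named integer vector of cluster
#'   labels 1..k), \code{tree} (the \code{hclust} object) and \code{k}.
#' @export
upgmaCluster <- function(distance, k) {
  if (!is.matrix(distance) || nrow(distance) != ncol(distance))
    stop("distance must be a square matrix")
  if (anyNA(distance)) stop("distance matrix contains NA")
  if (!isTRUE(all.equal(distance, t(distance), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  n <- nrow(distance)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  tree <- stats::hclust(stats::as.dist(distance), method = "average")
  labels <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree, k = k)
}

# Calinski-Harabasz index: between-cluster over within-cluster dispersion,
# scaled by degrees of freedom.
calinskiHarabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  if (k < 2 || k >= n) return(NA_real_)
  centroid <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (cl in unique(labels)) {
    xi <- x[labels == cl, , drop = FALSE]
    ci <- colMeans(xi)
    ssb <- ssb + nrow(xi) * sum((ci - centroid)^2)
    ssw <- ssw + sum(sweep(xi, 2, ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Cluster-number diagnostics
#'
#' Computes, for each candidate number of clusters k, the Calinski-Harabasz
#' index, the mean silhouette width and the gap statistic, using K-means on
#' L2-normalized embedding vectors (so Euclidean geometry approximates
#' cosine geometry). The gap statistic draws \code{B} reference datasets
#' uniformly within the bounding box of the data.
#'
#' @param embedding an \code{EventEmbedding} or numeric matrix.
#' @param kRange integer vector of candidate k, within [2, n-1].
#' @param B number of gap-statistic reference datasets, default 50.
#' @param seed integer seed (K-means restarts and gap references).
#' @param nstart K-means random restarts, default 10.
#' @return data.frame with columns \code{k}, \code{calinski_harabasz},
#'   \code{silhouette}, \code{gap}, \code{gap_se}.
#' @export
clusterNumberDiagnostics <- function(embedding, kRange, B = 50L,
                                     seed = 1L, nstart = 10L) {
  m <- if (is(embedding, "EventEmbedding")) embeddingVectors(embedding)
       else embedding
  x <- l2normalize(m)
  n <- nrow(x)
  if (any(kRange < 2 | kRange > n - 1))
    stop("kRange must lie within [2, n-1]")
  if (all(stats::dist(x) < 1e-12))
    stop("degenerate input: all points identical")
  kRange <- sort(unique(as.integer(kRange)))

  withSeed(seed, {
    dmat <- stats::dist(x)
    rows <- lapply(kRange, function(k) {
      km <- stats::kmeans(x, centers = k, nstart = nstart)
      sil <- cluster::silhouette(km$cluster, dmat)
      data.frame(
        k = k,
        calinski_harabasz = calinskiHarabasz(x, km$cluster),
        silhouette = mean(sil[, "sil_width"])
      )
    })
    gap <- cluster::clusGap(
      x, FUNcluster = function(xx, kk)
        list(cluster = stats::kmeans(xx, kk, nstart = nstart)$cluster),
      K.max = max(kRange), B = B, spaceH0 = "original", verbose = FALSE)
    out <- do.call(rbind, rows)
    out$gap <- gap$Tab[kRange, "gap"]
    out$gap_se <- gap$Tab[kRange, "SE.sim"]
    out
  })
}

# One clustering method -> integer labels; NULL if it cannot deliver k
# non-empty clusters.
runClusterMethod <- function(method, x, distance, k, nstart) {
  labels <- switch(method,
    single = ,
    complete = ,
    upgma = {
      meth <- if (method == "upgma") "average" else method
      tree <- stats::hclust(stats::as.dist(distance), method = meth)
      stats::cutree(tree, k = k)
    },
    kmeans = stats::kmeans(x, centers = k, nstart = nstart)$cluster,
    gmm = {
      # Mclust resolves mclustBIC in the caller's scope
      mclustBIC <- mclust::mclustBIC
      fit <- mclust::Mclust(x, G = k, verbose = FALSE)
      if (is.null(fit)) NULL else fit$classification
    },
    stop("unknown clustering method: ", method)
  )
  if (is.null(labels) || length(unique(labels)) != k) return(NULL)
  stats::setNames(as.integer(labels), rownames(x))
}

#' Consensus clustering across algorithms
#'
#' Runs several clustering algorithms at a common \code{k} — hierarchical
#' clustering with single and complete linkage on the cosine distance
#' matrix, K-means and Gaussian mixture models on the L2-normalized
#' embedding vectors — and records, for every term pair, the fraction of
#' methods that co-assigned them. The per-term consensus score is the mean
#' co-clustering frequency with the other members of the term's reference
#' cluster (by default the UPGMA assignment at the same k); it quantifies
#' how robustly a term sits in its cluster. A method failing to produce k
#' non-empty clusters is excluded with a warning.
#'
#' @param embedding an \code{EventEmbedding} or numeric matrix with row
#'   names.
#' @param k number of clusters, default 5.
#' @param methods subset of \code{c("single", "complete", "kmeans", "gmm",
#'   "upgma")}.
#' @param distance optional precomputed cosine distance matrix.
#' @param assignment optional reference labels for scoring; default UPGMA.
#' @param seed integer seed (K-means restarts).
#' @param nstart K-means restarts, default 10.
#' @return a \code{\linkS4class{ConsensusResult}}.
#' @export
consensusCluster <- function(embedding, k = 5L,
                             methods = c("single", "complete", "kmeans",
                                         "gmm"),
                             distance = NULL, assignment = NULL,
                             seed = 1L, nstart = 10L) {
  if (length(methods) < 1) stop("at least one method required")
  m <- if (is(embedding, "EventEmbedding")) embeddingVectors(embedding)
       else embedding
  x <- l2normalize(m)
  if (is.null(distance)) distance <- cosineDistanceMatrix(m)
  terms <- rownames(x)
  n <- length(terms)

  assignments <- list()
  withSeed(seed, {
    for (meth in methods) {
      lab <- runClusterMethod(meth, x, distance, k, nstart)
      if (is.null(lab)) {
        warning("method '", meth, "' did not produce ", k,
                " clusters; excluded")
      } else {
        assignments[[meth]] <- lab
      }
    }
  })
  if (!length(assignments))
    stop("no clustering method produced ", k, " clusters")

  if (is.null(assignment))
    assignment <- upgmaCluster(distance, k)$labels
  consensusFromAssignments(assignments, assignment)
}

#' Consensus matrix from a list of cluster assignments
#'
#' Lower-level constructor behind \code{\link{consensusCluster}}: given one
#' label vector per method (all over the same terms), computes the
#' co-clustering frequency matrix and per-term consensus scores relative to
#' a reference assignment. Frequencies are invariant to any relabeling of
#' clusters within a method.
#'
#' @param assignments named list of label vectors (names = terms).
#' @param assignment reference labels for scoring; default: the first
#'   method's assignment.
#' @return a \code{\linkS4class{ConsensusResult}}.
#' @export
consensusFromAssignments <- function(assignments, assignment = NULL) {
  if (!length(assignments)) stop("no assignments supplied")
  terms <- names(assignments[[1]])
  if (is.null(terms)) stop("assignments must be named by term")
  for (lab in assignments)
    if (!setequal(names(lab), terms))
      stop("all assignments must cover the same terms")
  if (is.null(assignment)) assignment <- assignments[[1]]
  n <- length(terms)

  cons <- matrix(0, n, n, dimnames = list(terms, terms))
  for (lab in assignments)
    cons <- cons + outer(lab[terms], lab[terms], "==") * 1
  cons <- cons / length(assignments)
  diag(cons) <- 1

  scores <- vapply(terms, function(tm) {
    mates <- setdiff(terms[assignment[terms] == assignment[tm]], tm)
    if (!length(mates)) return(NA_real_)
    mean(cons[tm, mates])
  }, numeric(1))

  methods <- names(assignments)
  if (is.null(methods)) methods <- paste0("method", seq_along(assignments))
  new("ConsensusResult",
      consensus = cons,
      scores = scores,
      assignment = stats::setNames(as.integer(assignment[terms]), terms),
      methods = methods,
      assignments = assignments)
}

#' Export a clustering as TSV / a dendrogram as Newick
#'
#' @param clustering result of \code{\link{upgmaCluster}}.
#' @param consensus optional \code{ConsensusResult} supplying per-term
#'   scores.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClusterAssignments <- function(clustering, path, consensus = NULL) {
  df <- data.frame(term = names(clustering$labels),
                   cluster = unname(clustering$labels),
                   stringsAsFactors = FALSE)
  if (!is.null(consensus))
    df$consensus_score <- unname(consensusScores(consensus)[df$term])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClusterAssignments
#' @export
writeNewick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
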