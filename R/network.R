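#' Build a term neighborhood network
#'
#' Constructs the neighborhood network around a set of seed terms (e.g.
#' sleep-related terms plus their closest childhood adversities): nodes are
#' the seeds and the union of each seed's k cosine nearest neighbors; edges
#' carry the cosine similarity between endpoints. Under the default
#' \code{"knn"} edge rule only seed-to-neighbor edges from the k-NN queries
#' are drawn; under \code{"threshold"} every node pair with similarity at or
#' above \code{threshold} is connected. The graph is undirected with no
#' self-loops, and duplicate pairs are collapsed.
#'
#' @param embedding an \code{EventEmbedding}.
#' @param seedTerms character vector of seed vocabulary tokens.
#' @param k neighbors per seed, default 10.
#' @param edgeRule \code{"knn"} (default) or \code{"threshold"}.
#' @param threshold similarity cutoff for the \code{"threshold"} rule.
#' @param restrictTo optional code systems to search neighbors within.
#' @return a \code{\linkS4class{TermNetwork}}.
#' @export
buildTermNetwork <- function(embedding, seedTerms, k = 10L,
                             edgeRule = c("knn", "threshold"),
                             threshold = 0.5, restrictTo = NULL) {
  edgeRule <- match.arg(edgeRule)
  vocab <- vocabulary(embedding)
  unresolved <- setdiff(seedTerms, vocab$token)
  if (length(unresolved))
    stop("seed terms not in vocabulary: ",
         paste(unresolved, collapse = ", "))

  nn <- do.call(rbind, lapply(seedTerms, function(q)
    nearestNeighbors(embedding, q, k = k, restrictTo = restrictTo)))
  nodes <- unique(c(seedTerms, nn$neighbor))

  if (edgeRule == "knn") {
    edges <- nn[, c("query", "neighbor", "similarity")]
    names(edges) <- c("source", "target", "similarity")
  } else {
    s <- cosineSimilarityMatrix(embedding, nodes)
    pairs <- which(upper.tri(s) & s >= threshold, arr.ind = TRUE)
    edges <- data.frame(
      source = nodes[pairs[, 1]],
      target = nodes[pairs[, 2]],
      similarity = s[pairs],
      stringsAsFactors = FALSE
    )
  }
  # undirected: canonical endpoint order, drop duplicates and self-loops
  if (nrow(edges)) {
    a <- pmin(edges$source, edges$target)
    b <- pmax(edges$source, edges$target)
    edges$source <- a; edges$target <- b
    edges <- edges[a != b, , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$source, edges$target)), ,
                   drop = FALSE]
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }

  tal <- table(c(edges$source, edges$target))
  sysMap <- stats::setNames(vocab$system, vocab$token)
  nodeDf <- data.frame(
    term = nodes,
    system = unname(sysMap[nodes]),
    is_seed = nodes %in% seedTerms,
    degree = as.integer(ifelse(is.na(tal[nodes]), 0L, tal[nodes])),
    stringsAsFactors = FALSE
  )
  rownames(nodeDf) <- NULL
  new("TermNetwork", nodes = nodeDf, edges = edges)
}

#' Rank network terms by degree
#'
#' @param net a \code{TermNetwork}.
#' @return data.frame with columns \code{term}, \code{degree}, sorted by
#'   degree descending, ties by term label.
#' @export
rankCentralTerms <- function(net) {
  nd <- networkNodes(net)
  if (!nrow(nd)) stop("empty network")
  out <- nd[order(-nd$degree, nd$term), c("term", "degree"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strongest edge in a term network
#'
#' The edge with the highest cosine similarity; ties broken by endpoint
#' labels for determinism.
#'
#' @param net a \code{TermNetwork}.
#' @return one-row data.frame with \code{source}, \code{target},
#'   \code{similarity}.
#' @export
strongestEdge <- function(net) {
  e <- networkEdges(net)
  if (!nrow(e)) stop("network has no edges")
  ord <- order(-e$similarity, e$source, e$target)
  out <- e[ord[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert / export a term network
#'
#' \code{asIgraph} returns an igraph object (edge attribute
#' \code{similarity}, node attributes \code{system}, \code{is_seed},
#' \code{degree}); \code{writeGraphML} and \code{writeEdgeList} export to
#' GraphML and a TSV edge list.
#'
#' @param net a \code{TermNetwork}.
#' @param path output path.
#' @return igraph object, or \code{path} invisibly.
#' @export
asIgraph <- function(net) {
  igraph::graph_from_data_frame(networkEdges(net), directed = FALSE,
                                vertices = networkNodes(net))
}

#' @rdname asIgraph
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname asIgraph
#' @export
writeEdgeList <- function(net, path) {
  e <- networkEdges(net)
  names(e) <- c("source", "target", "cosine_similarity")
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
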