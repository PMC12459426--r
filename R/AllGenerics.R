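#' Extract the vocabulary table
#'
#' @param object a \code{LifeCourseCorpus}, \code{EventEmbedding} or other
#'   object carrying a vocabulary.
#' @return data.frame with columns \code{token}, \code{index}, \code{count},
#'   \code{system}.
#' @export
setGeneric("vocabulary", function(object) standardGeneric("vocabulary"))

#' Extract the raw embedding matrix
#'
#' @param object an \code{EventEmbedding}.
#' @return numeric matrix, one row per vocabulary term.
#' @export
setGeneric("embeddingVectors",
           function(object) standardGeneric("embeddingVectors"))

#' Extract sentences as a list of token vectors
#'
#' @param object a \code{LifeCourseCorpus}.
#' @return named list of character vectors, one per person.
#' @export
setGeneric("sentences", function(object) standardGeneric("sentences"))

#' Network node table
#' @param object a \code{TermNetwork}.
#' @return data.frame of nodes with degrees.
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' Network edge list
#' @param object a \code{TermNetwork}.
#' @return data.frame with columns source, target, similarity.
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' Consensus co-clustering matrix
#' @param object a \code{ConsensusResult}.
#' @return symmetric matrix of co-clustering frequencies.
#' @export
setGeneric("consensusMatrix",
           function(object) standardGeneric("consensusMatrix"))

#' Per-term consensus scores
#' @param object a \code{ConsensusResult}.
#' @return named numeric vector.
#' @export
setGeneric("consensusScores",
           function(object) standardGeneric("consensusScores"))

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "LifeCourseCorpus", function(object) object@vocabulary)

#' @rdname vocabulary
#' @export
setMethod("vocabulary", "EventEmbedding", function(object) object@vocabulary)

#' @rdname embeddingVectors
#' @export
setMethod("embeddingVectors", "EventEmbedding", function(object) object@vectors)

#' @rdname sentences
#' @export
setMethod("sentences", "LifeCourseCorpus", function(object) {
  out <- object@tokens
  names(out) <- object@personIds
  out
})

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "TermNetwork", function(object) object@nodes)

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "TermNetwork", function(object) object@edges)

#' @rdname consensusMatrix
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(object) object@consensus)

#' @rdname consensusScores
#' @export
setMethod("consensusScores", "ConsensusResult", function(object) object@scores)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nIndividuals, "individuals, born",
      object@birthYearRange[1], "-", object@birthYearRange[2],
      ", followed to", object@observationEndYear, "\n")
  cat("  vocabulary:", nrow(object@vocabulary), "codes (",
      paste(sprintf("%s: %d", names(table(object@vocabulary$system)),
                    as.integer(table(object@vocabulary$system))),
            collapse = ", "), ")\n")
  cat("  communities:", length(object@communities),
      "| background rate:", object@backgroundRate,
      "| seed:", object@seed, "\n")
})

setMethod("show", "LifeCourseCorpus", function(object) {
  lens <- lengths(object@tokens)
  cat("LifeCourseCorpus:", length(object@tokens), "sentences,",
      sum(lens), "tokens,", nrow(object@vocabulary),
      "vocabulary terms (minCount =", object@minCount, ")\n")
  if (length(lens))
    cat("  sentence length: median", stats::median(lens),
        "max", max(lens), "\n")
})

setMethod("show", "EventEmbedding", function(object) {
  cat("EventEmbedding:", nrow(object@vectors), "terms x",
      ncol(object@vectors), "dimensions",
      sprintf("(backend: %s)\n",
              if (is.null(object@config$backend)) "?"
              else object@config$backend))
})

setMethod("show", "TermNetwork", function(object) {
  cat("TermNetwork:", nrow(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult:", nrow(object@consensus), "terms,",
      length(object@methods), "methods (",
      paste(object@methods, collapse = ", "), ")\n")
  cat("  mean consensus score:", round(mean(object@scores), 3), "\n")
})
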