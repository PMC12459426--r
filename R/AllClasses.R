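#' @import methods
NULL

#' Specification of a synthetic register cohort
#'
#' A \code{CohortSpec} describes a simulated nationwide-register cohort:
#' who is in it (number of individuals, birth-year range, end of follow-up),
#' which event codes exist (the vocabulary, one row per code with its code
#' system and age profile), and which codes form planted co-occurrence
#' communities. The generator draws, per person-year and code, a Poisson
#' number of events with rate \code{backgroundRate * ageProfile weight}, then
#' amplifies within-community co-occurrence by conditional sampling (see
#' \code{\link{generateCohort}}).
#'
#' @slot nIndividuals number of persons in the cohort.
#' @slot birthYearRange integer length-2, inclusive range of birth years.
#' @slot observationEndYear last calendar year of follow-up.
#' @slot vocabulary data.frame with columns \code{code}, \code{system}
#'   (one of \code{"diagnosis"}, \code{"medication"}, \code{"procedure"},
#'   \code{"adversity"}) and \code{adversity_only_before} (age cutoff,
#'   \code{NA} for non-adversity codes).
#' @slot ageProfiles numeric matrix of non-negative relative incidence
#'   weights, one row per vocabulary code (rownames = codes), one column per
#'   5-year age band 0-4 ... 40-44.
#' @slot communities list of lists, each with elements \code{members}
#'   (character, >= 2 vocabulary codes) and \code{boost} (> 1).
#' @slot backgroundRate per-code baseline event rate (events per
#'   person-year at age-profile weight 1); must be >= 0.
#' @slot seed integer seed making generation reproducible.
#'
#' @seealso \code{\link{cohortSpec}}, \code{\link{exampleCohortSpec}}
#' @export
setClass("CohortSpec",
  representation(
    nIndividuals = "numeric",
    birthYearRange = "numeric",
    observationEndYear = "numeric",
    vocabulary = "data.frame",
    ageProfiles = "matrix",
    communities = "list",
    backgroundRate = "numeric",
    seed = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nIndividuals) != 1 || object@nIndividuals < 1)
    msg <- c(msg, "nIndividuals must be a single positive number")
  if (length(object@birthYearRange) != 2 ||
      object@birthYearRange[1] > object@birthYearRange[2])
    msg <- c(msg, "birthYearRange must be an ordered [from, to] pair")
  if (length(object@observationEndYear) != 1 ||
      object@observationEndYear < object@birthYearRange[1])
    msg <- c(msg, "observationEndYear must not precede the first birth year")
  v <- object@vocabulary
  if (nrow(v) == 0) msg <- c(msg, "vocabulary is empty")
  need <- c("code", "system", "adversity_only_before")
  if (!all(need %in% names(v))) {
    msg <- c(msg, sprintf("vocabulary must have columns %s",
                          paste(need, collapse = ", ")))
  } else {
    if (anyDuplicated(v$code)) msg <- c(msg, "duplicate vocabulary codes")
    bad <- setdiff(unique(v$system),
                   c("diagnosis", "medication", "procedure", "adversity"))
    if (length(bad))
      msg <- c(msg, sprintf("unknown code system(s): %s",
                            paste(bad, collapse = ", ")))
    adv <- v$system == "adversity"
    if (any(adv & is.na(v$adversity_only_before)))
      msg <- c(msg, "adversity codes must carry an age cutoff")
    if (!identical(rownames(object@ageProfiles), as.character(v$code)))
      msg <- c(msg, "ageProfiles rownames must equal vocabulary codes")
  }
  if (any(object@ageProfiles < 0) || any(rowSums(object@ageProfiles) <= 0))
    msg <- c(msg, "each age profile must be non-negative with positive sum")
  for (cm in object@communities) {
    if (length(cm$members) < 2)
      msg <- c(msg, "each community needs >= 2 member codes")
    if (is.null(cm$boost) || cm$boost <= 1)
      msg <- c(msg, "community boost must exceed 1")
    if (!is.null(cm$membershipRate) &&
        (cm$membershipRate <= 0 || cm$membershipRate > 1))
      msg <- c(msg, "community membershipRate must lie in (0, 1]")
    if (!all(cm$members %in% v$code))
      msg <- c(msg, "community members must be vocabulary codes")
  }
  if (object@backgroundRate < 0) msg <- c(msg, "backgroundRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Life-course sentence corpus
#'
#' One "sentence" per person: the chronologically ordered sequence of
#' truncated event codes, with ties within a calendar year broken by a
#' seeded random shuffle, and codes rarer than \code{minCount} removed.
#' The vocabulary indexes the retained tokens.
#'
#' @slot personIds character, one id per sentence.
#' @slot tokens list of character vectors (the sentences).
#' @slot years list of integer vectors parallel to \code{tokens}.
#' @slot vocabulary data.frame with columns \code{token}, \code{index}
#'   (contiguous from 0), \code{count} (corpus count, all >= minCount) and
#'   \code{system}.
#' @slot minCount the minimum corpus count applied.
#'
#' @seealso \code{\link{buildSentences}}
#' @export
setClass("LifeCourseCorpus",
  representation(
    personIds = "character",
    tokens = "list",
    years = "list",
    vocabulary = "data.frame",
    minCount = "numeric"
  )
)

setValidity("LifeCourseCorpus", function(object) {
  msg <- character()
  n <- length(object@personIds)
  if (length(object@tokens) != n || length(object@years) != n)
    msg <- c(msg, "personIds, tokens and years must have equal length")
  v <- object@vocabulary
  if (!all(c("token", "index", "count", "system") %in% names(v)))
    msg <- c(msg, "vocabulary needs columns token, index, count, system")
  else {
    if (nrow(v) && !identical(sort(v$index), seq_len(nrow(v)) - 1L))
      msg <- c(msg, "vocabulary indices must be contiguous from 0")
    if (nrow(v) && any(v$count < object@minCount))
      msg <- c(msg, "vocabulary contains tokens below minCount")
  }
  for (i in seq_len(n)) {
    if (length(object@tokens[[i]]) != length(object@years[[i]])) {
      msg <- c(msg, "tokens and years must be parallel within each sentence")
      break
    }
    if (is.unsorted(object@years[[i]])) {
      msg <- c(msg, "years must be non-decreasing within each sentence")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Life-course event embedding
#'
#' The trained term-by-dimension embedding matrix together with the corpus
#' vocabulary it covers. Rows are the hidden-layer (input) vectors of the
#' skip-gram model, one per retained vocabulary token.
#'
#' @slot vectors numeric matrix, one row per term (rownames = tokens).
#' @slot vocabulary the corpus vocabulary data.frame (token, index, count,
#'   system).
#' @slot config list of training settings (dim, window, epochs,
#'   learningRate, seed, backend).
#'
#' @seealso \code{\link{trainEmbeddings}}, \code{\link{embeddingVectors}}
#' @export
setClass("EventEmbedding",
  representation(
    vectors = "matrix",
    vocabulary = "data.frame",
    config = "list"
  )
)

setValidity("EventEmbedding", function(object) {
  msg <- character()
  if (nrow(object@vectors) != nrow(object@vocabulary))
    msg <- c(msg, "one vector row per vocabulary term required")
  if (!identical(rownames(object@vectors), object@vocabulary$token))
    msg <- c(msg, "vector rownames must equal vocabulary tokens")
  if (any(!is.finite(object@vectors)))
    msg <- c(msg, "embedding contains non-finite entries")
  if (length(msg)) msg else TRUE
})

#' Term neighborhood network
#'
#' An undirected network whose nodes are query (seed) terms and their
#' cosine nearest neighbors, and whose edges carry the cosine similarity
#' between endpoints. Node degree is kept consistent with the edge list.
#'
#' @slot nodes data.frame with columns \code{term}, \code{system},
#'   \code{is_seed}, \code{degree}.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{similarity}.
#'
#' @seealso \code{\link{buildTermNetwork}}
#' @export
setClass("TermNetwork",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("TermNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$source == e$target)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$similarity < -1 - 1e-8 | e$similarity > 1 + 1e-8))
      msg <- c(msg, "edge weights must lie in [-1, 1]")
  }
  tal <- table(c(e$source, e$target))
  deg <- object@nodes$degree
  names(deg) <- object@nodes$term
  recount <- rep(0L, nrow(object@nodes))
  names(recount) <- object@nodes$term
  recount[names(tal)] <- as.integer(tal)
  if (!isTRUE(all.equal(unname(deg[object@nodes$term]),
                        unname(recount[object@nodes$term]))))
    msg <- c(msg, "node degrees inconsistent with the edge list")
  if (length(msg)) msg else TRUE
})

#' Consensus clustering result
#'
#' Co-clustering frequencies of term pairs across several clustering
#' algorithms run at a common k, plus the per-term consensus score (mean
#' co-clustering frequency with the other members of the term's assigned
#' cluster).
#'
#' @slot consensus symmetric term-by-term matrix of co-clustering
#'   frequencies in [0, 1], unit diagonal.
#' @slot scores named numeric vector, per-term consensus score.
#' @slot assignment named integer vector, the reference cluster labels used
#'   for scoring.
#' @slot methods character, the methods that contributed.
#' @slot assignments list of the individual methods' label vectors.
#'
#' @seealso \code{\link{consensusCluster}}
#' @export
setClass("ConsensusResult",
  representation(
    consensus = "matrix",
    scores = "numeric",
    assignment = "integer",
    methods = "character",
    assignments = "list"
  )
)

setValidity("ConsensusResult", function(object) {
  m <- object@consensus
  msg <- character()
  if (nrow(m) != ncol(m) || !isTRUE(all.equal(m, t(m))))
    msg <- c(msg, "consensus matrix must be symmetric")
  if (any(m < -1e-8 | m > 1 + 1e-8))
    msg <- c(msg, "consensus frequencies must lie in [0, 1]")
  if (nrow(m) && !isTRUE(all.equal(unname(diag(m)), rep(1, nrow(m)))))
    msg <- c(msg, "consensus diagonal must be 1")
  if (length(msg)) msg else TRUE
})
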