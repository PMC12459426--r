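#' Normalize and truncate register codes to token form
#'
#' Register codes are reduced to the granularity used for embedding
#' training: ATC medication codes to 5 characters, SKS procedure codes to 6,
#' ICD-10 diagnosis codes to 4 significant characters (dots are stripped
#' first, so \code{"G47.3"} becomes \code{"G473"}), and adversity labels
#' pass through unchanged. The undotted form is the canonical internal
#' representation.
#'
#' @param code character vector of raw codes.
#' @param system parallel character vector of code systems
#'   (\code{"diagnosis"}, \code{"medication"}, \code{"procedure"},
#'   \code{"adversity"}).
#' @return character vector of tokens.
#' @examples
#' truncateCode("N05CH01", "medication")  # "N05CH"
#' truncateCode("G47.3", "diagnosis")     # "G473"
#' @export
truncateCode <- function(code, system) {
  if (any(!nzchar(code))) stop("empty code")
  known <- c(diagnosis = 4L, medication = 5L, procedure = 6L)
  bad <- setdiff(unique(system), c(names(known), "adversity"))
  if (length(bad))
    stop("unknown code system(s): ", paste(bad, collapse = ", "))
  out <- code
  isDx <- system == "diagnosis"
  out[isDx] <- gsub(".", "", out[isDx], fixed = TRUE)
  lim <- known[system]
  trunc <- !is.na(lim)
  out[trunc] <- substr(out[trunc], 1L, lim[trunc])
  out
}

#' Build life-course sentences from an event table
#'
#' Converts register events into one token sequence per person: codes are
#' truncated (\code{\link{truncateCode}}), tokens with corpus-wide count
#' below \code{minCount} are removed before sentence emission (so training
#' windows never span dropped tokens), surviving tokens are ordered by
#' calendar year, and ties within a (person, year) block are broken by a
#' seeded uniformly random shuffle. Persons with no retained tokens yield no
#' sentence.
#'
#' @param events event table with columns \code{person_id}, \code{year},
#'   \code{code}, \code{system}.
#' @param minCount minimum corpus count for a token to be retained,
#'   default 20.
#' @param seed integer seed governing the within-year shuffle.
#' @return a \code{\linkS4class{LifeCourseCorpus}}.
#' @export
buildSentences <- function(events, minCount = 20L, seed = 1L) {
  checkEventTable(events)
  if (nrow(events) == 0) stop("events table is empty")
  if (minCount < 1) stop("minCount must be >= 1")

  tok <- truncateCode(events$code, events$system)
  counts <- table(tok)
  keep <- names(counts)[counts >= minCount]
  sel <- tok %in% keep
  ev <- data.frame(
    person_id = events$person_id[sel],
    year = events$year[sel],
    token = tok[sel],
    system = events$system[sel],
    stringsAsFactors = FALSE
  )

  if (nrow(ev)) {
    u <- withSeed(seed, stats::runif(nrow(ev)))
    ord <- order(ev$person_id, ev$year, u)
    ev <- ev[ord, , drop = FALSE]
  }

  ids <- unique(ev$person_id)
  tokens <- split(ev$token, factor(ev$person_id, levels = ids))
  years <- split(as.integer(ev$year), factor(ev$person_id, levels = ids))

  retained <- counts[keep]
  # index by decreasing corpus count (hierarchical-softmax convention),
  # ties broken alphabetically for determinism
  ordv <- order(-as.integer(retained), names(retained))
  vocab <- data.frame(
    token = names(retained)[ordv],
    index = seq_along(keep) - 1L,
    count = as.integer(retained)[ordv],
    stringsAsFactors = FALSE
  )
  sysMap <- ev$system[!duplicated(ev$token)]
  names(sysMap) <- ev$token[!duplicated(ev$token)]
  vocab$system <- unname(sysMap[vocab$token])

  new("LifeCourseCorpus",
      personIds = ids,
      tokens = unname(tokens),
      years = unname(years),
      vocabulary = vocab,
      minCount = as.numeric(minCount))
}

#' Sentence length distribution
#'
#' Exact counts of sentences per length, used to judge whether a context
#' window covers most life courses.
#'
#' @param corpus a \code{LifeCourseCorpus}.
#' @param window optional window size; when given, the fraction of sentences
#'   with length <= window is attached as attribute
#'   \code{"windowCoverage"}.
#' @return data.frame with columns \code{length} and \code{count}.
#' @export
sentenceLengthDistribution <- function(corpus, window = NULL) {
  lens <- lengths(corpus@tokens)
  tab <- table(lens)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.integer(tab))
  if (!is.null(window) && length(lens))
    attr(out, "windowCoverage") <- mean(lens <= window)
  out
}

#' Write a corpus as plain text and its vocabulary as TSV
#'
#' The corpus format is one whitespace-delimited line per person; the
#' vocabulary is tab-separated with columns
#' \code{token index count system}.
#'
#' @param corpus a \code{LifeCourseCorpus}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  writeLines(vapply(corpus@tokens, paste, "", collapse = " "), path)
  invisible(path)
}

#' @rdname writeCorpus
#' @export
writeVocabulary <- function(corpus, path) {
  utils::write.table(vocabulary(corpus), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
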