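# Shared fixtures, all built in code.

# Minimal two-code vocabulary for tiny cohort specs.
tinyVocabulary <- function() {
  data.frame(
    code = c("F510", "N05CH", "UXCC00", "foster_care"),
    system = c("diagnosis", "medication", "procedure", "adversity"),
    stringsAsFactors = FALSE
  )
}

tinySpec <- function(n = 50, rate = 0.05, communities = list(), seed = 11L) {
  cohortSpec(
    nIndividuals = n,
    birthYearRange = c(1990, 2005),
    observationEndYear = 2022,
    vocabulary = tinyVocabulary(),
    communities = communities,
    backgroundRate = rate,
    seed = seed
  )
}

# Hand-built event table (one row per event).
makeEvents <- function(person_id, year, code, system, birth_year = 1990) {
  data.frame(person_id = person_id, birth_year = birth_year, year = year,
             code = code, system = system, stringsAsFactors = FALSE)
}

# Wrap a raw matrix as an EventEmbedding with a synthetic vocabulary.
toyEmbedding <- function(m, systems = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("t", seq_len(nrow(m)))
  if (is.null(systems)) systems <- rep("diagnosis", nrow(m))
  vocab <- data.frame(
    token = rownames(m),
    index = seq_len(nrow(m)) - 1L,
    count = 100L,
    system = systems,
    stringsAsFactors = FALSE
  )
  new("EventEmbedding", vectors = m, vocabulary = vocab,
      config = list(dim = ncol(m), backend = "toy"))
}

# Corpus built directly from token sequences (one per person, single years).
corpusFromTokens <- function(tokenLists, systems = NULL) {
  ev <- do.call(rbind, lapply(seq_along(tokenLists), function(i) {
    tk <- tokenLists[[i]]
    data.frame(person_id = sprintf("P%03d", i),
               year = seq_along(tk) + 1999L,
               code = tk,
               system = if (is.null(systems)) "adversity"
                        else systems[match(tk, unlist(tokenLists))],
               stringsAsFactors = FALSE)
  }))
  buildSentences(ev, minCount = 1L, seed = 1L)
}

# Small planted cohort reused by embedding-adjacent tests (kept small so the
# module tests stay fast; the full study-conditions run lives in the
# acceptance suite).
plantedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- exampleCohortSpec(nIndividuals = 800, seed = 4242L)
      ev <- generateCohort(spec)
      corp <- buildSentences(ev, minCount = 20L, seed = 5L)
      emb <- trainEmbeddings(corp, dim = 25L, window = 100L, epochs = 3L,
                             seed = 5L)
      cache <<- list(spec = spec, events = ev, corpus = corp,
                     embedding = emb,
                     labels = attr(spec, "communityLabels"))
    }
    cache
  }
})

# Independent brute-force cosine for oracle comparisons.
bruteCosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Independent person-by-person enumeration of first-event incidence: the
# oracle loops over persons and years with no vectorization shared with the
# implementation.
enumerateIncidence <- function(events, census, term, period, ageGroups) {
  ev <- events
  ev$token <- truncateCode(ev$code, ev$system)
  ev <- ev[ev$token == term, , drop = FALSE]
  out <- data.frame(age_group = ageGroups$label, events = 0L,
                    person_years = 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(census))) {
    p <- census$person_id[i]; b <- census$birth_year[i]
    mine <- ev[ev$person_id == p, , drop = FALSE]
    firstYear <- if (nrow(mine)) min(mine$year) else Inf
    for (y in seq(period[1], period[2])) {
      age <- y - b
      if (age < 0) next
      gi <- which(ageGroups$min <= age & ageGroups$max >= age)
      if (!length(gi)) next
      if (y <= firstYear) {
        out$person_years[gi] <- out$person_years[gi] + 1
        if (y == firstYear)
          out$events[gi] <- out$events[gi] + 1L
      }
    }
  }
  out
}
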