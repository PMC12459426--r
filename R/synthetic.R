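#' Construct a synthetic cohort specification
#'
#' Builds and validates a \code{\linkS4class{CohortSpec}}. The generator it
#' parameterizes emulates a nationwide register cohort: every person has a
#' birth year, accrues coded events (diagnoses, medications, procedures,
#' childhood adversities) from birth until the end of follow-up, with
#' age-dependent rates, and codes belonging to a planted community co-occur
#' within persons at boosted rates. Childhood adversity codes are restricted
#' to ages below their cutoff (default 16).
#'
#' @param nIndividuals number of persons.
#' @param birthYearRange inclusive birth-year range, default 1980-2015.
#' @param observationEndYear last year of follow-up, default 2022.
#' @param vocabulary data.frame with columns \code{code}, \code{system} and
#'   optionally \code{adversity_only_before}.
#' @param ageProfiles matrix of non-negative age-band weights (one row per
#'   code, rownames = codes); defaults to flat profiles.
#' @param communities list of \code{list(members =, boost =)} entries.
#' @param backgroundRate per-code baseline rate, events per person-year.
#' @param seed integer seed.
#' @return a validated \code{CohortSpec}.
#' @examples
#' spec <- cohortSpec(
#'   nIndividuals = 50,
#'   vocabulary = data.frame(
#'     code = c("F510", "N05CH"),
#'     system = c("diagnosis", "medication")
#'   ),
#'   backgroundRate = 0.05, seed = 1
#' )
#' events <- generateCohort(spec)
#' @export
cohortSpec <- function(nIndividuals,
                       birthYearRange = c(1980, 2015),
                       observationEndYear = 2022,
                       vocabulary,
                       ageProfiles = NULL,
                       communities = list(),
                       backgroundRate = 0.01,
                       seed = 1L) {
  if (is.null(vocabulary) || nrow(vocabulary) == 0)
    stop("vocabulary must contain at least one code")
  if (birthYearRange[1] > birthYearRange[2])
    stop("birthYearRange is inverted")
  vocabulary <- as.data.frame(vocabulary, stringsAsFactors = FALSE)
  if (!"adversity_only_before" %in% names(vocabulary))
    vocabulary$adversity_only_before <-
      ifelse(vocabulary$system == "adversity", 16, NA_real_)
  bands <- defaultAgeGroups()
  if (is.null(ageProfiles)) {
    ageProfiles <- matrix(1, nrow(vocabulary), nrow(bands),
                          dimnames = list(vocabulary$code, bands$label))
  }
  new("CohortSpec",
      nIndividuals = nIndividuals,
      birthYearRange = as.numeric(birthYearRange),
      observationEndYear = observationEndYear,
      vocabulary = vocabulary,
      ageProfiles = ageProfiles,
      communities = communities,
      backgroundRate = backgroundRate,
      seed = seed)
}

#' Default study-conditions cohort specification
#'
#' The packaged synthetic stand-in for a Danish register cohort: 5,000
#' persons born 1980-2015 followed to 2022, a 60-code vocabulary spanning
#' ICD-10 diagnoses, ATC medications, SKS-style procedures and childhood
#' adversity indicators, organised into three planted communities of 20
#' codes each (sleep-medication/mental-health, sleep-apnea/respiratory,
#' nonorganic-sleep/neurodevelopmental + adversity) with a within-community
#' co-occurrence boost of 20. Codes and age profiles are synthetic but
#' shaped like their real-register counterparts: medication use rises in
#' adulthood, apnea-related codes peak late, adversities occur only before
#' age 16.
#'
#' @param nIndividuals cohort size, default 5000.
#' @param boost within-community co-occurrence multiplier, default 20.
#' @param backgroundRate per-code baseline rate, default 0.004
#'   events/person-year (roughly 20-50 lifetime register events per person
#'   at this scale).
#' @param membershipRate probability that a person belongs to a given
#'   community, default 0.25.
#' @param seed integer seed, default 20251.
#' @return a \code{CohortSpec} with a \code{community} column available via
#'   \code{attr(, "communityLabels")} mapping each code to its planted
#'   community (1-3).
#' @export
exampleCohortSpec <- function(nIndividuals = 5000, boost = 20,
                              backgroundRate = 0.004,
                              membershipRate = 0.25, seed = 20251L) {
  # codes are chosen to stay distinct after token truncation (ATC 5 chars,
  # SKS 6, ICD-10 4), so the 60 codes map to 60 vocabulary tokens
  sleepMed <- data.frame(
    code = c("N05CH", "N05CF", "R06AD", "N06AB", "N06AX",
             "N05BA", "N05AH", "N02AA", "N02AX", "N02BE",
             "N03AX", "N05AX", "N06AA", "R06AA",
             "UXCC00", "UXMC90", "UXRC00", "ZZ4920", "BANA10", "BVAA33"),
    system = c(rep("medication", 14), rep("procedure", 6)),
    community = 1L, stringsAsFactors = FALSE
  )
  apnea <- data.frame(
    code = c("G473", "G470", "G478", "G479", "R065", "E660", "E668",
             "J342", "J358", "I10", "R090", "R068",
             "ZZ7025", "ZZ7030", "BGFC30", "BGFC33", "UXAC85",
             "KEMB20", "KEJD10", "GBB000"),
    system = c(rep("diagnosis", 12), rep("procedure", 8)),
    community = 2L, stringsAsFactors = FALSE
  )
  nonorganic <- data.frame(
    code = c("F510", "F512", "F514", "F515", "F519", "F900", "F840",
             "F952", "F400", "F930", "F980", "G254", "ZZ0150",
             "BVAA50",
             "sibling_psychiatric_illness", "foster_care",
             "parental_divorce", "parental_death", "childhood_poverty",
             "parental_alcohol_abuse"),
    system = c(rep("diagnosis", 12), rep("procedure", 2),
               rep("adversity", 6)),
    community = 3L, stringsAsFactors = FALSE
  )
  vocab <- rbind(sleepMed, apnea, nonorganic)
  communityLabels <- stats::setNames(vocab$community, vocab$code)
  vocab$adversity_only_before <-
    ifelse(vocab$system == "adversity", 16, NA_real_)

  bands <- defaultAgeGroups()
  nb <- nrow(bands)
  prof <- matrix(1, nrow(vocab), nb,
                 dimnames = list(vocab$code, bands$label))
  adultRise <- seq(0.2, 2, length.out = nb)        # medication-like
  lateAdult <- c(0.1, 0.1, 0.2, 0.4, 0.8, 1.2, 1.8, 2.2, 2.5)  # apnea-like
  childPeak <- c(1.5, 2, 2, 1.5, 1, 0.8, 0.8, 0.7, 0.7)        # early-life
  prof[vocab$community == 1L, ] <- rep(adultRise, each = sum(vocab$community == 1L))
  prof[vocab$community == 2L, ] <- rep(lateAdult, each = sum(vocab$community == 2L))
  prof[vocab$community == 3L, ] <- rep(childPeak, each = sum(vocab$community == 3L))
  # adversities: only childhood bands can fire (cutoff enforces < 16 anyway)
  adv <- vocab$system == "adversity"
  prof[adv, ] <- 0
  prof[adv, 1:4] <- 3  # bands 0-4 .. 15-19, trimmed by the age-16 cutoff

  communities <- lapply(split(vocab$code, vocab$community),
                        function(m) list(members = m, boost = boost,
                                         membershipRate = membershipRate))
  names(communities) <- NULL
  spec <- cohortSpec(
    nIndividuals = nIndividuals,
    birthYearRange = c(1980, 2015),
    observationEndYear = 2022,
    vocabulary = vocab[, c("code", "system", "adversity_only_before")],
    ageProfiles = prof,
    communities = communities,
    backgroundRate = backgroundRate,
    seed = seed
  )
  attr(spec, "communityLabels") <- communityLabels
  spec
}

# Deterministic first block of the generation stream: birth years.
drawBirthYears <- function(spec) {
  yrs <- seq(spec@birthYearRange[1], spec@birthYearRange[2])
  sample(yrs, spec@nIndividuals, replace = TRUE)
}

#' Census of a synthetic cohort
#'
#' Person ids and birth years of the cohort \code{\link{generateCohort}}
#' would produce for the same spec (identical under the spec's seed, so the
#' census of persons with zero events is recoverable).
#'
#' @param spec a \code{CohortSpec}.
#' @return data.frame with columns \code{person_id}, \code{birth_year}.
#' @export
cohortCensus <- function(spec) {
  validObject(spec)
  birth <- withSeed(spec@seed, drawBirthYears(spec))
  data.frame(
    person_id = sprintf("P%06d", seq_len(spec@nIndividuals)),
    birth_year = birth,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic register event table
#'
#' Draws per person-year-code event counts as Poisson with rate
#' \code{backgroundRate * ageProfile weight}, then plants community
#' co-occurrence by conditional sampling: each person belongs to each
#' community independently with probability \code{membershipRate} (default
#' 0.25), and members accrue additional events for all member codes at rate
#' \code{(boost - 1)} times baseline, so a member's expected member-code
#' rate is \code{boost} times baseline. Conditioning the boost on a latent
#' person-level membership (rather than on having drawn a member event)
#' keeps the planted communities selective over multi-decade follow-up,
#' where nearly every person would otherwise trigger every community.
#' Adversity codes only fire at ages below their cutoff. Output is
#' bit-reproducible for a given spec (seed included).
#'
#' @param spec a \code{CohortSpec}.
#' @return data.frame of events with columns \code{person_id},
#'   \code{birth_year}, \code{year}, \code{code}, \code{system}, sorted by
#'   person, year, code. Multiple events of the same code in the same year
#'   appear as repeated rows.
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    birth <- drawBirthYears(spec)
    n <- spec@nIndividuals
    pid <- sprintf("P%06d", seq_len(n))
    years <- seq(spec@birthYearRange[1], spec@observationEndYear)
    bands <- defaultAgeGroups()
    vocab <- spec@vocabulary

    # persons x years age-band index (NA when unborn or out of band range)
    age <- outer(birth, years, function(b, y) y - b)
    bandIdx <- matrix(ageToBand(as.vector(age), bands), n, length(years))
    bandIdx[age < 0] <- NA

    drawBlock <- function(codeRows, rateMat) {
      # rateMat: persons x years lambda for one code
      cnt <- suppressWarnings(
        stats::rpois(length(rateMat), as.vector(rateMat)))
      cnt[is.na(cnt)] <- 0L
      hit <- which(cnt > 0L)
      if (!length(hit)) return(NULL)
      reps <- cnt[hit]
      p <- ((hit - 1L) %% n) + 1L
      y <- ((hit - 1L) %/% n) + 1L
      data.frame(
        person = rep(p, reps),
        year = rep(years[y], reps),
        stringsAsFactors = FALSE
      )
    }

    codeLambda <- function(i) {
      w <- spec@ageProfiles[i, ]
      lam <- matrix(0, n, length(years))
      ok <- !is.na(bandIdx)
      lam[ok] <- spec@backgroundRate * w[bandIdx[ok]]
      cutoff <- vocab$adversity_only_before[i]
      if (!is.na(cutoff)) lam[age >= cutoff] <- 0
      lam[age < 0] <- 0
      lam
    }

    # latent community memberships, drawn before the event stream so the
    # census draws stay aligned with cohortCensus()
    member <- lapply(spec@communities, function(cm) {
      p <- if (is.null(cm$membershipRate)) 0.25 else cm$membershipRate
      stats::runif(n) < p
    })

    base <- vector("list", nrow(vocab))
    for (i in seq_len(nrow(vocab))) {
      blk <- drawBlock(i, codeLambda(i))
      if (!is.null(blk)) blk$code_i <- i
      base[[i]] <- blk
    }
    baseDf <- do.call(rbind, base)

    extra <- list()
    for (ci in seq_along(spec@communities)) {
      cm <- spec@communities[[ci]]
      sel <- member[[ci]]
      if (!any(sel)) next
      for (i in match(cm$members, vocab$code)) {
        lam <- codeLambda(i) * (cm$boost - 1)
        lam[!sel, ] <- 0
        blk <- drawBlock(i, lam)
        if (!is.null(blk)) {
          blk$code_i <- i
          extra[[length(extra) + 1L]] <- blk
        }
      }
    }

    ev <- do.call(rbind, c(list(baseDf), extra))
    if (is.null(ev) || nrow(ev) == 0) {
      return(data.frame(person_id = character(), birth_year = integer(),
                        year = integer(), code = character(),
                        system = character(), stringsAsFactors = FALSE))
    }
    out <- data.frame(
      person_id = pid[ev$person],
      birth_year = birth[ev$person],
      year = ev$year,
      code = vocab$code[ev$code_i],
      system = vocab$system[ev$code_i],
      stringsAsFactors = FALSE
    )
    out <- out[order(out$person_id, out$year, out$code), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Aggregate yearly counts of affected persons
#'
#' Emulates public register extracts: for each year and code, the number of
#' distinct persons in the age band with at least one event that year, and
#' the number of persons alive and in the age band (the population
#' denominator). Consistent with \code{\link{generateCohort}} under the same
#' spec.
#'
#' @param spec a \code{CohortSpec}.
#' @param codes character vector of codes to tabulate.
#' @param years integer vector of calendar years.
#' @param ageBand length-2 inclusive age range, default c(15, 45).
#' @param events optional pre-generated event table from
#'   \code{generateCohort(spec)}; generated if missing.
#' @return data.frame with columns \code{year}, \code{code},
#'   \code{affected}, \code{population}.
#' @export
generateAggregateCounts <- function(spec, codes, years,
                                    ageBand = c(15, 45), events = NULL) {
  validObject(spec)
  if (!length(years)) stop("years must be non-empty")
  if (any(years > spec@observationEndYear))
    stop("years outside the observation window")
  if (is.null(events)) events <- generateCohort(spec)
  census <- cohortCensus(spec)

  out <- expand.grid(year = sort(unique(years)), code = codes,
                     stringsAsFactors = FALSE)
  out$affected <- 0L
  out$population <- 0L
  for (r in seq_len(nrow(out))) {
    y <- out$year[r]
    agePop <- y - census$birth_year
    inBand <- agePop >= ageBand[1] & agePop <= ageBand[2]
    out$population[r] <- sum(inBand)
    sub <- events[events$year == y & events$code == out$code[r], , drop = FALSE]
    if (nrow(sub)) {
      ageEv <- sub$year - sub$birth_year
      out$affected[r] <- length(unique(
        sub$person_id[ageEv >= ageBand[1] & ageEv <= ageBand[2]]))
    }
  }
  out
}

#' Read/write register event tables
#'
#' Tab-separated with header \code{person_id birth_year year code system}.
#'
#' @param events event table as from \code{\link{generateCohort}}.
#' @param path file path.
#' @return \code{readEventTable} returns the event data.frame;
#'   \code{writeEventTable} returns \code{path} invisibly.
#' @export
writeEventTable <- function(events, path) {
  checkEventTable(events, requireBirth = TRUE)
  data.table::fwrite(events, path, sep = "\t")
  invisible(path)
}

#' @rdname writeEventTable
#' @export
readEventTable <- function(path) {
  ev <- as.data.frame(data.table::fread(path, sep = "\t"))
  checkEventTable(ev)
  ev
}
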