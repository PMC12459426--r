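#' Age-specific incidence rates
#'
#' Incidence of first-ever events per term and 5-year age group over a
#' calendar period, as cases per 100,000 person-years. A person is at risk
#' for a term from birth (or the period start) until the year of their first
#' event of that term, inclusive; after the first event they exit the risk
#' set (set \code{recurrent = TRUE} to count every event with no exit). Age
#' is event year minus birth year, and persons contribute whole-year
#' increments to age bands. Cells with zero person-years get \code{NA} IR
#' and are flagged in \code{ir_defined}, never reported as zero.
#'
#' @param events event table with columns \code{person_id}, \code{year},
#'   \code{code}, \code{system} (codes are truncated to token form
#'   internally).
#' @param census data.frame with columns \code{person_id},
#'   \code{birth_year}, covering everyone at risk (also persons without
#'   events), as from \code{\link{cohortCensus}}.
#' @param terms character vector of tokens of interest.
#' @param period inclusive calendar-year range, default c(2010, 2021).
#' @param ageGroups data.frame with columns \code{label}, \code{min},
#'   \code{max}; default 5-year bands 0-4 .. 40-44.
#' @param observationEndYear censoring year, default the period end.
#' @param recurrent if TRUE, count all events and never exit the risk set.
#' @return data.frame with columns \code{term}, \code{age_group},
#'   \code{events}, \code{person_years}, \code{ir_per_100k},
#'   \code{ir_defined}.
#' @export
incidenceRates <- function(events, census, terms,
                           period = c(2010, 2021),
                           ageGroups = defaultAgeGroups(),
                           observationEndYear = max(period),
                           recurrent = FALSE) {
  checkEventTable(events)
  if (!all(c("person_id", "birth_year") %in% names(census)))
    stop("census needs columns person_id, birth_year")
  years <- seq(period[1], min(period[2], observationEndYear))
  birth <- stats::setNames(census$birth_year, census$person_id)

  ev <- events
  ev$token <- truncateCode(ev$code, ev$system)
  ev <- ev[ev$token %in% terms, , drop = FALSE]

  out <- expand.grid(term = terms, age_group = ageGroups$label,
                     stringsAsFactors = FALSE)
  out$events <- 0L
  out$person_years <- 0
  nP <- nrow(census)

  # person x year age-band membership, shared across terms
  ageMat <- outer(census$birth_year, years, function(b, y) y - b)
  bandMat <- matrix(ageToBand(as.vector(ageMat), ageGroups),
                    nP, length(years))
  bandMat[ageMat < 0] <- NA

  for (tm in terms) {
    sub <- ev[ev$token == tm, , drop = FALSE]
    firstYear <- if (nrow(sub))
      tapply(sub$year, sub$person_id, min) else numeric(0)
    fy <- rep(Inf, nP)
    hit <- match(names(firstYear), census$person_id)
    fy[hit[!is.na(hit)]] <- firstYear[!is.na(hit)]

    # at risk in year y while y <= first event year (or always if recurrent)
    atRisk <- outer(fy, years, function(f, y) recurrent | y <= f)
    atRisk[is.na(bandMat)] <- FALSE

    pyBand <- vapply(seq_len(nrow(ageGroups)), function(bi)
      sum(atRisk & !is.na(bandMat) & bandMat == bi), numeric(1))

    if (recurrent) {
      cnt <- sub[sub$year %in% years, , drop = FALSE]
      evAge <- cnt$year - birth[cnt$person_id]
      evBand <- ageToBand(evAge, ageGroups)
    } else {
      inPeriod <- is.finite(fy) & fy >= years[1] & fy <= years[length(years)]
      evAge <- fy[inPeriod] - census$birth_year[inPeriod]
      evBand <- ageToBand(evAge, ageGroups)
    }
    evCount <- tabulate(evBand[!is.na(evBand)], nrow(ageGroups))

    rows <- out$term == tm
    out$events[rows] <- evCount[match(out$age_group[rows], ageGroups$label)]
    out$person_years[rows] <-
      pyBand[match(out$age_group[rows], ageGroups$label)]
  }

  out$ir_defined <- out$person_years > 0
  out$ir_per_100k <- ifelse(out$ir_defined,
                            out$events / out$person_years * 1e5, NA_real_)
  out
}

#' Categorize incidence rates into within-term quantile bins
#'
#' Within each term, the age-group IRs are ranked and mapped to \code{q}
#' quantile categories (1 = lowest). The mapping is monotone (a higher IR
#' never receives a lower category) and invariant under strictly monotone
#' transformations of the IRs; tied IRs share a category, so all-identical
#' IRs collapse to a single category. Undefined IRs get \code{NA}.
#'
#' @param table data.frame from \code{\link{incidenceRates}}.
#' @param q number of quantile bins, default 5.
#' @return the input with an added \code{quantile} column (integer 1..q).
#' @export
quantileCategorize <- function(table, q = 5L) {
  table$quantile <- NA_integer_
  for (tm in unique(table$term)) {
    rows <- which(table$term == tm)
    ir <- table$ir_per_100k[rows]
    ok <- !is.na(ir)
    if (!any(ok)) next
    r <- rank(ir[ok], ties.method = "average")
    table$quantile[rows[ok]] <- as.integer(ceiling(q * r / sum(ok)))
  }
  table
}

#' Period prevalence trends from aggregate count tables
#'
#' Converts yearly (indicator, affected count, population) aggregates into a
#' prevalence series: rate per 1,000 persons, or percent for survey-style
#' indicators. Per-1000 rates are exactly 10 times the percent rates.
#'
#' @param aggregate data.frame with columns \code{year}, a code/indicator
#'   column (\code{code} or \code{indicator}), \code{affected},
#'   \code{population}.
#' @param scale \code{"per1000"} (default) or \code{"percent"}.
#' @return data.frame with columns \code{year}, \code{indicator},
#'   \code{affected}, \code{population}, \code{rate}, sorted by indicator
#'   then year.
#' @export
prevalenceTrend <- function(aggregate, scale = c("per1000", "percent")) {
  scale <- match.arg(scale)
  indCol <- intersect(c("indicator", "code"), names(aggregate))[1]
  if (is.na(indCol)) stop("aggregate needs an indicator or code column")
  need <- c("year", "affected", "population")
  if (!all(need %in% names(aggregate)))
    stop("aggregate needs columns year, affected, population")
  if (any(aggregate$population <= 0))
    stop("population must be positive in every row")
  mult <- if (scale == "per1000") 1000 else 100
  out <- data.frame(
    year = aggregate$year,
    indicator = aggregate[[indCol]],
    affected = aggregate$affected,
    population = aggregate$population,
    rate = aggregate$affected / aggregate$population * mult,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$indicator, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scale") <- scale
  out
}

#' Write an incidence table as TSV
#'
#' Columns \code{term age_group events person_years ir_per_100k quantile}.
#'
#' @param table data.frame from \code{\link{quantileCategorize}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIncidenceTable <- function(table, path) {
  cols <- intersect(c("term", "age_group", "events", "person_years",
                      "ir_per_100k", "quantile"), names(table))
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
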