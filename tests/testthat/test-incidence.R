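test_that("a toy cell follows the IR definition exactly", {
  # 2 first events among persons contributing 1,000 person-years in a band:
  # 1,000 persons aged 20 for one observed year, 2 with a first event
  census <- data.frame(person_id = sprintf("P%04d", 1:1000),
                       birth_year = 2000, stringsAsFactors = FALSE)
  events <- makeEvents(c("P0001", "P0002"), 2020, "F510", "diagnosis",
                       birth_year = 2000)
  tab <- incidenceRates(events, census, terms = "F510",
                        period = c(2020, 2020))
  cell <- tab[tab$age_group == "20-24", ]
  expect_equal(cell$events, 2L)
  expect_equal(cell$person_years, 1000)
  expect_equal(cell$ir_per_100k, 200)
})

test_that("no events gives zero IR with positive person-years", {
  census <- data.frame(person_id = c("P1", "P2"), birth_year = c(1990, 2000))
  events <- makeEvents("P1", 2015, "N05CH", "medication", 1990)
  tab <- incidenceRates(events, census, terms = "F510",
                        period = c(2010, 2021))
  expect_true(all(tab$events == 0))
  expect_true(any(tab$person_years > 0))
  expect_true(all(tab$ir_per_100k[tab$ir_defined] == 0))
})

test_that("zero person-year cells are flagged undefined, not zero", {
  census <- data.frame(person_id = "P1", birth_year = 2000)
  tab <- incidenceRates(
    makeEvents("P1", 2015, "F510", "diagnosis", 2000), census,
    terms = "F510", period = c(2010, 2021))
  far <- tab[tab$age_group == "40-44", ]
  expect_equal(far$person_years, 0)
  expect_false(far$ir_defined)
  expect_true(is.na(far$ir_per_100k))
})

test_that("incidence cells match person-by-person enumeration", {
  spec <- cohortSpec(
    nIndividuals = 200,
    birthYearRange = c(1985, 2010),
    observationEndYear = 2021,
    vocabulary = tinyVocabulary(),
    backgroundRate = 0.15,
    seed = 55L
  )
  ev <- generateCohort(spec)
  census <- cohortCensus(spec)
  groups <- defaultAgeGroups()
  for (term in c("F510", "N05CH")) {
    got <- incidenceRates(ev, census, terms = term, period = c(2010, 2021))
    want <- enumerateIncidence(ev, census, term, c(2010, 2021), groups)
    expect_equal(got$events, want$events)
    expect_equal(got$person_years, want$person_years)
  }
})

test_that("risk exit: persons stop contributing after their first event", {
  census <- data.frame(person_id = "P1", birth_year = 2000)
  ev <- makeEvents(c("P1", "P1"), c(2012, 2018), "F510", "diagnosis", 2000)
  tab <- incidenceRates(ev, census, terms = "F510", period = c(2010, 2021))
  # ages 10, 11, 12 at risk (event at age 12); nothing afterwards
  expect_equal(sum(tab$person_years), 3)
  expect_equal(sum(tab$events), 1L)
  rec <- incidenceRates(ev, census, terms = "F510", period = c(2010, 2021),
                        recurrent = TRUE)
  expect_equal(sum(rec$person_years), 12)
  expect_equal(sum(rec$events), 2L)
})

test_that("quantile categories equal the rank-then-bin oracle", {
  tab <- data.frame(
    term = "X",
    age_group = sprintf("g%d", 1:5),
    events = 1L, person_years = 1,
    ir_per_100k = c(10, 20, 30, 40, 50),
    ir_defined = TRUE, stringsAsFactors = FALSE
  )
  expect_equal(quantileCategorize(tab, q = 5)$quantile, 1:5)

  set.seed(8)
  tab8 <- data.frame(
    term = "Y", age_group = sprintf("g%d", 1:8),
    events = 1L, person_years = 1,
    ir_per_100k = runif(8, 0, 500), ir_defined = TRUE,
    stringsAsFactors = FALSE
  )
  got <- quantileCategorize(tab8, q = 5)$quantile
  r <- rank(tab8$ir_per_100k)
  want <- as.integer(ceiling(5 * r / 8))
  expect_equal(got, want)
  # monotone: higher IR never gets a lower category
  ord <- order(tab8$ir_per_100k)
  expect_true(all(diff(got[ord]) >= 0))
})

test_that("quantile categories are invariant under monotone transforms
           and collapse for constant IRs", {
  tab <- data.frame(
    term = "Z", age_group = sprintf("g%d", 1:6),
    events = 1L, person_years = 1,
    ir_per_100k = c(5, 1, 40, 12, 7, 100), ir_defined = TRUE,
    stringsAsFactors = FALSE
  )
  q1 <- quantileCategorize(tab, q = 5)$quantile
  tab2 <- tab; tab2$ir_per_100k <- log1p(tab$ir_per_100k)  # monotone
  expect_equal(quantileCategorize(tab2, q = 5)$quantile, q1)

  const <- tab; const$ir_per_100k <- 7
  expect_equal(length(unique(quantileCategorize(const, q = 5)$quantile)), 1)
})

test_that("prevalence rates follow the chosen scale exactly", {
  agg <- data.frame(
    year = c(2010, 2021), indicator = "survey",
    affected = c(34, 49), population = c(100, 100)
  )
  pct <- prevalenceTrend(agg, scale = "percent")
  expect_equal(pct$rate, c(34, 49))
  per1000 <- prevalenceTrend(agg, scale = "per1000")
  expect_equal(per1000$rate, 10 * pct$rate)

  toy <- data.frame(
    year = 2015:2019, indicator = "melatonin",
    affected = c(0, 12, 30, 45, 80),
    population = c(1000, 1200, 1250, 1300, 1500)
  )
  got <- prevalenceTrend(toy)$rate
  expect_equal(got, toy$affected / toy$population * 1000)
  expect_equal(got[1], 0)
  bad <- toy; bad$population[2] <- 0
  expect_error(prevalenceTrend(bad), "positive")
})

test_that("incidence table exports with quantile column", {
  census <- data.frame(person_id = sprintf("P%03d", 1:50),
                       birth_year = rep(c(1990, 2000), 25))
  ev <- makeEvents(sprintf("P%03d", 1:10), 2015, "F510", "diagnosis",
                   rep(c(1990, 2000), 5))
  tab <- quantileCategorize(
    incidenceRates(ev, census, "F510", period = c(2010, 2021)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeIncidenceTable(tab, path)
  got <- read.delim(path)
  expect_named(got, c("term", "age_group", "events", "person_years",
                      "ir_per_100k", "quantile"))
})
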