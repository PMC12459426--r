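# Internal helpers.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Age bands 0-4 ... 40-44, the unit of the age profiles and incidence tables.
defaultAgeGroups <- function(maxAge = 44) {
  starts <- seq(0, maxAge, by = 5)
  data.frame(
    label = sprintf("%d-%d", starts, starts + 4),
    min = starts, max = starts + 4,
    stringsAsFactors = FALSE
  )
}

ageToBand <- function(age, ageGroups) {
  idx <- findInterval(age, ageGroups$min)
  idx[age < ageGroups$min[1] | age > ageGroups$max[nrow(ageGroups)]] <- NA
  idx
}

# Validate an event table's required columns.
checkEventTable <- function(events, requireBirth = FALSE) {
  need <- c("person_id", "year", "code", "system")
  if (requireBirth) need <- c("person_id", "birth_year", "year", "code", "system")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table is missing column(s): ", paste(miss, collapse = ", "))
  invisible(events)
}
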