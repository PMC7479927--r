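# Brute-force day-enumeration oracles for the interval engine, plus shared
# fixtures. Oracles deliberately use a per-day boolean array, independent of
# the interval-union implementation under test.

oracle_covered_days <- function(fill_dates, days_supplied, start, end) {
  start <- as.Date(start); end <- as.Date(end)
  days <- seq(start, end, by = "day")
  covered <- rep(FALSE, length(days))
  for (i in seq_along(fill_dates)) {
    f <- as.Date(fill_dates[i])
    span <- seq(f, f + days_supplied[i] - 1, by = "day")
    covered[days %in% span] <- TRUE
  }
  sum(covered)
}

oracle_max_window <- function(fill_dates, days_supplied, obs_start, obs_end,
                              window_len = 365L) {
  obs_start <- as.Date(obs_start); obs_end <- as.Date(obs_end)
  days <- seq(obs_start, obs_end, by = "day")
  covered <- rep(FALSE, length(days))
  for (i in seq_along(fill_dates)) {
    f <- as.Date(fill_dates[i])
    span <- seq(f, f + days_supplied[i] - 1, by = "day")
    covered[days %in% span] <- TRUE
  }
  cs <- c(0L, cumsum(covered))
  n_starts <- length(days) - window_len + 1
  if (n_starts < 1) stop("span shorter than window")
  max(vapply(seq_len(n_starts),
             function(s) cs[s + window_len] - cs[s], integer(1)))
}

oracle_nearest_rank <- function(x, p) sort(x)[ceiling(p * length(x))]

random_dispensing_set <- function(n_max = 12, obs_start = "2005-01-01",
                                  obs_end = "2007-12-31") {
  n <- sample(0:n_max, 1)
  lo <- as.Date(obs_start); hi <- as.Date(obs_end)
  list(
    fill_dates = lo + sample.int(as.integer(hi - lo) + 1L, n, replace = TRUE) - 1L,
    days_supplied = sample(1:120, n, replace = TRUE)
  )
}

# a small shared bundle, generated once per test run
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_population(sim_config(n_families = 400, seed = 20060101))
    cache
  }
})

toy_registry <- function() {
  tibble::tibble(
    person_id = c("M1", "C1", "M2", "C2", "C3", "M3", "M4", "C4"),
    family_contract_id = c("F1", "F1", "F2", "F2", "F2", "F3", "F3", "F3"),
    role = c("mother", "child", "mother", "child", "child", "mother", "mother", "child"),
    sex = c("F", "M", "F", "F", "M", "F", "F", "F"),
    birth_year = c(1970, 1998, 1968, 1999, 1996, 1972, 1975, 2000),
    income_quintile = c(2L, 2L, 1L, 1L, 1L, 4L, 4L, 4L),
    premium_subsidy = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    year = 2006L
  )
}
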