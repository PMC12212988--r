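# Toy longitudinal fixtures built in code. Rain and rank coverage are
# deliberately generous so builder tests exercise the risk-set rules, not
# missing-data handling (which has its own tests).

toy_rain <- function(seed = NULL, from = as.Date("1989-01-01"),
                     to = as.Date("2001-12-31"), constant = NULL) {
  dates <- seq(from, to, by = "day")
  mm <- if (!is.null(constant)) rep(constant, length(dates)) else {
    set.seed(seed %||% 1)
    round(stats::rexp(length(dates), rate = 1), 2)
  }
  rain_series(dates, mm)
}

toy_ranks <- function(ids, from = "1989-01", to = "2001-12", value = 0.5) {
  months <- seq(as.Date(paste0(from, "-01")), as.Date(paste0(to, "-01")),
                by = "month")
  grid <- expand.grid(female_id = ids, month = months,
                      stringsAsFactors = FALSE)
  rank_series(grid$female_id, grid$month, rep(value, nrow(grid)))
}

toy_census <- function(groups = "G1", from = "1989-01", to = "2001-12",
                       size = 25) {
  months <- seq(as.Date(paste0(from, "-01")), as.Date(paste0(to, "-01")),
                by = "month")
  grid <- expand.grid(group_id = groups, month = months,
                      stringsAsFactors = FALSE)
  tibble::tibble(group_id = grid$group_id, month = grid$month,
                 size = rep(size, nrow(grid)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 12-month history: 6 cycling months (conception in the 6th), then pregnant
toy_conception_records <- function() {
  females <- tibble::tibble(female_id = "F1", mother_id = "M1",
                            birth_date = as.Date("1990-06-15"),
                            death_date = as.Date(NA))
  months <- seq(as.Date("1996-01-01"), by = "month", length.out = 12)
  states <- tibble::tibble(female_id = "F1", month = months,
                           state = c(rep("cycling", 6), rep("pregnant", 6)),
                           group_id = "G1")
  pregnancies <- tibble::tibble(female_id = "F1",
                                conception_date = as.Date("1996-06-20"),
                                end_date = as.Date("1997-01-10"),
                                live = TRUE)
  infants <- tibble::tibble(infant_id = character(), mother_id = character(),
                            birth_date = as.Date(character()),
                            death_date = as.Date(character()),
                            observed_until = as.Date(character()))
  repro_records(females, states, pregnancies, infants, toy_census())
}

# five pregnancies: three live, one loss, one still in progress
toy_livebirth_records <- function() {
  ids <- paste0("F", 1:5)
  females <- tibble::tibble(female_id = ids, mother_id = paste0("M", 1:5),
                            birth_date = as.Date("1990-06-15") + (1:5),
                            death_date = as.Date(NA))
  conc <- as.Date(c("1995-02-10", "1995-03-10", "1995-04-10",
                    "1995-05-10", "1999-05-10"))
  ends <- as.Date(c("1995-09-01", "1995-10-01", "1995-11-01",
                    "1995-12-01", NA))
  pregnancies <- tibble::tibble(female_id = ids, conception_date = conc,
                                end_date = ends,
                                live = c(TRUE, TRUE, TRUE, FALSE, NA))
  states <- dplyr::bind_rows(lapply(1:5, function(i) {
    last <- if (is.na(ends[i])) as.Date("1999-12-01") else ends[i]
    months <- seq(lubridate::floor_date(conc[i], "month"),
                  lubridate::floor_date(last, "month"), by = "month")
    tibble::tibble(female_id = ids[i], month = months, state = "pregnant",
                   group_id = "G1")
  }))
  infants <- tibble::tibble(infant_id = character(), mother_id = character(),
                            birth_date = as.Date(character()),
                            death_date = as.Date(character()),
                            observed_until = as.Date(character()))
  repro_records(females, states, pregnancies, infants, toy_census())
}

# six live births: 3 survivors, 1 death at 69 weeks, 1 censored,
# 1 maternal-death exclusion
toy_infant_records <- function() {
  ids <- paste0("F", 1:6)
  females <- tibble::tibble(
    female_id = ids, mother_id = paste0("M", 1:6),
    birth_date = as.Date("1990-06-15") + (1:6),
    death_date = as.Date(c(NA, NA, NA, NA, NA, "1995-08-01")))
  births <- as.Date(c("1995-01-10", "1995-02-10", "1995-03-10",
                      "1995-04-01", "2001-06-01", "1995-06-01"))
  deaths <- as.Date(c(NA, NA, NA, "1996-07-28", NA, "1995-10-01"))
  infants <- tibble::tibble(
    infant_id = paste0("I", 1:6), mother_id = ids,
    birth_date = births, death_date = deaths,
    observed_until = as.Date("2001-12-31"))
  states <- dplyr::bind_rows(lapply(1:6, function(i) {
    months <- seq(lubridate::floor_date(births[i], "month"),
                  by = "month", length.out = 20)
    tibble::tibble(female_id = ids[i], month = months, state = "postpartum",
                   group_id = "G1")
  }))
  pregnancies <- tibble::tibble(female_id = character(),
                                conception_date = as.Date(character()),
                                end_date = as.Date(character()),
                                live = logical())
  repro_records(females, states, pregnancies, infants, toy_census())
}

# random multi-female history driven by a monthly state machine; returns the
# records plus an independently computed walk of the expected conception
# risk set
random_history <- function(seed, n_females = 5, n_months = 30) {
  set.seed(seed)
  ids <- paste0("F", seq_len(n_females))
  start <- as.Date("1995-01-01")
  months <- seq(start, by = "month", length.out = n_months)
  states_l <- list(); preg_l <- list()
  expected <- list()
  for (f in ids) {
    state <- "cycling"
    preg_left <- 0; pp_left <- 0
    for (m in months) {
      m <- as.Date(m, origin = "1970-01-01")
      states_l[[length(states_l) + 1]] <-
        tibble::tibble(female_id = f, month = m, state = state, group_id = "G1")
      conceived <- FALSE
      if (state == "cycling" && stats::runif(1) < 0.25) {
        conceived <- TRUE
        preg_l[[length(preg_l) + 1]] <- tibble::tibble(
          female_id = f, conception_date = m + 14,
          end_date = m + 180, live = TRUE)
      }
      if (state == "cycling") {
        expected[[length(expected) + 1]] <-
          tibble::tibble(female_id = f, month = m,
                         outcome = as.numeric(conceived))
      }
      # advance the state machine
      if (state == "cycling" && conceived) {
        state <- "pregnant"; preg_left <- 6
      } else if (state == "pregnant") {
        preg_left <- preg_left - 1
        if (preg_left <= 0) { state <- "postpartum"; pp_left <- 4 }
      } else if (state == "postpartum") {
        pp_left <- pp_left - 1
        if (pp_left <= 0) state <- "cycling"
      }
    }
  }
  females <- tibble::tibble(female_id = ids, mother_id = paste0("M", seq_len(n_females)),
                            birth_date = as.Date("1989-03-01") + seq_len(n_females),
                            death_date = as.Date(NA))
  infants <- tibble::tibble(infant_id = character(), mother_id = character(),
                            birth_date = as.Date(character()),
                            death_date = as.Date(character()),
                            observed_until = as.Date(character()))
  list(records = repro_records(females, dplyr::bind_rows(states_l),
                               dplyr::bind_rows(preg_l), infants,
                               toy_census(to = "2001-12")),
       expected_conception = dplyr::bind_rows(expected))
}

all_toy_ids <- function() c(paste0("F", 1:6), paste0("M", 1:6))
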