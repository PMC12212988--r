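#' Structured longitudinal reproductive records
#'
#' Container for the raw observational inputs from which the risk-set
#' analysis tables are built. Five tables:
#'
#' * `females`: `female_id`, `mother_id`, `birth_date`, `death_date`
#'   (`NA` if alive / still observed).
#' * `states`: one row per female-month with the reproductive state on
#'   the first day of the month (`cycling`, `pregnant`, `postpartum`)
#'   and the female's social group that month.
#' * `pregnancies`: `female_id`, `conception_date`, `end_date` (`NA`
#'   while in progress), `live` (logical; `NA` while in progress).
#' * `infants`: `infant_id`, `mother_id`, `birth_date`, `death_date`
#'   (`NA` if not observed to die), `observed_until` (last date the
#'   infant's status is known).
#' * `census`: `group_id`, `month`, `size` — the mean number of group
#'   members per day in that month.
#'
#' @param females,states,pregnancies,infants,census Data frames as above.
#' @return A list with class `repro_records`.
#' @export
repro_records <- function(females, states, pregnancies, infants, census) {
  females <- tibble::as_tibble(females)
  states <- tibble::as_tibble(states)
  pregnancies <- tibble::as_tibble(pregnancies)
  infants <- tibble::as_tibble(infants)
  census <- tibble::as_tibble(census)

  females$birth_date <- as.Date(females$birth_date)
  females$death_date <- as.Date(females$death_date)
  states$month <- as_month(states$month)
  pregnancies$conception_date <- as.Date(pregnancies$conception_date)
  pregnancies$end_date <- as.Date(pregnancies$end_date)
  infants$birth_date <- as.Date(infants$birth_date)
  infants$death_date <- as.Date(infants$death_date)
  infants$observed_until <- as.Date(infants$observed_until)
  census$month <- as_month(census$month)

  if (!all(states$state %in% c("cycling", "pregnant", "postpartum"))) {
    stop("reproductive states must be cycling / pregnant / postpartum.", call. = FALSE)
  }
  if (anyDuplicated(states[c("female_id", "month")]) > 0) {
    stop("states must partition female-months: duplicate female-month found.",
         call. = FALSE)
  }
  done <- !is.na(pregnancies$end_date)
  if (any(done & pregnancies$end_date < pregnancies$conception_date)) {
    stop("pregnancy end precedes its conception date.", call. = FALSE)
  }
  if (any(!is.na(infants$death_date) &
          infants$death_date < infants$birth_date)) {
    stop("infant death date precedes birth date.", call. = FALSE)
  }

  structure(list(females = females, states = states,
                 pregnancies = pregnancies, infants = infants,
                 census = census),
            class = "repro_records")
}

#' Read reproductive events from a typed long-format CSV
#'
#' One CSV holds all reproductive events with columns `female_id`,
#' `record_type`, `date`, `value`, `group_id`. Recognised record types:
#' `female_birth` (`value` = mother id), `female_death`, `state`
#' (`value` = cycling/pregnant/postpartum, `group_id` set), `conception`,
#' `pregnancy_end` (`value` = live/loss), `infant_birth` /
#' `infant_death` / `infant_censor` (`value` = infant id). Each
#' `pregnancy_end` is matched to the female's most recent preceding
#' conception; a `pregnancy_end` with no preceding conception is a
#' data-integrity error. `census` is supplied separately.
#'
#' @param events Data frame (or CSV path) in the long format above.
#' @param census Data frame (or CSV path) with `group_id`, `year_month`
#'   (`"YYYY-MM"`) or `month`, and `size`.
#' @return A [repro_records()] object.
#' @export
read_repro_events <- function(events, census) {
  if (is.character(events)) events <- utils::read.csv(events, stringsAsFactors = FALSE)
  if (is.character(census)) census <- utils::read.csv(census, stringsAsFactors = FALSE)
  events <- tibble::as_tibble(events)
  events$date <- as.Date(events$date)
  known <- c("female_birth", "female_death", "state", "conception",
             "pregnancy_end", "infant_birth", "infant_death", "infant_censor")
  bad <- setdiff(unique(events$record_type), known)
  if (length(bad) > 0) {
    stop("unknown record_type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }

  take <- function(type) events[events$record_type == type, , drop = FALSE]

  fb <- take("female_birth")
  fd <- take("female_death")
  females <- tibble::tibble(
    female_id = fb$female_id,
    mother_id = fb$value,
    birth_date = fb$date,
    death_date = as.Date(fd$date[match(fb$female_id, fd$female_id)])
  )

  st <- take("state")
  states <- tibble::tibble(female_id = st$female_id, month = as_month(st$date),
                           state = st$value, group_id = st$group_id)

  # pair each pregnancy end with the female's latest preceding conception
  co <- take("conception")
  pe <- take("pregnancy_end")
  preg_females <- union(unique(co$female_id), unique(pe$female_id))
  pregnancies <- dplyr::bind_rows(lapply(preg_females, function(f) {
    cdates <- sort(co$date[co$female_id == f])
    edates <- sort(pe$date[pe$female_id == f])
    evals <- pe$value[pe$female_id == f][order(pe$date[pe$female_id == f])]
    if (length(edates) > length(cdates)) {
      stop("pregnancy end without a conception date for female ", f, call. = FALSE)
    }
    tibble::tibble(
      female_id = f,
      conception_date = cdates,
      end_date = c(edates, rep(as.Date(NA), length(cdates) - length(edates))),
      live = c(evals == "live", rep(NA, length(cdates) - length(edates)))
    )
  }))
  if (nrow(pregnancies) == 0) {
    pregnancies <- tibble::tibble(female_id = character(),
                                  conception_date = as.Date(character()),
                                  end_date = as.Date(character()),
                                  live = logical())
  }
  if (nrow(pregnancies) > 0 &&
      any(!is.na(pregnancies$end_date) &
          pregnancies$end_date < pregnancies$conception_date)) {
    stop("pregnancy end precedes its conception date.", call. = FALSE)
  }

  ib <- take("infant_birth")
  id <- take("infant_death")
  ic <- take("infant_censor")
  infants <- tibble::tibble(
    infant_id = ib$value,
    mother_id = ib$female_id,
    birth_date = ib$date,
    death_date = as.Date(id$date[match(ib$value, id$value)]),
    observed_until = as.Date(ic$date[match(ib$value, ic$value)])
  )
  infants$observed_until[is.na(infants$observed_until)] <-
    pmax(infants$birth_date, max(events$date), na.rm = TRUE)[
      is.na(infants$observed_until)]

  if (!"month" %in% names(census) && "year_month" %in% names(census)) {
    census$month <- census$year_month
  }
  census <- tibble::tibble(group_id = census$group_id,
                           month = as_month(census$month),
                           size = as.numeric(census$size))

  repro_records(females, states, pregnancies, infants, census)
}

#' Validate raw input tables against the documented schema
#'
#' Checks the four delimited inputs (rainfall, ranks, reproductive
#' events, group census) and reports all violations rather than stopping
#' at the first.
#'
#' @param rain,ranks,events,census Data frames (any may be `NULL` to skip).
#' @return A tibble with columns `table`, `check`, `detail`; zero rows
#'   means all supplied inputs validate.
#' @export
validate_inputs <- function(rain = NULL, ranks = NULL, events = NULL,
                            census = NULL) {
  v <- list()
  note <- function(tab, check, detail) {
    v[[length(v) + 1]] <<- tibble::tibble(table = tab, check = check,
                                          detail = detail)
  }
  if (!is.null(rain)) {
    if (!all(c("date", "rain_mm") %in% names(rain))) {
      note("rain", "columns", "need date, rain_mm")
    } else {
      d <- suppressWarnings(as.Date(as.character(rain$date)))
      if (anyNA(d)) note("rain", "date_parse", "unparseable ISO-8601 date")
      else if (is.unsorted(d, strictly = TRUE)) {
        note("rain", "date_order", "dates not strictly increasing")
      }
      if (any(rain$rain_mm < 0, na.rm = TRUE)) note("rain", "range", "negative rainfall")
      if (anyNA(rain$rain_mm)) note("rain", "missing", "NA rainfall values")
    }
  }
  if (!is.null(ranks)) {
    needed <- c("female_id", "year_month", "rank")
    if (!all(needed %in% names(ranks))) {
      note("ranks", "columns", paste("need", paste(needed, collapse = ", ")))
    } else {
      if (any(ranks$rank < 0 | ranks$rank > 1, na.rm = TRUE)) {
        note("ranks", "range", "rank outside [0, 1]")
      }
      if (anyDuplicated(ranks[c("female_id", "year_month")]) > 0) {
        note("ranks", "uniqueness", "duplicate female-month")
      }
    }
  }
  if (!is.null(events)) {
    needed <- c("female_id", "record_type", "date", "value", "group_id")
    if (!all(needed %in% names(events))) {
      note("events", "columns", paste("need", paste(needed, collapse = ", ")))
    } else {
      ok <- tryCatch({
        read_repro_events(events,
                          census %||% tibble::tibble(group_id = character(),
                                                     month = character(),
                                                     size = numeric()))
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) note("events", "integrity", ok)
    }
  }
  if (!is.null(census)) {
    if (!all(c("group_id", "size") %in% names(census)) ||
        !any(c("month", "year_month") %in% names(census))) {
      note("census", "columns", "need group_id, year_month (or month), size")
    } else if (any(census$size <= 0, na.rm = TRUE)) {
      note("census", "range", "non-positive group size")
    }
  }
  if (length(v) == 0) {
    tibble::tibble(table = character(), check = character(), detail = character())
  } else {
    dplyr::bind_rows(v)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- internal helpers shared by the three builders ----------------------

na_or <- function(expr) tryCatch(expr, error = function(e) NA_real_)

# developmental environment, computed once per female
dev_environment <- function(records, female, env, rain, ranks) {
  fem <- records$females[records$females$female_id == female, ]
  if (nrow(fem) != 1 || is.na(fem$birth_date)) return(NA_real_)
  if (env == "rain") {
    na_or(rain_development(rain, fem$birth_date))
  } else {
    if (is.na(fem$mother_id)) return(NA_real_)
    na_or(rank_window_3mo(ranks, fem$mother_id, fem$birth_date))
  }
}

# the female's group in a given month (falls back to latest earlier month)
female_group <- function(states, female, month) {
  s <- states[states$female_id == female, ]
  hit <- s$group_id[s$month == month]
  if (length(hit) == 1) return(hit)
  prior <- s[s$month < month, ]
  if (nrow(prior) == 0) return(NA_character_)
  prior$group_id[which.max(as.numeric(prior$month))]
}

# mean daily group size over a span of months (gap tolerant; NA if empty)
span_group_size <- function(records, female, months) {
  sizes <- vapply(months, function(m) {
    g <- female_group(records$states, female, m)
    if (is.na(g)) return(NA_real_)
    sz <- records$census$size[records$census$group_id == g &
                                records$census$month == m]
    if (length(sz) == 1) sz else NA_real_
  }, numeric(1))
  if (all(is.na(sizes))) NA_real_ else mean(sizes, na.rm = TRUE)
}

age_years <- function(birth, at) as.numeric(as.Date(at) - as.Date(birth)) / 365.25

assemble_table <- function(rows, drops, outcome_kind, environment_kind) {
  drops <- if (length(drops) == 0) NULL else dplyr::bind_rows(drops)
  if (length(rows) == 0) {
    rows <- tibble::tibble(female_id = character(), group_id = character(),
                           event_time = as.Date(character()), outcome = numeric(),
                           e0 = numeric(), e1 = numeric(), delta = numeric(),
                           abs_delta = numeric(), age = numeric(),
                           age_sq = numeric(), group_size = numeric())
  } else {
    rows <- dplyr::bind_rows(rows)
  }
  analysis_table(rows, outcome_kind = outcome_kind,
                 environment_kind = environment_kind, drop_log = drops)
}

build_row <- function(female, group, time, outcome, e0, e1, age, gsize) {
  d <- compute_delta(e0, e1)
  # canonicalise so e0 + delta == e1 bit-exactly
  e1 <- e0 + d$delta
  tibble::tibble(female_id = female, group_id = group, event_time = time,
                 outcome = outcome, e0 = e0, e1 = e1, delta = d$delta,
                 abs_delta = d$abs_delta, age = age, age_sq = age^2,
                 group_size = gsize)
}

# ---- the three risk-set builders ----------------------------------------

#' Build the conception risk-set table
#'
#' One record per female-month in which the female was cycling on the
#' first day of the month (months beginning pregnant or in postpartum
#' amenorrhea are excluded from the risk set). The outcome is 1 iff a
#' conception occurred in that month. The adult environment is the mean
#' rank over the three-month window centred on the cycling month (rank)
#' or the mean monthly rainfall over the year before the cycling month
#' (rain). Records with an unavailable developmental or adult
#' environment, or no group-size data, are dropped and logged.
#'
#' @param records A [repro_records()] object.
#' @param env `"rank"` or `"rain"`.
#' @param rain A [rain_series()] (required when `env = "rain"` and for
#'   rain developmental environments).
#' @param ranks A [rank_series()] (required when `env = "rank"`).
#' @return An [analysis_table()] with `outcome_kind = "conception"`.
#' @export
build_conception_table <- function(records, env = c("rank", "rain"),
                                   rain = NULL, ranks = NULL) {
  env <- match.arg(env)
  cyc <- records$states[records$states$state == "cycling", ]
  rows <- list(); drops <- list()
  e0_cache <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(cyc))) {
    f <- cyc$female_id[i]; m <- cyc$month[i]
    unit <- paste0(f, ":", format(m, "%Y-%m"))
    e0 <- get0(f, envir = e0_cache, ifnotfound = NULL)
    if (is.null(e0)) {
      e0 <- dev_environment(records, f, env, rain, ranks)
      assign(f, e0, envir = e0_cache)
    }
    if (is.na(e0)) {
      drops[[length(drops) + 1]] <- tibble::tibble(
        female_id = f, unit = unit,
        reason = if (env == "rank") "missing_rank_window" else "missing_environment")
      next
    }
    e1 <- if (env == "rank") na_or(rank_window_3mo(ranks, f, m)) else
      na_or(rain_adult(rain, m))
    if (is.na(e1)) {
      drops[[length(drops) + 1]] <- tibble::tibble(
        female_id = f, unit = unit,
        reason = if (env == "rank") "missing_rank_window" else "missing_environment")
      next
    }
    gsize <- span_group_size(records, f, m)
    if (is.na(gsize)) {
      drops[[length(drops) + 1]] <- tibble::tibble(female_id = f, unit = unit,
                                                   reason = "missing_group_size")
      next
    }
    p <- records$pregnancies
    conceived <- any(p$female_id == f &
                       p$conception_date >= m &
                       p$conception_date < add_months(m, 1L))
    birth <- records$females$birth_date[records$females$female_id == f]
    rows[[length(rows) + 1]] <- build_row(
      f, cyc$group_id[i], m, as.numeric(conceived),
      e0, e1, age_years(birth, m), gsize)
  }
  assemble_table(rows, drops, "conception", env)
}

#' Build the live-birth risk-set table
#'
#' One record per completed pregnancy; the outcome is 1 iff it ended in
#' a live birth. In-progress (censored) pregnancies are dropped and
#' logged. The adult environment is the mean rank over the months of the
#' pregnancy (rank) or the mean monthly rainfall in the year before the
#' pregnancy end date (rain).
#'
#' @inheritParams build_conception_table
#' @return An [analysis_table()] with `outcome_kind = "live_birth"`.
#' @export
build_livebirth_table <- function(records, env = c("rank", "rain"),
                                  rain = NULL, ranks = NULL) {
  env <- match.arg(env)
  preg <- records$pregnancies
  if (nrow(preg) > 0 && anyNA(preg$conception_date)) {
    stop("pregnancy without a conception date.", call. = FALSE)
  }
  rows <- list(); drops <- list()
  e0_cache <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(preg))) {
    f <- preg$female_id[i]
    unit <- paste0(f, ":preg:", format(preg$conception_date[i]))
    if (is.na(preg$end_date[i])) {
      drops[[length(drops) + 1]] <- tibble::tibble(female_id = f, unit = unit,
                                                   reason = "censored")
      next
    }
    e0 <- get0(f, envir = e0_cache, ifnotfound = NULL)
    if (is.null(e0)) {
      e0 <- dev_environment(records, f, env, rain, ranks)
      assign(f, e0, envir = e0_cache)
    }
    months <- seq(as_month(preg$conception_date[i]),
                  as_month(preg$end_date[i]), by = "month")
    e1 <- if (env == "rank") na_or(rank_window_mean(ranks, f, months)) else
      na_or(rain_adult(rain, preg$end_date[i]))
    if (is.na(e0) || is.na(e1)) {
      drops[[length(drops) + 1]] <- tibble::tibble(
        female_id = f, unit = unit,
        reason = if (env == "rank") "missing_rank_window" else "missing_environment")
      next
    }
    gsize <- span_group_size(records, f, months)
    if (is.na(gsize)) {
      drops[[length(drops) + 1]] <- tibble::tibble(female_id = f, unit = unit,
                                                   reason = "missing_group_size")
      next
    }
    birth <- records$females$birth_date[records$females$female_id == f]
    grp <- female_group(records$states, f, as_month(preg$end_date[i]))
    rows[[length(rows) + 1]] <- build_row(
      f, grp, as_month(preg$end_date[i]), as.numeric(preg$live[i]),
      e0, e1, age_years(birth, preg$end_date[i]), gsize)
  }
  assemble_table(rows, drops, "live_birth", env)
}

#' Build the infant-survival risk-set table
#'
#' One record per live birth; the outcome is 1 iff the infant was still
#' alive at 70 weeks (490 days, the average weaning age). Infants whose
#' status at 70 weeks is unknown (still under 70 weeks when observation
#' ends) are dropped as censored; records where the mother died before
#' the infant's outcome was determined are excluded, because early
#' maternal loss itself strongly predicts infant death. The adult
#' environment is aggregated over the year before the infant dies or
#' reaches 70 weeks (monthly mean rank, or mean monthly rainfall).
#'
#' @inheritParams build_conception_table
#' @return An [analysis_table()] with `outcome_kind = "infant_survival"`.
#' @export
build_infantsurvival_table <- function(records, env = c("rank", "rain"),
                                       rain = NULL, ranks = NULL) {
  env <- match.arg(env)
  inf <- records$infants
  rows <- list(); drops <- list()
  e0_cache <- new.env(parent = emptyenv())

  for (i in seq_len(nrow(inf))) {
    f <- inf$mother_id[i]
    unit <- paste0(f, ":infant:", inf$infant_id[i])
    due <- inf$birth_date[i] + 490L # 70 weeks
    died_early <- !is.na(inf$death_date[i]) && inf$death_date[i] < due
    if (died_early) {
      outcome <- 0; anchor <- inf$death_date[i]
    } else if (inf$observed_until[i] >= due ||
               (!is.na(inf$death_date[i]) && inf$death_date[i] >= due)) {
      outcome <- 1; anchor <- due
    } else {
      drops[[length(drops) + 1]] <- tibble::tibble(female_id = f, unit = unit,
                                                   reason = "censored")
      next
    }
    mdeath <- records$females$death_date[records$females$female_id == f]
    if (length(mdeath) == 1 && !is.na(mdeath) && mdeath < anchor) {
      drops[[length(drops) + 1]] <- tibble::tibble(female_id = f, unit = unit,
                                                   reason = "maternal_death")
      next
    }
    e0 <- get0(f, envir = e0_cache, ifnotfound = NULL)
    if (is.null(e0)) {
      e0 <- dev_environment(records, f, env, rain, ranks)
      assign(f, e0, envir = e0_cache)
    }
    year_before <- add_months(as_month(anchor), -(12:1))
    e1 <- if (env == "rank") na_or(rank_window_mean(ranks, f, year_before)) else
      na_or(rain_adult(rain, anchor))
    if (is.na(e0) || is.na(e1)) {
      drops[[length(drops) + 1]] <- tibble::tibble(
        female_id = f, unit = unit,
        reason = if (env == "rank") "missing_rank_window" else "missing_environment")
      next
    }
    life_months <- seq(as_month(inf$birth_date[i]), as_month(anchor), by = "month")
    gsize <- span_group_size(records, f, life_months)
    if (is.na(gsize)) {
      drops[[length(drops) + 1]] <- tibble::tibble(female_id = f, unit = unit,
                                                   reason = "missing_group_size")
      next
    }
    mbirth <- records$females$birth_date[records$females$female_id == f]
    grp <- female_group(records$states, f, as_month(inf$birth_date[i]))
    rows[[length(rows) + 1]] <- build_row(
      f, grp, as_month(anchor), outcome,
      e0, e1, age_years(mbirth, inf$birth_date[i]), gsize)
  }
  assemble_table(rows, drops, "infant_survival", env)
}
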