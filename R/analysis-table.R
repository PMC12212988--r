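#' Analysis tables: conditional risk-set observations
#'
#' An `analysis_table` is a tibble of risk-set observations, one per
#' eligible unit (cycling female-month, completed pregnancy, or live birth),
#' carrying the developmental environment `e0`, the adult environment `e1`,
#' their difference `delta = e1 - e0`, the mismatch magnitude
#' `abs_delta = |delta|`, and the covariates used by the quadratic model
#' (age, age squared, mean group size). The table remembers which outcome
#' and which environmental variable it describes.
#'
#' @param records A data frame with columns `female_id`, `group_id`,
#'   `event_time`, `outcome`, `e0`, `e1`, `delta`, `abs_delta`, `age`,
#'   `age_sq`, `group_size`.
#' @param outcome_kind One of `"conception"`, `"live_birth"`,
#'   `"infant_survival"`, or `"synthetic"` (generator output).
#' @param environment_kind `"rank"` (proportional dominance rank in `[0,1]`)
#'   or `"rain"` (mm per month).
#' @param drop_log Optional tibble of records dropped while building the
#'   table, with a machine-readable `reason` column.
#'
#' @return A tibble with class `analysis_table` and attributes
#'   `outcome_kind`, `environment_kind`, `drop_log`.
#' @export
analysis_table <- function(records,
                           outcome_kind = c("conception", "live_birth",
                                            "infant_survival", "synthetic"),
                           environment_kind = c("rank", "rain"),
                           drop_log = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  environment_kind <- match.arg(environment_kind)
  records <- tibble::as_tibble(records)

  required <- c("female_id", "group_id", "event_time", "outcome",
                "e0", "e1", "delta", "abs_delta", "age", "age_sq", "group_size")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("analysis_table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  if (nrow(records) > 0) {
    if (!all(records$outcome %in% c(0, 1))) {
      stop("`outcome` must be binary (0/1).", call. = FALSE)
    }
    if (!isTRUE(all(records$e0 + records$delta == records$e1))) {
      stop("invariant violated: e0 + delta must equal e1 exactly.", call. = FALSE)
    }
    if (!isTRUE(all(records$abs_delta == abs(records$delta)))) {
      stop("invariant violated: abs_delta must equal |delta| exactly.", call. = FALSE)
    }
    if (environment_kind == "rank" &&
        (any(records$e0 < 0 | records$e0 > 1) ||
         any(records$e1 < 0 | records$e1 > 1))) {
      stop("rank environments must lie in [0, 1].", call. = FALSE)
    }
    if (any(records$e0 < 0) || any(records$e1 < 0)) {
      stop("environment values must be non-negative.", call. = FALSE)
    }
    if (any(records$age <= 0)) {
      stop("`age` must be positive.", call. = FALSE)
    }
  }

  if (is.null(drop_log)) {
    drop_log <- tibble::tibble(female_id = character(), unit = character(),
                               reason = character())
  }

  structure(records,
            class = c("analysis_table", class(tibble::tibble())),
            outcome_kind = outcome_kind,
            environment_kind = environment_kind,
            drop_log = tibble::as_tibble(drop_log))
}

#' @export
print.analysis_table <- function(x, ...) {
  cat(sprintf("<analysis_table> outcome: %s | environment: %s | %d records (%d dropped)\n",
              attr(x, "outcome_kind"), attr(x, "environment_kind"),
              nrow(x), nrow(attr(x, "drop_log"))))
  NextMethod()
}

#' Outcome / environment kind of an analysis table
#' @param table An `analysis_table`.
#' @return A string.
#' @export
outcome_kind <- function(table) attr(table, "outcome_kind")

#' @rdname outcome_kind
#' @export
environment_kind <- function(table) attr(table, "environment_kind")

#' Drop log of an analysis table
#'
#' Records excluded during panel construction, with machine-readable
#' reason codes (`censored`, `maternal_death`, `missing_environment`,
#' `missing_rank_window`, `missing_group_size`, `single_observation`).
#'
#' @param table An `analysis_table`.
#' @return A tibble with columns `female_id`, `unit`, `reason`.
#' @export
drop_log <- function(table) attr(table, "drop_log")

#' Write / read an analysis table as CSV
#'
#' The CSV carries the exact `analysis_table` column set; outcome and
#' environment kinds travel in `# key: value` header comment lines so a
#' round trip preserves them. The drop log is written alongside as
#' `<path>_drops.csv` when non-empty.
#'
#' @param table An `analysis_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_analysis_table <- function(table, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines(c(paste0("# outcome_kind: ", outcome_kind(table)),
               paste0("# environment_kind: ", environment_kind(table))), con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  dl <- drop_log(table)
  if (nrow(dl) > 0) {
    utils::write.csv(as.data.frame(dl),
                     sub("\\.csv$", "_drops.csv", path), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_analysis_table
#' @export
read_analysis_table <- function(path) {
  header <- readLines(path, n = 2L)
  meta <- function(key) sub(paste0("^# ", key, ": "), "", grep(key, header, value = TRUE))
  records <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  analysis_table(records,
                 outcome_kind = meta("outcome_kind"),
                 environment_kind = meta("environment_kind"))
}

#' Environment deltas
#'
#' The mismatch between the adult and developmental environments:
#' `delta = e1 - e0` and its magnitude `abs_delta = |delta|`. Both inputs
#' must be on the same scale (both rank proportions or both mm/month);
#' mixing units is a type error.
#'
#' @param e0 Developmental environment value(s).
#' @param e1 Adult environment value(s), same units as `e0`.
#' @param units0,units1 Optional unit labels (`"rank"` or `"rain"`); when
#'   both are given they must agree.
#' @return A list with numeric components `delta` and `abs_delta`.
#' @export
#' @examples
#' compute_delta(0.2, 0.7) # delta 0.5, abs_delta 0.5
compute_delta <- function(e0, e1, units0 = NULL, units1 = NULL) {
  if (!is.null(units0) && !is.null(units1) && !identical(units0, units1)) {
    stop("unit mismatch: e0 is in '", units0, "' but e1 is in '", units1, "'.",
         call. = FALSE)
  }
  if (!is.numeric(e0) || !is.numeric(e1)) {
    stop("e0 and e1 must be numeric.", call. = FALSE)
  }
  delta <- e1 - e0
  list(delta = delta, abs_delta = abs(delta))
}
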