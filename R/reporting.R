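test_grid <- function(include_not_estimable = FALSE) {
  grid <- tibble::tibble(
    hypothesis = c("DC", "AR", "AR", if (include_not_estimable) "DC"),
    fixed_effect = c("group", "group", "individual",
                     if (include_not_estimable) "individual"))
  grid
}

#' Run the full battery of derivative tests
#'
#' Orchestrates the whole analysis: for each analysis table, fits the
#' quadratic model under each requested fixed-effect specification, runs
#' the developmental-constraints test (group fixed effects only — e0 is
#' absorbed by individual fixed effects) and the adaptive-response test
#' (both specifications), then computes sharpened two-stage q-values
#' over the whole family of tests. With the default three outcomes and
#' two environments this is the 18-test family (3 outcomes x (2 DC +
#' 4 AR)).
#'
#' @param tables Either a named list of [analysis_table()]s (names
#'   become row labels) or a [synth_config()], in which case one
#'   synthetic panel is generated per outcome x environment combination
#'   (seeds derived from the config seed).
#' @param alpha Level for the theory-consistency flag.
#' @param q_grid_step Grid for [sharpened_qvalues()].
#' @param include_not_estimable Also emit rows for the DC test under
#'   individual fixed effects, marked not estimable (`NA` estimate with
#'   a reason) instead of being silently omitted.
#' @return A list with class `results_bundle`: `results` (one row per
#'   test with estimate, se, statistic, p, q, consistency flag and
#'   Table-style context columns: sample means and sds of the outcome,
#'   `e0` and `|delta|`), `coefficients` (stacked [tidy_fit()] tables),
#'   `qvalues`, `drop_logs`, `tables`.
#' @export
run_full_analysis <- function(tables, alpha = 0.05, q_grid_step = 0.001,
                              include_not_estimable = FALSE) {
  if (inherits(tables, "synth_config")) {
    cfg <- tables
    base_seed <- cfg$seed %||% 1L
    outcomes <- c("conception", "live_birth", "infant_survival")
    envs <- c("rank", "rain")
    tables <- list()
    k <- 0L
    for (ok_ in outcomes) for (ev in envs) {
      k <- k + 1L
      cfg_i <- cfg
      cfg_i$seed <- base_seed + k
      cfg_i$e0_distribution <- ev
      tables[[paste(ok_, ev, sep = ":")]] <-
        suppressWarnings(simulate_panel(cfg_i, outcome_kind = ok_))
    }
  }
  stopifnot(is.list(tables), length(tables) > 0)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("table", seq_along(tables))
  }

  grid <- test_grid(include_not_estimable)
  rows <- list(); coefs <- list(); drops <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    df <- tibble::as_tibble(tab)
    context <- tibble::tibble(
      y_mean = mean(df$outcome), y_sd = stats::sd(df$outcome),
      e0_mean = mean(df$e0), e0_sd = stats::sd(df$e0),
      absd_mean = mean(df$abs_delta), absd_sd = stats::sd(df$abs_delta))
    fits <- list()
    for (fe in unique(grid$fixed_effect)) {
      fits[[fe]] <- tryCatch(
        suppressMessages(fit_quadratic(tab, model_spec(fe))),
        error = function(e) e)
    }
    for (j in seq_len(nrow(grid))) {
      hyp <- grid$hypothesis[j]; fe <- grid$fixed_effect[j]
      label <- paste(nm, hyp, fe, sep = ":")
      fit <- fits[[fe]]
      res <- if (inherits(fit, "error")) fit else
        tryCatch(test_derivative(fit, hyp, alpha = alpha),
                 error = function(e) e)
      if (inherits(res, "error")) {
        rows[[label]] <- dplyr::bind_cols(
          tibble::tibble(label = label, table = nm, hypothesis = hyp,
                         fixed_effect = fe, estimate = NA_real_,
                         se = NA_real_, statistic = NA_real_,
                         p_value = NA_real_, consistent = NA,
                         n_obs = nrow(df),
                         n_clusters = length(unique(df$female_id)),
                         status = paste("not_estimable:", conditionMessage(res))),
          context)
      } else {
        rows[[label]] <- dplyr::bind_cols(
          tibble::tibble(label = label, table = nm, hypothesis = hyp,
                         fixed_effect = fe, estimate = res$estimate,
                         se = res$se, statistic = res$statistic,
                         p_value = res$p_value,
                         consistent = res$consistent_with_theory,
                         n_obs = fit$n_obs, n_clusters = fit$n_clusters,
                         status = "ok"),
          context)
      }
    }
    for (fe in names(fits)) {
      if (!inherits(fits[[fe]], "error")) {
        coefs[[paste(nm, fe, sep = ":")]] <-
          dplyr::mutate(tidy_fit(fits[[fe]]),
                        table = nm, fixed_effect = fe, .before = 1)
      }
    }
    dl <- drop_log(tab)
    if (!is.null(dl) && nrow(dl) > 0) {
      drops[[nm]] <- dplyr::mutate(dl, table = nm, .before = 1)
    }
  }
  results <- dplyr::bind_rows(rows)

  tested <- !is.na(results$p_value)
  qvalues <- NULL
  if (sum(tested) >= 2) {
    p <- stats::setNames(results$p_value[tested], results$label[tested])
    q <- sharpened_qvalues(p, grid_step = q_grid_step)
    results$q_value <- NA_real_
    results$q_value[tested] <- unname(q[results$label[tested]])
    qvalues <- tibble::tibble(test_label = names(q), p = unname(p),
                              q = unname(q))
  }

  structure(list(results = results,
                 coefficients = dplyr::bind_rows(coefs),
                 qvalues = qvalues,
                 drop_logs = dplyr::bind_rows(drops),
                 tables = tables,
                 alpha = alpha),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat(sprintf("<results_bundle> %d tests over %d table(s)\n",
              nrow(x$results), length(x$tables)))
  cols <- intersect(c("table", "hypothesis", "fixed_effect", "estimate",
                      "p_value", "q_value"), names(x$results))
  print(as.data.frame(x$results[cols]), digits = 4)
  invisible(x)
}

#' Write a results bundle to CSV files
#'
#' Writes `results.csv`, `coefficients.csv`, `qvalues.csv` and
#' `drop_log.csv` (the latter two only when non-empty) into `dir`.
#' Outputs are deterministic: identical bundles produce byte-identical
#' files.
#'
#' @param bundle A [run_full_analysis()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    utils::write.csv(as.data.frame(df), file.path(dir, name), row.names = FALSE)
  }
  wr(bundle$results, "results.csv")
  wr(bundle$coefficients, "coefficients.csv")
  if (!is.null(bundle$qvalues)) wr(bundle$qvalues, "qvalues.csv")
  if (!is.null(bundle$drop_logs) && nrow(bundle$drop_logs) > 0) {
    wr(bundle$drop_logs, "drop_log.csv")
  }
  invisible(dir)
}

#' Equal-count binned scatter with quadratic fit
#'
#' Sorts records by `x`, splits them into `n_bins` equal-count bins
#' (when the count does not divide evenly, the remainder is spread one
#' extra record each over the leading bins), and returns per-bin means
#' of `x` and the raw outcome, together with an unadjusted quadratic
#' least-squares fit of the outcome on `x`. With 933 records and 50
#' bins, bins hold 18 or 19 records each.
#'
#' @param table An [analysis_table()] (or plain data frame with an
#'   `outcome` column).
#' @param x Column to bin on (default the signed `delta`; `abs_delta`
#'   is also accepted — the choice is recorded in the result).
#' @param n_bins Number of bins (reduced with a warning when the table
#'   has fewer records).
#' @return A list with class `binned_scatter`: `bins` (tibble `bin`,
#'   `n`, `x_mean`, `y_mean`), `fit` (quadratic coefficients), `x_var`.
#' @export
binned_scatter <- function(table, x = "delta", n_bins = 50L) {
  df <- tibble::as_tibble(table)
  n <- nrow(df)
  if (n < n_bins) {
    warning(sprintf("only %d records; reducing bin count from %d.", n, n_bins),
            call. = FALSE)
    n_bins <- n
  }
  ord <- order(df[[x]])
  xs <- df[[x]][ord]
  ys <- df$outcome[ord]
  n_bins <- as.integer(n_bins)
  base <- as.integer(n %/% n_bins)
  rem <- as.integer(n %% n_bins)
  sizes <- base + c(rep(1L, rem), rep(0L, n_bins - rem))
  bin_of <- rep(seq_len(n_bins), sizes)
  bins <- tibble::tibble(bin = seq_len(n_bins),
                         n = sizes,
                         x_mean = as.vector(tapply(xs, bin_of, mean)),
                         y_mean = as.vector(tapply(ys, bin_of, mean)))
  quad <- stats::lm(ys ~ xs + I(xs^2))
  fit <- stats::setNames(stats::coef(quad), c("intercept", "linear", "quadratic"))
  structure(list(bins = bins, fit = fit, x_var = x), class = "binned_scatter")
}

#' ggplot of a binned scatter with its quadratic fit line
#' @param bs A [binned_scatter()] result.
#' @return A ggplot object.
#' @export
plot_binned_scatter <- function(bs) {
  b <- bs$fit
  ggplot2::ggplot(bs$bins, ggplot2::aes(x = .data$x_mean, y = .data$y_mean)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_function(fun = function(x) b[1] + b[2] * x + b[3] * x^2,
                           colour = "steelblue") +
    ggplot2::labs(x = bs$x_var, y = "mean outcome",
                  title = "Binned raw data with quadratic fit") +
    ggplot2::theme_minimal()
}

#' Signed-delta histogram with zero-centred bins
#'
#' Histogram of the signed environment deltas using bins centred on
#' zero (the central bin straddles a delta of exactly 0, i.e. a perfect
#' developmental/adult match).
#'
#' @param table An [analysis_table()].
#' @param bin_width Bin width; default Freedman-Diaconis (falling back
#'   to a single bin when the deltas are constant).
#' @return A tibble with class `delta_histogram`: `lower`, `upper`,
#'   `mid`, `count`; counts sum to the number of records.
#' @export
delta_histogram <- function(table, bin_width = NULL) {
  df <- tibble::as_tibble(table)
  if (nrow(df) == 0) stop("table is empty.", call. = FALSE)
  d <- df$delta
  if (is.null(bin_width)) {
    iqr <- stats::IQR(d)
    bin_width <- if (iqr > 0) 2 * iqr / length(d)^(1 / 3) else
      max(1, 2 * max(abs(d)))
  }
  w <- bin_width
  idx <- floor(d / w + 0.5) # bin i covers [i*w - w/2, i*w + w/2)
  rng <- range(idx)
  all_idx <- rng[1]:rng[2]
  counts <- as.vector(table(factor(idx, levels = all_idx)))
  out <- tibble::tibble(lower = all_idx * w - w / 2,
                        upper = all_idx * w + w / 2,
                        mid = all_idx * w,
                        count = counts)
  structure(out, class = c("delta_histogram", class(out)))
}

#' ggplot of a delta histogram
#' @param h A [delta_histogram()] result.
#' @return A ggplot object.
#' @export
plot_delta_histogram <- function(h) {
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = h$upper[1] - h$lower[1], fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "delta (adult - developmental environment)",
                  y = "count") +
    ggplot2::theme_minimal()
}
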