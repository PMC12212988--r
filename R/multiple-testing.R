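#' Two-stage sharpened FDR step-up procedure
#'
#' Benjamini–Krieger–Yekutieli two-stage step-up at false-discovery-rate
#' level `q`. Stage 1 runs a linear step-up at the deflated level
#' `q' = q / (1 + q)`; the number of stage-1 rejections r1 estimates the
#' number of true nulls as `m - r1`, and stage 2 re-runs the step-up at
#' the sharpened level `q' * m / (m - r1)`. With no stage-1 rejections
#' the procedure stops and rejects nothing; with all hypotheses rejected
#' in stage 1 it rejects everything.
#'
#' @param pvals Named numeric vector of p-values in `[0, 1]` (unique
#'   labels).
#' @param q FDR level in (0, 1).
#' @return Character vector of rejected labels (empty if none).
#' @export
#' @examples
#' bky_two_stage(c(a = 0.01, b = 0.04, c = 0.30), q = 0.05) # a and b
bky_two_stage <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1).", call. = FALSE)
  m <- length(pvals)
  if (m == 0) return(character(0))
  if (is.null(names(pvals))) names(pvals) <- paste0("t", seq_len(m))
  if (anyDuplicated(names(pvals)) > 0) stop("p-value labels must be unique.", call. = FALSE)
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1].", call. = FALSE)

  step_up <- function(level) {
    ps <- sort(pvals)
    ok <- which(ps <= seq_len(m) * level / m)
    if (length(ok) == 0) 0L else max(ok)
  }
  q1 <- q / (1 + q)
  r1 <- step_up(q1)
  if (r1 == 0L) return(character(0))
  if (r1 == m) return(names(pvals))
  r2 <- step_up(q1 * m / (m - r1))
  if (r2 == 0L) return(character(0))
  thresh <- sort(pvals)[r2]
  names(pvals)[pvals <= thresh]
}

#' Sharpened two-stage q-values
#'
#' The q-value of each test is the smallest FDR level on a fixed grid at
#' which the two-stage procedure ([bky_two_stage()]) rejects it; tests
#' never rejected anywhere on the grid receive q = 1. Because the
#' procedure adapts to the observed p-value distribution, a q-value can
#' be smaller than its p-value ("sharpening"). Q-values are always
#' monotone in p within a family.
#'
#' @param pvals Named numeric vector of p-values.
#' @param grid_step Grid resolution (default 0.001, i.e. levels 0.001,
#'   0.002, ..., 1.000, matching three-decimal q-value reporting).
#' @return Named numeric vector of q-values, same order as `pvals`.
#' @export
sharpened_qvalues <- function(pvals, grid_step = 0.001) {
  m <- length(pvals)
  if (m == 0) stop("p-value family is empty.", call. = FALSE)
  if (is.null(names(pvals))) names(pvals) <- paste0("t", seq_len(m))
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1].", call. = FALSE)

  # at any level the two-stage step-up rejects exactly {p <= cutoff(level)},
  # so precompute that cutoff once per grid level
  ps <- sort(pvals)
  idx <- seq_len(m)
  cutoff <- function(g) {
    q1 <- g / (1 + g)
    ok <- which(ps <= idx * q1 / m)
    r1 <- if (length(ok) > 0) max(ok) else 0L
    if (r1 == 0L) return(-Inf)
    if (r1 == m) return(1)
    lvl <- q1 * m / (m - r1)
    ok2 <- which(ps <= idx * lvl / m)
    r2 <- if (length(ok2) > 0) max(ok2) else 0L
    if (r2 == 0L) -Inf else ps[r2]
  }
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  cuts <- vapply(grid, cutoff, numeric(1))
  qs <- vapply(pvals, function(p) {
    hit <- which(p <= cuts)
    if (length(hit) > 0) grid[hit[1]] else 1
  }, numeric(1))
  stats::setNames(qs, names(pvals))
}

#' Write a p/q table as CSV
#' @param pvals Named p-value vector.
#' @param path Output path.
#' @param grid_step Passed to [sharpened_qvalues()].
#' @return The tibble written, invisibly.
#' @export
write_qvalue_table <- function(pvals, path, grid_step = 0.001) {
  out <- tibble::tibble(test_label = names(pvals), p = unname(pvals),
                        q = unname(sharpened_qvalues(pvals, grid_step)))
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(out)
}
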