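# Independent oracles used across the suite. Each is deliberately written
# along a different route than the package implementation.

# brute-force one-way cluster sandwich: explicit per-cluster outer products
oracle_cluster_vcov <- function(X, u, cl, K) {
  X <- as.matrix(X)
  XtXinv <- solve(t(X) %*% X)
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    s <- t(X[cl == g, , drop = FALSE]) %*% u[cl == g]
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(cl))
  N <- nrow(X)
  (G / (G - 1)) * ((N - 1) / (N - K)) * XtXinv %*% meat %*% XtXinv
}

# the fitted quadratic surface as a plain function of (e0, |delta|)
oracle_surface <- function(fit) {
  cf <- function(term) {
    if (term %in% names(fit$coefficients)) fit$coefficients[[term]] else 0
  }
  function(e0, d) {
    cf("e0") * e0 + cf("abs_delta") * d + cf("e0_sq") * e0^2 +
      cf("abs_delta_sq") * d^2 + cf("e0_x_absdelta") * e0 * d
  }
}

central_diff <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# independent two-stage step-up built on stats::p.adjust (BH adjusted
# p-values <= level  <=>  step-up rejection at that level)
oracle_bky <- function(p, q) {
  padj <- stats::p.adjust(p, method = "BH")
  q1 <- q / (1 + q)
  r1 <- sum(padj <= q1)
  if (r1 == 0) return(rep(FALSE, length(p)))
  if (r1 == length(p)) return(rep(TRUE, length(p)))
  padj <= q1 * length(p) / (length(p) - r1)
}

# q-values by re-running the oracle procedure at every grid level
oracle_qvalues <- function(p, grid_step = 0.001) {
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  qs <- rep(1, length(p))
  for (g in grid) {
    rej <- oracle_bky(p, g)
    qs[rej & qs == 1] <- g
    if (all(qs < 1)) break
  }
  stats::setNames(qs, names(p))
}

# day-by-day rainfall summation over a half-open date window
oracle_rain_sum <- function(series, start, end) {
  total <- 0
  for (i in seq_len(nrow(series))) {
    if (series$date[i] >= start && series$date[i] < end) {
      total <- total + series$rain_mm[i]
    }
  }
  total
}
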