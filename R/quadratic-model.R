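ENV_TERMS <- c("e0", "abs_delta", "e0_sq", "abs_delta_sq", "e0_x_absdelta")
DEV_TERMS <- c("e0", "e0_sq") # constant within female, absorbed by individual FE

#' Model specification for the quadratic outcome regression
#'
#' Describes one fit of the quadratic approximation of the adult-outcome
#' surface: the outcome y1 is regressed on the developmental environment
#' e0, the mismatch magnitude `|delta e|`, their squares and interaction,
#' plus covariates, under a chosen fixed-effect structure. Under an
#' individual (female) fixed effect the development-only terms e0 and
#' e0^2 are absorbed (each female has a single developmental
#' environment) and are excluded from the design; the interaction
#' `e0 * |delta e|` is retained because it varies within female.
#'
#' @param fixed_effect `"group"` (compare females within social groups),
#'   `"individual"` (compare a female to herself across time), or
#'   `"none"` (plain OLS with intercept; mainly for diagnostics).
#' @param covariates Ordered covariate column names; default age, age
#'   squared, and mean group size.
#' @param outcome_kind,environment_kind Optional labels checked against
#'   the table at fit time.
#' @return A list with class `model_spec`.
#' @export
model_spec <- function(fixed_effect = c("group", "individual", "none"),
                       covariates = c("age", "age_sq", "group_size"),
                       outcome_kind = NULL, environment_kind = NULL) {
  fixed_effect <- match.arg(fixed_effect)
  structure(list(fixed_effect = fixed_effect,
                 covariates = covariates,
                 include_development_terms = fixed_effect != "individual",
                 outcome_kind = outcome_kind,
                 environment_kind = environment_kind),
            class = "model_spec")
}

#' Build the design matrix for the quadratic regression
#'
#' Constructs the response, the named predictor matrix (environment
#' polynomial terms plus covariates), the cluster vector (always the
#' female id) and the fixed-effect vector from an [analysis_table()].
#' Under an individual fixed effect, females contributing a single
#' observation are dropped (they carry no within-female information)
#' and logged.
#'
#' @param table An [analysis_table()].
#' @param spec A [model_spec()].
#' @return A list with class `design_matrix`: `y`, `X`, `cluster`, `fe`,
#'   `fe_type`, `absorbed` (term names excluded as absorbed), `means`
#'   (sample means of `e0` and `abs_delta`), `n_dropped`.
#' @export
build_design <- function(table, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  df <- tibble::as_tibble(table)
  if (nrow(df) == 0) stop("analysis table is empty.", call. = FALSE)
  if (!is.null(spec$outcome_kind) &&
      !identical(spec$outcome_kind, outcome_kind(table))) {
    stop("spec outcome_kind does not match the table.", call. = FALSE)
  }
  if (!is.null(spec$environment_kind) &&
      !identical(spec$environment_kind, environment_kind(table))) {
    stop("spec environment_kind does not match the table.", call. = FALSE)
  }

  n_dropped <- 0L
  if (spec$fixed_effect == "individual") {
    n_per <- table(df$female_id)
    singletons <- names(n_per)[n_per == 1L]
    if (length(singletons) > 0) {
      n_dropped <- sum(df$female_id %in% singletons)
      message(n_dropped, " single-observation female(s) dropped under individual fixed effects.")
      df <- df[!df$female_id %in% singletons, , drop = FALSE]
    }
  }
  if (length(unique(df$female_id)) < 2L) {
    stop("inference impossible: fewer than 2 female clusters.", call. = FALSE)
  }

  env <- cbind(e0 = df$e0,
               abs_delta = df$abs_delta,
               e0_sq = df$e0^2,
               abs_delta_sq = df$abs_delta^2,
               e0_x_absdelta = df$e0 * df$abs_delta)
  absorbed <- character(0)
  if (!spec$include_development_terms) {
    absorbed <- DEV_TERMS
    env <- env[, setdiff(colnames(env), DEV_TERMS), drop = FALSE]
  }
  miss <- setdiff(spec$covariates, names(df))
  if (length(miss) > 0) {
    stop("covariates not found in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(env, as.matrix(df[spec$covariates]))

  fe <- switch(spec$fixed_effect,
               group = as.character(df$group_id),
               individual = as.character(df$female_id),
               none = NULL)

  structure(list(y = as.numeric(df$outcome), X = X,
                 cluster = as.character(df$female_id),
                 fe = fe, fe_type = spec$fixed_effect,
                 absorbed = absorbed,
                 means = c(e0 = mean(df$e0), abs_delta = mean(df$abs_delta)),
                 n_dropped = n_dropped, spec = spec),
            class = "design_matrix")
}

demean_by <- function(M, f) {
  M <- as.matrix(M)
  f <- as.character(f)
  sums <- rowsum(M, f)
  counts <- as.vector(table(f)[rownames(sums)])
  means <- sums / counts
  M - means[f, , drop = FALSE]
}

#' Fit the quadratic linear probability model
#'
#' Least-squares fit of the binary outcome on the quadratic environment
#' terms and covariates, with fixed effects handled either by within
#' demeaning or by explicit dummy encoding (the two give identical slope
#' coefficients; `"auto"` demeans for individual fixed effects and uses
#' dummies otherwise). Collinear columns are dropped by QR pivoting and
#' reported by name.
#'
#' @param design A [build_design()] result.
#' @param method `"auto"`, `"demean"`, or `"dummy"`.
#' @return A list with class `quad_fit`: `gamma` (environment and
#'   covariate coefficients), `coefficients` (everything estimated,
#'   including intercept/dummies when present), `absorbed`, `dropped`
#'   (collinear columns), `residuals`, `fitted`, `n_obs`, `n_clusters`,
#'   `K` (parameter count entering the CR1 small-sample factor), and the
#'   pieces needed for [cluster_vcov()].
#' @export
fit_lpm <- function(design, method = c("auto", "demean", "dummy")) {
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (design$fe_type == "individual") "demean" else "dummy"
  }
  y <- design$y
  n <- length(y)

  if (is.null(design$fe) || method == "dummy") {
    if (is.null(design$fe)) {
      Xf <- cbind(`(Intercept)` = 1, design$X)
      n_absorbed_levels <- 0L
    } else {
      f <- factor(design$fe)
      D <- stats::model.matrix(~f)
      colnames(D) <- c("(Intercept)", paste0("fe_", levels(f)[-1]))
      Xf <- cbind(D, design$X)
      n_absorbed_levels <- 0L
    }
    qrX <- qr(Xf)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(Xf), colnames(Xf)[keep])
    if (length(dropped) > 0) {
      warning("collinear column(s) dropped: ", paste(dropped, collapse = ", "),
              call. = FALSE)
      Xf <- Xf[, keep, drop = FALSE]
      qrX <- qr(Xf)
    }
    beta <- qr.coef(qrX, y)
    fitted <- drop(Xf %*% beta)
    resid <- y - fitted
    K <- ncol(Xf)
    X_used <- Xf
    coefficients <- beta
  } else {
    f <- design$fe
    Xd <- demean_by(design$X, f)
    yd <- y - ave(y, f)
    qrX <- qr(Xd)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(Xd), colnames(Xd)[keep])
    if (length(dropped) > 0) {
      warning("collinear column(s) dropped: ", paste(dropped, collapse = ", "),
              call. = FALSE)
      Xd <- Xd[, keep, drop = FALSE]
      qrX <- qr(Xd)
    }
    beta <- qr.coef(qrX, yd)
    resid <- yd - drop(Xd %*% beta)
    fitted <- y - resid
    n_levels <- length(unique(f))
    cluster_is_fe <- identical(as.character(f), design$cluster)
    # CR1 parameter count: absorbed levels are counted unless the cluster
    # variable IS the absorbed factor (within-estimator convention)
    K <- ncol(Xd) + if (cluster_is_fe) 1L else n_levels
    X_used <- Xd
    coefficients <- beta
  }

  gamma_names <- intersect(c(ENV_TERMS, design$spec$covariates),
                           names(coefficients))
  structure(list(gamma = coefficients[gamma_names],
                 coefficients = coefficients,
                 absorbed = design$absorbed,
                 dropped = dropped,
                 residuals = resid,
                 fitted = fitted,
                 y = y,
                 X_used = X_used,
                 cluster = design$cluster,
                 fe_type = design$fe_type,
                 method = method,
                 means = design$means,
                 n_obs = n,
                 n_clusters = length(unique(design$cluster)),
                 K = K,
                 vcov = NULL),
            class = "quad_fit")
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("<quad_fit> %s fixed effects (%s), n = %d, clusters = %d\n",
              x$fe_type, x$method, x$n_obs, x$n_clusters))
  print(round(x$gamma, 5))
  invisible(x)
}

#' Cluster-robust (CR1) sandwich covariance
#'
#' One-way cluster-robust covariance of the fitted coefficients,
#' clustering on female id: bread * meat * bread with meat the sum of
#' per-cluster score outer products, scaled by the small-sample factor
#' `G/(G-1) * (N-1)/(N-K)` (G clusters, N observations, K parameters as
#' counted by [fit_lpm()]).
#'
#' @param fit A [fit_lpm()] result.
#' @return A symmetric covariance matrix with dimnames matching
#'   `fit$coefficients`.
#' @export
cluster_vcov <- function(fit) {
  X <- fit$X_used
  u <- fit$residuals
  XtX <- crossprod(X)
  condition <- kappa(XtX, exact = FALSE)
  bread <- tryCatch(solve(XtX),
                    error = function(e) {
                      stop(sprintf("bread matrix is numerically singular (condition number %.3g).",
                                   condition), call. = FALSE)
                    })
  scores <- X * u
  S <- rowsum(scores, fit$cluster) # per-cluster score sums
  meat <- crossprod(S)
  G <- fit$n_clusters
  N <- fit$n_obs
  adj <- (G / (G - 1)) * ((N - 1) / (N - fit$K))
  V <- adj * bread %*% meat %*% bread
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  V
}

#' Fit the quadratic model with cluster-robust inference in one call
#'
#' Convenience wrapper: [build_design()], [fit_lpm()], [cluster_vcov()].
#'
#' @inheritParams build_design
#' @inheritParams fit_lpm
#' @return A `quad_fit` with its `vcov` slot filled.
#' @export
fit_quadratic <- function(table, spec = model_spec(),
                          method = c("auto", "demean", "dummy")) {
  design <- build_design(table, spec)
  fit <- fit_lpm(design, method = match.arg(method))
  fit$vcov <- cluster_vcov(fit)
  fit
}

#' Tidy coefficient table of a fit
#'
#' @param fit A `quad_fit` (with `vcov` filled, e.g. from
#'   [fit_quadratic()]).
#' @return A tibble with `term`, `estimate`, `se`, `absorbed` (TRUE for
#'   terms absorbed by the fixed effect, with NA estimates rather than
#'   zeros).
#' @export
tidy_fit <- function(fit) {
  V <- fit$vcov %||% cluster_vcov(fit)
  est_terms <- names(fit$coefficients)
  out <- tibble::tibble(term = est_terms,
                        estimate = unname(fit$coefficients),
                        se = sqrt(diag(V))[est_terms],
                        absorbed = FALSE)
  if (length(fit$absorbed) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(term = fit$absorbed,
                                                estimate = NA_real_,
                                                se = NA_real_,
                                                absorbed = TRUE))
  }
  out
}
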