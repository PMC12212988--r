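# small helper: a design constructed directly, bypassing the table layer,
# for edge cases a binary analysis table cannot express
manual_design <- function(y, X, cluster, fe = NULL,
                          fe_type = c("none", "group", "individual")) {
  fe_type <- match.arg(fe_type)
  structure(list(y = y, X = X, cluster = as.character(cluster), fe = fe,
                 fe_type = fe_type, absorbed = character(0),
                 means = c(e0 = 0, abs_delta = 0), n_dropped = 0L,
                 spec = model_spec("none", covariates = character(0))),
            class = "design_matrix")
}

test_that("design matrix has the quadratic term census and absorption rules", {
  p <- simulate_panel(synth_config(n_females = 10, obs_per_female = 4, seed = 1))
  d <- build_design(p, model_spec("group"))
  expect_setequal(colnames(d$X),
                  c("e0", "abs_delta", "e0_sq", "abs_delta_sq",
                    "e0_x_absdelta", "age", "age_sq", "group_size"))
  expect_identical(d$cluster, as.character(p$female_id))

  di <- build_design(p, model_spec("individual"))
  expect_false("e0" %in% colnames(di$X))
  expect_false("e0_sq" %in% colnames(di$X))
  expect_true("e0_x_absdelta" %in% colnames(di$X)) # varies within female
  expect_identical(di$absorbed, c("e0", "e0_sq"))
})

test_that("a single female cannot support clustered inference", {
  p <- simulate_panel(synth_config(n_females = 1, obs_per_female = 6, seed = 2))
  expect_error(build_design(p, model_spec("group")), "fewer than 2")
})

test_that("single-observation females are dropped under individual fixed effects", {
  p1 <- simulate_panel(synth_config(n_females = 8, obs_per_female = 3, seed = 3))
  one <- tibble::as_tibble(p1)[1, ]
  one$female_id <- "LONER"
  p <- analysis_table(dplyr::bind_rows(tibble::as_tibble(p1), one),
                      outcome_kind = "synthetic", environment_kind = "rank")
  expect_message(d <- build_design(p, model_spec("individual")),
                 "single-observation")
  expect_false("LONER" %in% d$cluster)
  expect_identical(d$n_dropped, 1L)
})

test_that("constant response gives zero slopes and the constant as intercept", {
  set.seed(4)
  X <- cbind(x1 = rnorm(20), x2 = rnorm(20))
  d <- manual_design(rep(0.5, 20), X, cluster = rep(1:5, each = 4))
  fit <- fit_lpm(d)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.5)
  expect_equal(unname(fit$coefficients[c("x1", "x2")]), c(0, 0),
               tolerance = 1e-12)
})

test_that("noiseless data generated from known coefficients is interpolated exactly", {
  set.seed(5)
  n <- 60
  e0 <- runif(n); ad <- runif(n)
  X <- cbind(e0 = e0, abs_delta = ad, e0_sq = e0^2, abs_delta_sq = ad^2,
             e0_x_absdelta = e0 * ad)
  truth <- c(0.3, 0.2, -0.15, 0.1, 0.05)
  y <- 0.4 + drop(X %*% truth)
  fit <- fit_lpm(manual_design(y, X, cluster = rep(1:10, 6)))
  expect_equal(unname(fit$coefficients[colnames(X)]), truth, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 0.4, tolerance = 1e-8)
})

test_that("demeaned and dummy-encoded fixed effects give identical slopes and vcov", {
  p <- simulate_panel(synth_config(n_females = 40, obs_per_female = 5, seed = 6))
  for (fe in c("group", "individual")) {
    f1 <- suppressMessages(fit_quadratic(p, model_spec(fe), method = "demean"))
    f2 <- suppressMessages(fit_quadratic(p, model_spec(fe), method = "dummy"))
    shared <- intersect(names(f1$gamma), names(f2$gamma))
    expect_equal(f1$gamma[shared], f2$gamma[shared], tolerance = 1e-8)
    if (fe == "group") {
      # same CR1 parameter count, hence identical covariance of the slopes
      expect_equal(f1$vcov[shared, shared], f2$vcov[shared, shared],
                   tolerance = 1e-8)
    }
  }
})

test_that("perfectly collinear columns are dropped with a warning", {
  set.seed(7)
  x <- rnorm(30)
  X <- cbind(a = x, b = 2 * x, c = rnorm(30))
  d <- manual_design(rnorm(30), X, cluster = rep(1:6, 5))
  expect_warning(fit <- fit_lpm(d), "collinear")
  expect_true("b" %in% fit$dropped)
  expect_false("b" %in% names(fit$coefficients))
})

test_that("cluster-robust vcov matches the brute-force sandwich", {
  # hand-sized case: 2 clusters x 2 observations
  X <- cbind(`(Intercept)` = 1, x = c(1, 2, 3, 4))
  y <- c(0, 1, 1, 0)
  cl <- c("a", "a", "b", "b")
  fit <- fit_lpm(manual_design(y, X[, 2, drop = FALSE], cluster = cl))
  V <- cluster_vcov(fit)
  Vo <- oracle_cluster_vcov(fit$X_used, fit$residuals, cl, K = fit$K)
  expect_equal(unclass(V), unclass(Vo), tolerance = 1e-12,
               ignore_attr = TRUE)

  # zero residuals give a zero matrix
  y_exact <- drop(X %*% c(0.2, 0.1))
  fit0 <- fit_lpm(manual_design(y_exact, X[, 2, drop = FALSE], cluster = cl))
  expect_equal(max(abs(cluster_vcov(fit0))), 0, tolerance = 1e-20)

  # random datasets, including fixed effects, against the oracle
  for (seed in 1:5) {
    p <- simulate_panel(synth_config(n_females = 12, obs_per_female = 3,
                                     seed = seed))
    for (fe in c("group", "individual")) {
      fit <- suppressMessages(fit_quadratic(p, model_spec(fe)))
      Vo <- oracle_cluster_vcov(fit$X_used, fit$residuals, fit$cluster,
                                K = fit$K)
      expect_equal(unclass(fit$vcov), unclass(Vo), tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  }
})

test_that("cluster vcov agrees with the sandwich package on a dummy-encoded fit", {
  skip_if_not_installed("sandwich")
  p <- simulate_panel(synth_config(n_females = 25, obs_per_female = 4, seed = 8))
  fit <- fit_quadratic(p, model_spec("group"), method = "dummy")
  df <- as.data.frame(p)
  m <- stats::lm(outcome ~ e0 + abs_delta + I(e0^2) + I(abs_delta^2) +
                   I(e0 * abs_delta) + age + age_sq + group_size +
                   factor(group_id), data = df)
  Vcl <- sandwich::vcovCL(m, cluster = df$female_id, type = "HC1")
  expect_equal(fit$vcov["e0", "e0"], Vcl["e0", "e0"], tolerance = 1e-8)
  expect_equal(fit$vcov["abs_delta", "abs_delta"],
               Vcl["abs_delta", "abs_delta"], tolerance = 1e-8)
})

test_that("one observation per cluster reduces to the HC1 heteroskedasticity-robust vcov", {
  skip_if_not_installed("sandwich")
  set.seed(9)
  n <- 40
  X <- cbind(x = rnorm(n))
  y <- 0.5 + 0.3 * X[, 1] + rnorm(n, 0, 0.4)
  fit <- fit_lpm(manual_design(y, X, cluster = seq_len(n)))
  V <- cluster_vcov(fit)
  m <- stats::lm(y ~ x, data = data.frame(y = y, x = X[, 1]))
  Vhc <- sandwich::vcovHC(m, type = "HC1")
  expect_equal(V["x", "x"], Vhc["x", "x"], tolerance = 1e-8)
})

test_that("vcov is symmetric with non-negative eigenvalues", {
  for (seed in c(21, 22)) {
    p <- simulate_panel(synth_config(n_females = 30, obs_per_female = 4,
                                     seed = seed))
    fit <- fit_quadratic(p, model_spec("group"))
    expect_identical(fit$vcov, t(fit$vcov))
    expect_true(min(eigen(fit$vcov, symmetric = TRUE,
                          only.values = TRUE)$values) >= -1e-10)
  }
})

test_that("clustered and classical standard errors agree under independent errors", {
  # independent observations: female effect zero, one observation per female
  set.seed(10)
  reps <- 40
  ratio <- numeric(reps)
  for (r in seq_len(reps)) {
    p <- simulate_panel(synth_config(n_females = 400, obs_per_female = 1,
                                     female_sd = 0, noise_sd = 0.1,
                                     seed = 3000 + r))
    fit <- fit_quadratic(p, model_spec("group"))
    Xd <- fit$X_used
    sigma2 <- sum(fit$residuals^2) / (fit$n_obs - fit$K)
    Vc <- sigma2 * solve(crossprod(Xd))
    ratio[r] <- sqrt(fit$vcov["e0", "e0"] / Vc["e0", "e0"])
  }
  expect_equal(mean(ratio), 1, tolerance = 0.05)
})

test_that("coefficient bias shrinks as the panel grows", {
  truth <- c(e0 = 0.2, abs_delta = -0.15)
  bias <- sapply(c(500, 5000), function(n_rec) {
    cfg <- synth_config(n_females = n_rec / 10, obs_per_female = 10,
                        gamma = c(intercept = 0.35, e0 = 0.2,
                                  abs_delta = -0.15),
                        standardize_effects = FALSE,
                        female_sd = 0, noise_sd = 0, seed = 99)
    fit <- fit_quadratic(simulate_panel(cfg), model_spec("group"))
    abs(fit$gamma[names(truth)] - truth)
  })
  expect_true(all(bias[, 2] < 0.25))
  expect_true(mean(bias[, 2]) < mean(bias[, 1]) + 0.05)
})
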