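test_that("design matrix lays out stick, covariate, and boxcar columns", {
  fs <- 20
  sp <- regressor_spec("ev", "transient", event_times = 5, window = c(0, 1))
  dm <- build_design_matrix(list(sp), n_samples = 200, fs = fs)
  expect_equal(ncol(dm$X), 21L)      # lags 0, 0.05, ..., 1.0
  expect_true(all(Matrix::colSums(dm$X != 0) == 1))
  expect_equal(unname(which(dm$X[, 1] != 0)), 101L)   # t = 5 s -> row 101
  expect_equal(dm$column_map$lag, seq(0, 1, by = 0.05))
  # zero covariate value contributes nothing (pre-centering)
  spc <- regressor_spec("v", "covariate", event_times = c(2, 5),
                        window = c(0, 0.5), covariate_values = c(1, 1))
  dmc <- build_design_matrix(list(spc), 200, fs)
  expect_equal(Matrix::colSums(dmc$X != 0), rep(0, 11), ignore_attr = TRUE)
  spc2 <- regressor_spec("v", "covariate", event_times = c(2, 5, 8),
                         window = c(0, 0.5),
                         covariate_values = c(1, 2, 3))
  dmc2 <- build_design_matrix(list(spc2), 220, fs)
  zs <- (c(1, 2, 3) - 2) / sd(c(1, 2, 3))
  expect_equal(dmc2$X[41, 1], zs[1])
  expect_equal(dmc2$X[101, 1], 0)
  expect_equal(dmc2$X[161, 1], zs[3])
  # boxcar: height one over mean duration, spanning each event
  spb <- regressor_spec("box", "boxcar", event_times = c(1, 6),
                        durations = c(0.5, 1.5))
  dmb <- build_design_matrix(list(spb), 200, fs)
  expect_equal(ncol(dmb$X), 1L)
  expect_equal(unique(dmb$X[dmb$X[, 1] != 0, 1]), 1 / 1)
  expect_error(build_design_matrix(list(sp, sp), 200, fs), "unique")
})

test_that("least squares on the built design is self-consistent", {
  set.seed(23)
  fs <- 20
  ev1 <- cumsum(runif(12, 3, 6))
  ev2 <- ev1 + runif(12, 0.8, 1.6)
  n <- round((max(ev2) + 5) * fs)
  specs <- list(
    regressor_spec("a", "transient", ev1, c(-0.5, 2)),
    regressor_spec("v", "covariate", ev2, c(0, 2),
                   covariate_values = rnorm(12)))
  dm <- build_design_matrix(specs, n, fs)
  beta_true <- rnorm(ncol(dm$X))
  Xc <- sweep(as.matrix(dm$X), 2, dm$col_means)
  y <- as.numeric(Xc %*% beta_true)
  est <- ridge_solve(dm, y, 0)
  expect_equal(est, beta_true, tolerance = 1e-8)
})

test_that("ridge solutions match the direct normal-equation oracle", {
  set.seed(24)
  for (rep in 1:5) {
    X <- matrix(rnorm(50 * 30), 50, 30)
    y <- rnorm(50)
    for (lam in c(0, 0.1, 0.5, 1)) {
      expect_equal(ridge_solve(X, y, lam), oracle_ridge(X, y, lam),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
    # shrinkage monotone in the penalty
    norms <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                    function(l) sqrt(sum(ridge_solve(X, y, l)^2)), 0.0)
    expect_true(all(diff(norms) <= 1e-12))
  }
  expect_error(ridge_solve(matrix(rnorm(20), 10, 2), rnorm(10), -0.1),
               "non-negative")
})

test_that("lambda = 0 reproduces ordinary least squares", {
  set.seed(25)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  ols <- lm.fit(cbind(1, X), y)$coefficients[-1]
  expect_equal(ridge_solve(X, y, 0), unname(ols), tolerance = 1e-10)
})

test_that("cross-validation picks sensible penalties deterministically", {
  set.seed(26)
  # orthogonal-ish design, noiseless response: smallest penalty wins
  X <- matrix(rnorm(400 * 8), 400, 8)
  beta <- rnorm(8)
  yc <- as.numeric(scale(X, scale = FALSE) %*% beta)
  dm <- list(X = Matrix::Matrix(X, sparse = TRUE), col_means = colMeans(X))
  sel0 <- cross_validate_lambda(dm, yc, grid = c(0, 0.5, 1), n_splits = 6,
                                seed = 2)
  expect_equal(sel0$lambda_star, 0)
  # identical seeds agree
  sel1 <- cross_validate_lambda(dm, yc, n_splits = 5, seed = 7)
  sel2 <- cross_validate_lambda(dm, yc, n_splits = 5, seed = 7)
  expect_identical(sel1, sel2)
  expect_error(cross_validate_lambda(dm, yc, grid = numeric(0)), "empty")
  expect_error(cross_validate_lambda(dm, yc, grid = c(0, 2)), "within")
})

test_that("collinear noisy designs prefer a positive penalty", {
  set.seed(27)
  hits <- 0L
  for (rep in 1:5) {
    z <- rnorm(300)
    X <- cbind(z + 0.02 * rnorm(300), z + 0.02 * rnorm(300),
               z + 0.02 * rnorm(300), rnorm(300))
    beta <- c(2, -1.5, 1, 0.5)
    y <- as.numeric(scale(X, scale = FALSE) %*% beta) + 4 * rnorm(300)
    dm <- list(X = Matrix::Matrix(X, sparse = TRUE), col_means = colMeans(X))
    sel <- cross_validate_lambda(dm, y, n_splits = 10, seed = rep)
    if (sel$lambda_star > 0) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("deconvolve composes the pieces and handles degenerate input", {
  fs <- 20
  t <- seq(0, 60, by = 1 / fs)
  ev <- c(5, 15, 25, 35, 45)
  kernel <- pupil_irf(seq(0, 3, by = 1 / fs))
  stick <- numeric(length(t)); stick[round(ev * fs) + 1] <- 1
  y <- as.numeric(stats::filter(stick, kernel, sides = 1))
  y[is.na(y)] <- 0
  ts <- pupil_ts(t, y, fs)
  specs <- list(regressor_spec("ev", "transient", ev, c(-0.5, 3)))
  res <- deconvolve(ts, specs, cv = NULL)
  b <- response_of(res, "ev")
  truth <- pupil_irf(b$lag)
  expect_gt(cor(b$beta, truth), 0.999)
  # all-zero signal: all coefficients zero (tiny ridge keeps it defined)
  res0 <- deconvolve(pupil_ts(t, numeric(length(t)), fs), specs,
                     cv = list(grid = 0.5, n_splits = 2, seed = 1))
  expect_lt(max(abs(res0$betas$beta)), 1e-10)
  expect_error(response_of(res, "nope"), "no regressor")
})

test_that("delta-value response is the chosen-minus-unchosen difference", {
  res <- structure(list(betas = data.frame(
    regressor = rep(c("q_chosen_choice", "q_unchosen_choice"), each = 3),
    lag = rep(0:2, 2), beta = c(3, 2, 1, 1, 1, 1))), class = "deconv_result")
  dv <- delta_value_response(res)
  expect_equal(dv$beta, c(2, 1, 0))
})

test_that("default regressor sets mirror the standard designs", {
  cfg <- task_config(n_runs_learning = 1, trials_per_run = 30,
                     n_runs_transfer = 1)
  sim <- simulate_agent(agent_params(0.4, 0.2, 10), cfg, seed = 61)
  learning <- sim$trials[sim$trials$phase == "learning", ]
  lr <- learning_regressors(learning, sim$trajectory)
  nm <- vapply(lr, `[[`, "", "name")
  expect_setequal(nm, c("options_on", "choice", "feedback",
                        "decision_boxcar", "fixation", "options_off",
                        "q_chosen_choice", "q_unchosen_choice",
                        "q_chosen_fb", "q_unchosen_fb", "rpe_fb"))
  kinds <- vapply(lr, `[[`, "", "kind")
  expect_equal(sum(kinds == "covariate"), 5L)
  expect_equal(sum(kinds == "boxcar"), 1L)
  w_choice <- lr[[which(nm == "choice")]]$window
  expect_equal(w_choice, c(-2, 1.5))
  expect_equal(lr[[which(nm == "feedback")]]$window, c(-0.5, 3))
  # transfer: no feedback regressors, conflict sticks added
  transfer <- sim$trials[sim$trials$phase == "transfer", ]
  tv <- transfer_values(sim$final_q, transfer)
  tr <- transfer_regressors(transfer, tv, cfg)
  nmt <- vapply(tr, `[[`, "", "name")
  expect_false(any(grepl("fb|feedback", nmt)))
  expect_true(all(c("conflict_low", "conflict_medium", "conflict_high")
                  %in% nmt))
  # conflict bins partition all transfer trials
  n_conflict <- sum(vapply(tr[grepl("conflict", nmt)],
                           function(s) length(s$event_times), 0L))
  expect_equal(n_conflict, nrow(transfer))
})
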