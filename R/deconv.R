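#' Regressor specification for FIR deconvolution
#'
#' Describes one regressor of the event-related design: a `transient`
#' stick set (one free coefficient per lag of the window), a `covariate`
#' stick set (same structure, scaled per event by a z-scored single-trial
#' value), or a `boxcar` (one column spanning each event's duration, with
#' height `1 / mean(duration)` so sustained and transient coefficients
#' are on a comparable scale).
#'
#' @param name Regressor name (unique within a design).
#' @param kind `"transient"`, `"covariate"`, or `"boxcar"`.
#' @param event_times Event times in seconds.
#' @param window `c(t_start, t_end)` in seconds relative to the event
#'   (transient/covariate kinds).
#' @param covariate_values One scalar per event (covariate kind); they
#'   are z-scored by [build_design_matrix()].
#' @param durations One duration per event in seconds (boxcar kind).
#' @return An object of class `regressor_spec`.
#' @export
regressor_spec <- function(name, kind = c("transient", "covariate", "boxcar"),
                           event_times, window = c(-0.5, 3.0),
                           covariate_values = NULL, durations = NULL) {
  kind <- match.arg(kind)
  if (kind != "boxcar") {
    if (window[1] >= window[2]) stop("window start must precede its end")
  }
  if (kind == "covariate") {
    if (is.null(covariate_values) ||
        length(covariate_values) != length(event_times))
      stop("covariate kind needs one value per event")
  }
  if (kind == "boxcar") {
    if (is.null(durations) || length(durations) != length(event_times))
      stop("boxcar kind needs one duration per event")
  }
  structure(list(name = name, kind = kind,
                 event_times = as.numeric(event_times),
                 window = window,
                 covariate_values = covariate_values,
                 durations = durations),
            class = "regressor_spec")
}

#' Build the sparse FIR design matrix
#'
#' Transient and covariate regressors contribute one column per lag of
#' their window, with a (possibly scaled) unit entry at `event + lag`;
#' boxcars contribute a single column. Events are snapped to the nearest
#' sample; entries falling outside the recording are truncated. The
#' matrix is stored uncentered and sparse, together with its column
#' means; the ridge solver centres implicitly via a rank-one correction,
#' and no intercept column is included.
#'
#' @param specs List of [regressor_spec()] objects.
#' @param n_samples Number of rows (samples of the response).
#' @param fs Sampling rate in Hz (default 20).
#' @param t0 Time of the first sample (default 0).
#' @return A list of class `deconv_design`: `X` (dgCMatrix),
#'   `col_means`, `column_map` (data frame `regressor`, `lag`), `fs`,
#'   `t0`.
#' @export
build_design_matrix <- function(specs, n_samples, fs = 20, t0 = 0) {
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("regressor names must be unique")
  ii <- list(); jj <- list(); xx <- list()
  map_reg <- character(0); map_lag <- numeric(0)
  col0 <- 0L
  for (sp in specs) {
    ev_idx <- round((sp$event_times - t0) * fs) + 1L
    if (sp$kind == "boxcar") {
      h <- 1 / mean(sp$durations)
      rows <- integer(0)
      for (e in seq_along(ev_idx)) {
        len <- round(sp$durations[e] * fs)
        rows <- c(rows, seq(ev_idx[e], ev_idx[e] + len))
      }
      keep <- rows >= 1 & rows <= n_samples
      if (!all(keep)) warning("boxcar '", sp$name, "' truncated at recording edge")
      rows <- rows[keep]
      ii[[length(ii) + 1]] <- rows
      jj[[length(jj) + 1]] <- rep(col0 + 1L, length(rows))
      xx[[length(xx) + 1]] <- rep(h, length(rows))
      map_reg <- c(map_reg, sp$name); map_lag <- c(map_lag, 0)
      col0 <- col0 + 1L
    } else {
      lag_idx <- seq(round(sp$window[1] * fs), round(sp$window[2] * fs))
      lags <- lag_idx / fs
      vals <- if (sp$kind == "covariate") {
        v <- sp$covariate_values
        s <- stats::sd(v)
        if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
      } else rep(1, length(sp$event_times))
      for (k in seq_along(lag_idx)) {
        rows <- ev_idx + lag_idx[k]
        keep <- rows >= 1 & rows <= n_samples
        ii[[length(ii) + 1]] <- rows[keep]
        jj[[length(jj) + 1]] <- rep(col0 + k, sum(keep))
        xx[[length(xx) + 1]] <- vals[keep]
      }
      map_reg <- c(map_reg, rep(sp$name, length(lags)))
      map_lag <- c(map_lag, lags)
      col0 <- col0 + length(lags)
    }
  }
  X <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n_samples, col0))
  structure(list(X = X, col_means = Matrix::colMeans(X),
                 column_map = data.frame(regressor = map_reg, lag = map_lag),
                 fs = fs, t0 = t0),
            class = "deconv_design")
}

## centred cross-products for a row subset; centring by rank-one correction
.centered_xtx <- function(dm, rows = NULL) {
  X <- if (is.null(rows)) dm$X else dm$X[rows, , drop = FALSE]
  n <- nrow(X)
  m <- Matrix::colMeans(X)
  XtX <- as.matrix(Matrix::crossprod(X)) - n * tcrossprod(m)
  list(XtX = XtX, m = m, n = n)
}

.centered_xty <- function(dm, y, rows = NULL, m = NULL) {
  X <- if (is.null(rows)) dm$X else dm$X[rows, , drop = FALSE]
  yc <- y - mean(y)
  as.numeric(Matrix::crossprod(X, yc))
}

#' Ridge regression solve
#'
#' Solves `(Xc' Xc + lambda I) beta = Xc' yc` where `Xc` and `yc` are the
#' mean-centred design and response, via Cholesky decomposition. With
#' `lambda = 0` and a full-rank design this is ordinary least squares.
#'
#' @param dm A [build_design_matrix()] design (or a plain numeric
#'   matrix, which is centred internally).
#' @param y Response vector.
#' @param lambda Non-negative penalty.
#' @return Coefficient vector (one per design column).
#' @export
ridge_solve <- function(dm, y, lambda = 0) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.matrix(dm)) {
    Xc <- scale(dm, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    A <- crossprod(Xc)
    b <- crossprod(Xc, yc)
  } else {
    cc <- .centered_xtx(dm)
    A <- cc$XtX
    b <- .centered_xty(dm, y)
  }
  diag(A) <- diag(A) + lambda
  R <- chol(A)
  drop(backsolve(R, backsolve(R, b, transpose = TRUE)))
}

#' Cross-validated ridge penalty selection
#'
#' For each candidate penalty, measures out-of-sample R-squared on
#' `n_splits` random contiguous train/test partitions of the recording
#' (contiguous blocks preserve the signal's temporal autocorrelation) and
#' returns the penalty with the best mean score, breaking ties toward
#' the smallest penalty.
#'
#' @param dm A [build_design_matrix()] design.
#' @param y Response vector.
#' @param grid Candidate penalties in `[0, 1]` (default 21 evenly spaced
#'   values).
#' @param n_splits Number of train/test partitions (default 20).
#' @param test_frac Fraction of samples held out per split (default 0.2).
#' @param seed Integer seed for split placement.
#' @return List with `lambda_star`, `cv_scores` (data frame `lambda`,
#'   `score`), `n_splits`.
#' @export
cross_validate_lambda <- function(dm, y, grid = seq(0, 1, length.out = 21),
                                  n_splits = 20, test_frac = 0.2, seed = 1L) {
  if (length(grid) == 0) stop("empty penalty grid")
  if (any(grid < 0 | grid > 1)) stop("penalty grid must lie within [0, 1]")
  n <- nrow(dm$X)
  len_test <- max(1L, floor(n * test_frac))
  set.seed(seed)
  starts <- sample.int(n - len_test + 1L, n_splits, replace = n_splits > n - len_test + 1L)
  scores <- matrix(NA_real_, n_splits, length(grid))
  for (s in seq_len(n_splits)) {
    test <- seq(starts[s], starts[s] + len_test - 1L)
    train <- setdiff(seq_len(n), test)
    cc <- .centered_xtx(dm, train)
    b <- as.numeric(Matrix::crossprod(dm$X[train, , drop = FALSE],
                                      y[train] - mean(y[train])))
    eg <- eigen(cc$XtX, symmetric = TRUE)
    qb <- crossprod(eg$vectors, b)
    Xte <- dm$X[test, , drop = FALSE]
    yte <- y[test] - mean(y[train])
    ss_tot <- sum(yte^2)
    for (g in seq_along(grid)) {
      beta <- eg$vectors %*% (qb / (pmax(eg$values, 0) + grid[g] + 1e-12))
      pred <- as.numeric(Xte %*% beta) - sum(cc$m * beta)
      scores[s, g] <- if (ss_tot == 0) NA_real_
                      else 1 - sum((yte - pred)^2) / ss_tot
    }
  }
  mean_scores <- colMeans(scores, na.rm = TRUE)
  best <- if (all(is.nan(mean_scores))) 1L
          else which(mean_scores >= max(mean_scores) - 1e-12)[1]
  list(lambda_star = grid[best],
       cv_scores = data.frame(lambda = grid, score = mean_scores),
       n_splits = n_splits)
}

#' Deconvolve event-related pupil responses
#'
#' Composition of [build_design_matrix()], [cross_validate_lambda()],
#' and [ridge_solve()]: estimates the FIR response time course of every
#' regressor jointly from the continuous signal.
#'
#' @param ts A preprocessed, nuisance-removed [pupil_ts()].
#' @param specs List of [regressor_spec()] objects.
#' @param cv List of cross-validation settings (`grid`, `n_splits`,
#'   `test_frac`, `seed`); set to `NULL` to skip CV and use
#'   `lambda = 0`.
#' @return An object of class `deconv_result`: `betas` (data frame
#'   `regressor`, `lag`, `beta`), `lambda_star`, `cv_scores`,
#'   `n_splits`, `fs`.
#' @export
deconvolve <- function(ts, specs,
                       cv = list(grid = seq(0, 1, length.out = 21),
                                 n_splits = 20, test_frac = 0.2, seed = 1L)) {
  fs <- attr(ts, "fs")
  dm <- build_design_matrix(specs, n_samples = nrow(ts), fs = fs,
                            t0 = ts$time[1])
  y <- ts$diameter
  if (is.null(cv)) {
    sel <- list(lambda_star = 0,
                cv_scores = data.frame(lambda = 0, score = NA_real_),
                n_splits = 0L)
  } else {
    sel <- cross_validate_lambda(dm, y,
                                 grid = cv$grid %||% seq(0, 1, length.out = 21),
                                 n_splits = cv$n_splits %||% 20,
                                 test_frac = cv$test_frac %||% 0.2,
                                 seed = cv$seed %||% 1L)
  }
  beta <- ridge_solve(dm, y, sel$lambda_star)
  structure(list(betas = cbind(dm$column_map, beta = beta),
                 lambda_star = sel$lambda_star, cv_scores = sel$cv_scores,
                 n_splits = sel$n_splits, fs = fs),
            class = "deconv_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.deconv_result <- function(x, ...) {
  cat(sprintf("deconv_result: %d regressors, %d coefficients, lambda* = %g\n",
              length(unique(x$betas$regressor)), nrow(x$betas), x$lambda_star))
  invisible(x)
}

#' Extract one regressor's response time course
#'
#' @param result A [deconvolve()] result.
#' @param name Regressor name.
#' @return Data frame with `lag` (seconds) and `beta`.
#' @export
response_of <- function(result, name) {
  b <- result$betas[result$betas$regressor == name, c("lag", "beta")]
  if (nrow(b) == 0) stop("no regressor named '", name, "'")
  rownames(b) <- NULL
  b
}

#' Chosen-minus-unchosen value response
#'
#' The time course of the value-difference correlate, computed as the
#' difference between the chosen-value and unchosen-value covariate
#' responses at matching lags.
#'
#' @param result A [deconvolve()] result.
#' @param chosen,unchosen Names of the two covariate regressors.
#' @return Data frame with `lag` and `beta`.
#' @export
delta_value_response <- function(result, chosen = "q_chosen_choice",
                                 unchosen = "q_unchosen_choice") {
  a <- response_of(result, chosen)
  b <- response_of(result, unchosen)
  stopifnot(nrow(a) == nrow(b))
  data.frame(lag = a$lag, beta = a$beta - b$beta)
}

#' Default learning-phase regressor set
#'
#' The standard design for the learning phase: transient responses for
#' options onset and feedback (window -0.5 to 3 s), choice (-2 to
#' 1.5 s), a normalized boxcar over each decision interval, nuisance
#' sticks for fixation onset and options offset, and covariate sticks for
#' chosen value and unchosen value (choice- and feedback-locked) and the
#' signed reward prediction error (feedback-locked).
#'
#' @param trials Learning-phase trial data frame (post-rejection).
#' @param trajectory Matching [compute_trajectory()] rows.
#' @return List of [regressor_spec()] objects.
#' @export
learning_regressors <- function(trials, trajectory) {
  stopifnot(nrow(trials) == nrow(trajectory))
  list(
    regressor_spec("options_on", "transient", trials$t_options_on, c(-0.5, 3.0)),
    regressor_spec("choice", "transient", trials$t_choice, c(-2.0, 1.5)),
    regressor_spec("feedback", "transient", trials$t_feedback, c(-0.5, 3.0)),
    regressor_spec("decision_boxcar", "boxcar", trials$t_options_on,
                   durations = trials$rt),
    regressor_spec("fixation", "transient", trials$t_fixation, c(-0.5, 3.0)),
    regressor_spec("options_off", "transient", trials$t_options_off, c(-0.5, 3.0)),
    regressor_spec("q_chosen_choice", "covariate", trials$t_choice,
                   c(-2.0, 1.5), covariate_values = trajectory$q_chosen),
    regressor_spec("q_unchosen_choice", "covariate", trials$t_choice,
                   c(-2.0, 1.5), covariate_values = trajectory$q_unchosen),
    regressor_spec("q_chosen_fb", "covariate", trials$t_feedback,
                   c(-0.5, 3.0), covariate_values = trajectory$q_chosen),
    regressor_spec("q_unchosen_fb", "covariate", trials$t_feedback,
                   c(-0.5, 3.0), covariate_values = trajectory$q_unchosen),
    regressor_spec("rpe_fb", "covariate", trials$t_feedback,
                   c(-0.5, 3.0), covariate_values = trajectory$rpe))
}

#' Default transfer-phase regressor set
#'
#' Identical to [learning_regressors()] minus all feedback-locked
#' regressors (there is no feedback in the transfer phase), plus three
#' choice-locked conflict sticks built from the experimental
#' reward-probability differences, binned into small (50-60%), medium
#' (30-40%) and large (10-20% difference) conflict levels.
#'
#' @param trials Transfer-phase trial data frame (post-rejection).
#' @param values Matching [transfer_values()] rows.
#' @param config The [task_config()] defining the experimental reward
#'   probabilities.
#' @return List of [regressor_spec()] objects.
#' @export
transfer_regressors <- function(trials, values, config) {
  stopifnot(nrow(trials) == nrow(values))
  p <- c(config$pairs$p_reward_hi, 1 - config$pairs$p_reward_hi)
  names(p) <- c(config$pairs$option_hi, config$pairs$option_lo)
  d <- abs(p[substr(trials$pair, 1, 1)] - p[substr(trials$pair, 2, 2)])
  conflict <- cut(round(100 * d), breaks = c(5, 25, 45, 65),
                  labels = c("high", "medium", "low"))
  specs <- list(
    regressor_spec("options_on", "transient", trials$t_options_on, c(-0.5, 3.0)),
    regressor_spec("choice", "transient", trials$t_choice, c(-2.0, 1.5)),
    regressor_spec("decision_boxcar", "boxcar", trials$t_options_on,
                   durations = trials$rt),
    regressor_spec("fixation", "transient", trials$t_fixation, c(-0.5, 3.0)),
    regressor_spec("options_off", "transient", trials$t_options_off, c(-0.5, 3.0)),
    regressor_spec("q_chosen_choice", "covariate", trials$t_choice,
                   c(-2.0, 1.5), covariate_values = values$q_chosen),
    regressor_spec("q_unchosen_choice", "covariate", trials$t_choice,
                   c(-2.0, 1.5), covariate_values = values$q_unchosen))
  for (lev in levels(conflict)) {
    ev <- trials$t_choice[conflict == lev]
    if (length(ev) > 0)
      specs[[length(specs) + 1]] <-
        regressor_spec(paste0("conflict_", lev), "transient", ev, c(-2.0, 1.5))
  }
  specs
}
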