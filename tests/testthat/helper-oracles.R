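## Independent brute-force oracles, deliberately written as plain loops
## over the model equations; they never call the package's own
## vectorised/C++ code paths.

## delta-rule trajectory oracle: returns pre-update chosen/unchosen
## values and prediction errors for a learning-phase trial table
oracle_trajectory <- function(trials, alpha_gain, alpha_loss) {
  options <- sort(unique(c(substr(trials$pair, 1, 1),
                           substr(trials$pair, 2, 2))))
  q <- stats::setNames(rep(0.5, length(options)), options)
  n <- nrow(trials)
  out <- data.frame(q_chosen = numeric(n), q_unchosen = numeric(n),
                    rpe = numeric(n))
  for (t in seq_len(n)) {
    a <- substr(trials$pair[t], 1, 1)
    b <- substr(trials$pair[t], 2, 2)
    ch <- trials$choice[t]
    un <- if (ch == a) b else a
    out$q_chosen[t] <- q[[ch]]
    out$q_unchosen[t] <- q[[un]]
    r <- trials$outcome[t]
    out$rpe[t] <- r - q[[ch]]
    alpha <- if (r == 1) alpha_gain else alpha_loss
    q[[ch]] <- q[[ch]] + alpha * (r - q[[ch]])
  }
  out$final_q <- NULL
  attr(out, "final_q") <- q
  out
}

## choice negative log-likelihood oracle (all trials included unless an
## rt column puts them outside the window; excluded trials still update)
oracle_nll <- function(trials, alpha_gain, alpha_loss, beta,
                       rt_window = c(0.15, 3.5)) {
  options <- sort(unique(c(substr(trials$pair, 1, 1),
                           substr(trials$pair, 2, 2))))
  q <- stats::setNames(rep(0.5, length(options)), options)
  nll <- 0
  for (t in seq_len(nrow(trials))) {
    a <- substr(trials$pair[t], 1, 1)
    b <- substr(trials$pair[t], 2, 2)
    ch <- trials$choice[t]
    include <- is.null(trials$rt) ||
      (trials$rt[t] >= rt_window[1] && trials$rt[t] <= rt_window[2])
    if (include) {
      p_ch <- exp(beta * q[[ch]]) / (exp(beta * q[[a]]) + exp(beta * q[[b]]))
      nll <- nll - log(p_ch)
    }
    r <- trials$outcome[t]
    alpha <- if (r == 1) alpha_gain else alpha_loss
    q[[ch]] <- q[[ch]] + alpha * (r - q[[ch]])
  }
  nll
}

## direct evaluation of the ridge normal equations on a centred system
oracle_ridge <- function(X, y, lambda) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  solve(crossprod(Xc) + lambda * diag(ncol(X)), crossprod(Xc, yc))[, 1]
}

## random learning-phase trial table over the standard three pairs
random_trials <- function(n, seed, with_rt = FALSE) {
  set.seed(seed)
  pair <- sample(c("AB", "CD", "EF"), n, replace = TRUE)
  choice <- ifelse(runif(n) < 0.5, substr(pair, 1, 1), substr(pair, 2, 2))
  df <- data.frame(pair = pair, choice = choice,
                   outcome = rbinom(n, 1, 0.6),
                   stringsAsFactors = FALSE)
  if (with_rt) df$rt <- c(runif(n - 2, 0.3, 2), 0.05, 3.9)[sample(n)]
  df
}

## small simulated multi-subject data set for hierarchical fits
make_subjects <- function(n_subjects, n_runs, trials_per_run, params_list,
                          seed = 1) {
  cfg <- task_config(n_runs_learning = n_runs,
                     trials_per_run = trials_per_run, n_runs_transfer = 0)
  lapply(seq_len(n_subjects), function(i) {
    sim <- simulate_agent(params_list[[i]], cfg, seed = seed + i)
    sim$trials[sim$trials$phase == "learning", ]
  })
}
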