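#' Probabilistic selection task configuration
#'
#' Describes the two-phase probabilistic selection task: a learning phase
#' with three fixed option pairs rewarded at complementary probabilities
#' (AB 80/20, CD 70/30, EF 60/40 by default) followed by a transfer phase
#' pairing all options without feedback.
#'
#' @param pairs Data frame with columns `option_hi`, `option_lo`,
#'   `p_reward_hi`; the low option of a pair is rewarded with probability
#'   `1 - p_reward_hi`.
#' @param reward_magnitude Points per rewarded choice (bookkeeping only).
#' @param n_runs_learning,trials_per_run,n_runs_transfer Run structure;
#'   defaults give 6 x 60 = 360 learning and 5 x 60 = 300 transfer trials.
#' @param rt_deadline,rt_floor Admissible response-time window in seconds.
#' @param event_timing List of `mean`/`sd` pairs (seconds) for the
#'   fixation interval, the choice-to-feedback interval, and the
#'   inter-trial interval.
#' @return An object of class `task_config`.
#' @export
task_config <- function(pairs = data.frame(option_hi = c("A", "C", "E"),
                                           option_lo = c("B", "D", "F"),
                                           p_reward_hi = c(0.8, 0.7, 0.6)),
                        reward_magnitude = 0.1,
                        n_runs_learning = 6L, trials_per_run = 60L,
                        n_runs_transfer = 5L,
                        rt_deadline = 3.5, rt_floor = 0.15,
                        event_timing = list(
                          fixation = c(mean = 0.5, sd = 0.2),
                          feedback_delay = c(mean = 1.5, sd = 0.3),
                          iti = c(mean = 3.0, sd = 0.3))) {
  stopifnot(is.data.frame(pairs),
            all(c("option_hi", "option_lo", "p_reward_hi") %in% names(pairs)))
  if (any(pairs$p_reward_hi <= 0.5 | pairs$p_reward_hi > 1))
    stop("reward probabilities of the high option must lie in (0.5, 1]")
  opts <- c(pairs$option_hi, pairs$option_lo)
  if (anyDuplicated(opts)) stop("options must be distinct across pairs")
  if (trials_per_run %% nrow(pairs) != 0)
    stop("trials_per_run must be divisible by the number of pairs")
  cfg <- list(pairs = pairs, reward_magnitude = reward_magnitude,
              n_runs_learning = as.integer(n_runs_learning),
              trials_per_run = as.integer(trials_per_run),
              n_runs_transfer = as.integer(n_runs_transfer),
              rt_deadline = rt_deadline, rt_floor = rt_floor,
              event_timing = event_timing,
              options = opts)
  # all unordered pairings of the option set, for the transfer phase
  cmb <- utils::combn(sort(opts), 2L)
  cfg$transfer_pairs <- paste0(cmb[1, ], cmb[2, ])
  if (cfg$n_runs_transfer > 0 &&
      trials_per_run %% length(cfg$transfer_pairs) != 0)
    stop("trials_per_run must be divisible by the number of transfer pairs")
  structure(cfg, class = "task_config")
}

## Internal: pair label of a learning pair row, e.g. "AB".
.pair_label <- function(cfg) paste0(cfg$pairs$option_hi, cfg$pairs$option_lo)

## Internal: sample truncated Gaussian interval, floored at 50 ms so the
## session clock is strictly increasing within a trial.
.rtrunc_interval <- function(n, ms) pmax(stats::rnorm(n, ms["mean"], ms["sd"]), 0.05)

#' Build the task schedule
#'
#' Generates the full trial skeleton (pair sequence and event timestamps,
#' no choices): per learning run each pair appears `trials_per_run /
#' n_pairs` times in shuffled order; per transfer run each of the 15
#' pairings appears equally often. Choice-dependent timestamps
#' (`t_choice`, `t_feedback`, `t_options_off`) are filled in by
#' [simulate_agent()] or by real data.
#'
#' @param config A [task_config()].
#' @param seed Integer seed controlling shuffling and interval draws.
#' @return Data frame with one row per trial: `phase`, `run`, `trial`,
#'   `pair`, `side_left` (option shown left), `t_fixation`,
#'   `t_options_on`, and `NA` placeholders for the choice-dependent
#'   fields.
#' @export
build_schedule <- function(config, seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  labels <- .pair_label(config)
  sched <- list()
  clock <- 0
  mk_phase <- function(phase, n_runs, pool) {
    reps <- config$trials_per_run / length(pool)
    out <- vector("list", n_runs)
    for (run in seq_len(n_runs)) {
      pair <- sample(rep(pool, reps))
      n <- length(pair)
      fix_iv <- .rtrunc_interval(n, config$event_timing$fixation)
      iti <- .rtrunc_interval(n, config$event_timing$iti)
      t_fix <- numeric(n)
      t_on <- numeric(n)
      for (i in seq_len(n)) {
        t_fix[i] <- clock
        t_on[i] <- clock + fix_iv[i]
        # provisional advance: deadline + feedback delay mean + iti; the
        # simulator re-times trials once choices exist
        clock <<- t_on[i] + config$rt_deadline +
          config$event_timing$feedback_delay[["mean"]] + iti[i]
      }
      side <- ifelse(stats::runif(n) < 0.5,
                     substr(pair, 1L, 1L), substr(pair, 2L, 2L))
      out[[run]] <- data.frame(
        phase = phase, run = run, trial = NA_integer_, pair = pair,
        side_left = side, choice = NA_character_, outcome = NA_integer_,
        rt = NA_real_, t_fixation = t_fix, t_options_on = t_on,
        t_choice = NA_real_, t_feedback = NA_real_,
        t_options_off = NA_real_, stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  learning <- mk_phase("learning", config$n_runs_learning, labels)
  transfer <- if (config$n_runs_transfer > 0)
    mk_phase("transfer", config$n_runs_transfer, config$transfer_pairs)
  else NULL
  out <- rbind(learning, transfer)
  out$trial <- stats::ave(seq_len(nrow(out)), out$phase, FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Sample probabilistic feedback for a choice
#'
#' Bernoulli reward draw: probability `p_reward_hi` if the chosen option
#' is the pair's high option, `1 - p_reward_hi` otherwise. Uses the
#' current R random-number stream.
#'
#' @param pair Pair label, e.g. `"AB"` (must be a learning pair of
#'   `config`).
#' @param choice Chosen option letter, a member of `pair`.
#' @param config A [task_config()].
#' @param n Number of draws (default 1).
#' @return Integer vector of 0/1 outcomes.
#' @export
sample_feedback <- function(pair, choice, config, n = 1L) {
  stopifnot(inherits(config, "task_config"))
  labels <- .pair_label(config)
  k <- match(pair, labels)
  if (is.na(k)) stop("unknown learning pair: ", pair)
  hi <- config$pairs$option_hi[k]
  lo <- config$pairs$option_lo[k]
  if (!choice %in% c(hi, lo)) stop("choice ", choice, " not in pair ", pair)
  p <- if (choice == hi) config$pairs$p_reward_hi[k] else 1 - config$pairs$p_reward_hi[k]
  as.integer(stats::runif(n) < p)
}

## Internal: draw RTs from a log-normal with median 0.8 s and sigma 0.3,
## truncated to the admissible window by resampling.
.sample_rt <- function(n, config) {
  rt <- stats::rlnorm(n, meanlog = log(0.8), sdlog = 0.3)
  bad <- rt < config$rt_floor | rt > config$rt_deadline
  while (any(bad)) {
    rt[bad] <- stats::rlnorm(sum(bad), meanlog = log(0.8), sdlog = 0.3)
    bad <- rt < config$rt_floor | rt > config$rt_deadline
  }
  rt
}

#' Simulate a Q-learning agent on the task
#'
#' Samples choices from the softmax rule, updates values with the delta
#' rule after each learning-phase outcome, and freezes values for the
#' transfer phase. Event timestamps are laid out on one session clock
#' using the configured interval distributions.
#'
#' @param params An [agent_params()] object.
#' @param config A [task_config()].
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @return A list with `trials` (completed trial data frame),
#'   `trajectory` (learning-phase [compute_trajectory()] output),
#'   `transfer` ([transfer_values()] output, `NULL` if no transfer runs)
#'   and `final_q`.
#' @export
simulate_agent <- function(params, config, seed = 1L) {
  stopifnot(inherits(params, "agent_params"), inherits(config, "task_config"))
  sched <- build_schedule(config, seed = seed)
  set.seed(seed + 1000003L)
  labels <- .pair_label(config)
  options <- sort(config$options)
  q <- rep(0.5, length(options))
  names(q) <- options
  n <- nrow(sched)
  rt <- .sample_rt(n, config)
  fb_delay <- .rtrunc_interval(n, config$event_timing$feedback_delay)
  iti <- .rtrunc_interval(n, config$event_timing$iti)
  # jittered option-offset delays; exactly constant delays would make
  # offset regressors collinear with their anchor event in the FIR design
  off_learn <- stats::runif(n, 0.3, 0.9)
  off_trans <- stats::runif(n, 0.1, 0.5)
  fix_iv <- sched$t_options_on - sched$t_fixation
  clock <- 0
  for (i in seq_len(n)) {
    pair <- sched$pair[i]
    a <- substr(pair, 1L, 1L)
    b <- substr(pair, 2L, 2L)
    p_a <- choice_prob(q[[a]], q[[b]], params$beta)
    ch <- if (stats::runif(1) < p_a) a else b
    sched$choice[i] <- ch
    sched$rt[i] <- rt[i]
    sched$t_fixation[i] <- clock
    sched$t_options_on[i] <- clock + fix_iv[i]
    sched$t_choice[i] <- sched$t_options_on[i] + rt[i]
    if (sched$phase[i] == "learning") {
      r <- sample_feedback(pair, ch, config)
      sched$outcome[i] <- r
      sched$t_feedback[i] <- sched$t_choice[i] + fb_delay[i]
      sched$t_options_off[i] <- sched$t_feedback[i] + off_learn[i]
      q[[ch]] <- update_q(q[[ch]], r, params)
    } else {
      sched$t_options_off[i] <- sched$t_choice[i] + off_trans[i]
    }
    clock <- sched$t_options_off[i] + iti[i]
  }
  learning <- sched[sched$phase == "learning", ]
  transfer <- sched[sched$phase == "transfer", ]
  traj <- compute_trajectory(learning, params)
  final_q <- attr(traj, "final_q")
  tv <- if (nrow(transfer) > 0) transfer_values(final_q, transfer) else NULL
  list(trials = sched, trajectory = traj, transfer = tv, final_q = final_q)
}

#' Accuracy by run and pair
#'
#' Fraction of trials on which the pair's higher-probability option was
#' chosen, tabulated by learning run and pair.
#'
#' @param trials Completed trial data frame (learning phase rows used).
#' @param config A [task_config()].
#' @return Data frame with `run`, `pair`, `accuracy`.
#' @export
accuracy_by_run <- function(trials, config) {
  learning <- trials[trials$phase == "learning" & !is.na(trials$choice), ]
  hi <- config$pairs$option_hi[match(learning$pair, .pair_label(config))]
  correct <- as.integer(learning$choice == hi)
  agg <- stats::aggregate(correct,
                          by = list(run = learning$run, pair = learning$pair),
                          FUN = mean)
  names(agg)[3] <- "accuracy"
  agg[order(agg$pair, agg$run), ]
}
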