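#' Q-learning agent parameters
#'
#' Bundle of the three subject-level parameters of the asymmetric
#' Q-learning model: a learning rate for rewarded outcomes, a learning
#' rate for unrewarded outcomes, and the softmax inverse temperature
#' ("explore-exploit" parameter).
#'
#' @param alpha_gain Learning rate applied after rewarded outcomes, in
#'   `[0, 1]`.
#' @param alpha_loss Learning rate applied after unrewarded outcomes, in
#'   `[0, 1]`.
#' @param beta Softmax inverse temperature, in `[0, 100]`. Higher values
#'   make choices more deterministic toward the higher-valued option.
#' @return An object of class `agent_params`.
#' @export
#' @examples
#' agent_params(0.4, 0.2, 8)
agent_params <- function(alpha_gain, alpha_loss, beta) {
  stopifnot(is.numeric(alpha_gain), length(alpha_gain) == 1L,
            is.numeric(alpha_loss), length(alpha_loss) == 1L,
            is.numeric(beta), length(beta) == 1L)
  if (alpha_gain < 0 || alpha_gain > 1) stop("alpha_gain must be in [0, 1]")
  if (alpha_loss < 0 || alpha_loss > 1) stop("alpha_loss must be in [0, 1]")
  if (beta < 0 || beta > 100) stop("beta must be in [0, 100]")
  structure(list(alpha_gain = alpha_gain, alpha_loss = alpha_loss,
                 beta = beta), class = "agent_params")
}

#' @exportS3Method base::print
print.agent_params <- function(x, ...) {
  cat(sprintf("Q-learning agent: alpha_gain = %.3f, alpha_loss = %.3f, beta = %.2f\n",
              x$alpha_gain, x$alpha_loss, x$beta))
  invisible(x)
}

#' Delta-rule value update
#'
#' Updates the chosen option's value estimate with the reward prediction
#' error `r - q`, scaled by `alpha_gain` when `r = 1` and `alpha_loss`
#' when `r = 0`.
#'
#' @param q Current value estimate in `[0, 1]`.
#' @param r Binary outcome, 0 or 1.
#' @param params An [agent_params()] object.
#' @return Updated value, guaranteed to stay in `[0, 1]`.
#' @export
update_q <- function(q, r, params) {
  stopifnot(inherits(params, "agent_params"))
  if (any(q < 0 | q > 1)) stop("q must be in [0, 1]")
  if (!all(r %in% c(0, 1))) stop("r must be binary (0 or 1)")
  alpha <- ifelse(r == 1, params$alpha_gain, params$alpha_loss)
  q + alpha * (r - q)
}

#' Softmax choice probability for a two-option pair
#'
#' Probability of choosing option A over option B given their current
#' values, `P(A) = exp(beta * q_a) / (exp(beta * q_a) + exp(beta * q_b))`.
#' Computed with max-subtraction so it is stable at the upper bound
#' `beta = 100`.
#'
#' @param q_a,q_b Value estimates of the two options.
#' @param beta Softmax inverse temperature.
#' @return Probability of choosing A, in `(0, 1)`; vectorised over inputs.
#' @export
choice_prob <- function(q_a, q_b, beta) {
  if (any(beta < 0 | beta > 100)) stop("beta must be in [0, 100]")
  xa <- beta * q_a
  xb <- beta * q_b
  m <- pmax(xa, xb)
  ea <- exp(xa - m)
  ea / (ea + exp(xb - m))
}

## Internal: map option letters (A..F) to integer indices and assemble the
## integer vectors the C++ recursion consumes. Outcome NA -> -1 (no update).
.ql_encode <- function(trials) {
  pair <- as.character(trials$pair)
  opt_a <- substr(pair, 1L, 1L)
  opt_b <- substr(pair, 2L, 2L)
  options <- sort(unique(c(opt_a, opt_b)))
  idx <- function(x) match(x, options)
  choice <- as.character(trials$choice)
  if (!all(choice == opt_a | choice == opt_b))
    stop("every choice must be a member of its pair")
  outcome <- trials$outcome
  outcome[is.na(outcome)] <- -1L
  list(opt_a = idx(opt_a) - 1L, opt_b = idx(opt_b) - 1L,
       choice = idx(choice) - 1L, outcome = as.integer(outcome),
       options = options)
}

#' Negative log-likelihood of learning-phase choices
#'
#' Evolves Q-values with [update_q()] over the trial sequence (all options
#' initialised at 0.5) and accumulates `-log P(choice)` under the softmax
#' rule. Trials whose RT falls outside `rt_window` are excluded from the
#' likelihood but their outcomes still drive the value update, since the
#' agent experienced the feedback.
#'
#' @param trials Learning-phase trial data frame with columns `pair`,
#'   `choice`, `outcome`, and optionally `rt`.
#' @param params An [agent_params()] object.
#' @param rt_window Inclusion window for RTs in seconds (default 0.15 to
#'   3.5); trials without an `rt` column are all included.
#' @return The scalar negative log-likelihood.
#' @export
qlearn_nll <- function(trials, params, rt_window = c(0.15, 3.5)) {
  stopifnot(inherits(params, "agent_params"))
  if (any(is.na(trials$outcome)))
    stop("likelihood requires outcomes on every trial (learning phase only)")
  enc <- .ql_encode(trials)
  include <- if (!is.null(trials$rt)) {
    trials$rt >= rt_window[1] & trials$rt <= rt_window[2]
  } else rep(TRUE, nrow(trials))
  ql_nll_cpp(enc$opt_a, enc$opt_b, enc$choice, enc$outcome, include,
             params$alpha_gain, params$alpha_loss, params$beta,
             length(enc$options))
}

#' Single-trial value and prediction-error trajectory
#'
#' Replays the learning-phase trial sequence under the delta rule and
#' returns, per trial, the pre-update value of the chosen and unchosen
#' options, the signed reward prediction error `r - Q_chosen`, and their
#' difference. Pre-update values are the beliefs that drove the choice.
#'
#' @param trials Learning-phase trial data frame in session order.
#' @param params An [agent_params()] object (only the learning rates are
#'   used).
#' @return A data frame with columns `trial`, `q_chosen`, `q_unchosen`,
#'   `rpe`, `delta_value`; the per-trial per-option value matrix is
#'   attached as attribute `"q_by_option"` and the end-of-learning values
#'   as attribute `"final_q"` (a named vector over options).
#' @export
compute_trajectory <- function(trials, params) {
  stopifnot(inherits(params, "agent_params"))
  if (!is.null(trials$trial) && is.unsorted(order(seq_len(nrow(trials)))[order(trials$trial)]))
    trials <- trials[order(trials$trial), ]
  enc <- .ql_encode(trials)
  res <- ql_traj_cpp(enc$opt_a, enc$opt_b, enc$choice, enc$outcome,
                     params$alpha_gain, params$alpha_loss,
                     length(enc$options))
  out <- data.frame(trial = seq_len(nrow(trials)),
                    q_chosen = res$q_chosen, q_unchosen = res$q_unchosen,
                    rpe = res$rpe,
                    delta_value = res$q_chosen - res$q_unchosen)
  colnames(res$q_by_option) <- enc$options
  attr(out, "q_by_option") <- res$q_by_option
  fq <- res$final_q
  names(fq) <- enc$options
  attr(out, "final_q") <- fq
  out
}

#' Transfer-phase values from frozen end-of-learning estimates
#'
#' In the transfer phase no feedback is given, so option values are frozen
#' at their end-of-learning estimates. This looks up, per transfer trial,
#' the value of the chosen and unchosen options; no updating occurs.
#'
#' @param final_q Named numeric vector of end-of-learning values, one per
#'   option (e.g. the `"final_q"` attribute of [compute_trajectory()]).
#' @param transfer_trials Transfer-phase trial data frame with `pair` and
#'   `choice` columns.
#' @return Data frame with `trial`, `q_chosen`, `q_unchosen`, `delta_value`.
#' @export
transfer_values <- function(final_q, transfer_trials) {
  pair <- as.character(transfer_trials$pair)
  opt_a <- substr(pair, 1L, 1L)
  opt_b <- substr(pair, 2L, 2L)
  needed <- unique(c(opt_a, opt_b))
  if (!all(needed %in% names(final_q)))
    stop("final_q is missing options: ",
         paste(setdiff(needed, names(final_q)), collapse = ", "))
  choice <- as.character(transfer_trials$choice)
  unchosen <- ifelse(choice == opt_a, opt_b, opt_a)
  data.frame(trial = seq_len(nrow(transfer_trials)),
             q_chosen = unname(final_q[choice]),
             q_unchosen = unname(final_q[unchosen]),
             delta_value = unname(final_q[choice] - final_q[unchosen]))
}
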