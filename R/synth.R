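#' Synthetic pupil recording specification
#'
#' The generator emulates the statistical structure the deconvolution
#' analysis assumes: a linear time-invariant superposition of
#' event-locked kernels whose amplitudes are modulated by z-scored
#' single-trial covariates, a sustained boxcar drive during the decision
#' interval, 1/f background noise, and blink/saccade artifacts with
#' their own slow pupil responses.
#'
#' Default effect sizes plant the qualitative pattern the pipeline is
#' meant to recover: a positive pre-choice chosen-value slope, opposite
#' chosen/unchosen value slopes around feedback (value uncertainty), and
#' a negative reward-prediction-error slope on the late feedback
#' component.
#'
#' @param fs_raw Raw sampling rate in Hz (default 1000, the tracker's
#'   native rate; tests use lower rates for speed).
#' @param irf_w,irf_t_max Canonical pupil IRF parameters.
#' @param base_gains Named amplitudes (z-units) of the unmodulated
#'   event kernels.
#' @param boxcar_amp Sustained drive during the decision interval.
#' @param effect_sizes Named covariate slopes in z-units per z-scored
#'   covariate unit.
#' @param noise_sd SD of the 1/f background noise (z-units).
#' @param noise_exponent Spectral exponent of the background noise
#'   (power ~ 1/f^exponent).
#' @param blink_rate,saccade_rate Artifact rates per minute.
#' @param saccade_big_frac Fraction of saccades exceeding the 3.3 degree
#'   rejection threshold.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs_raw = 1000,
                       irf_w = 10.1, irf_t_max = 0.93,
                       base_gains = c(fixation = 0.1, options_on = 0.4,
                                      choice = 0.5, feedback_fast = 0.8,
                                      feedback_slow = -0.9,
                                      options_off = 0.1),
                       boxcar_amp = 0.2,
                       effect_sizes = c(q_chosen_choice = 0.3,
                                        q_unchosen_choice = 0,
                                        q_chosen_fb = -0.15,
                                        q_unchosen_fb = 0.15,
                                        rpe_fb = -0.3),
                       noise_sd = 0.5, noise_exponent = 1,
                       blink_rate = 10, saccade_rate = 6,
                       saccade_big_frac = 0.05) {
  stopifnot(noise_sd >= 0, blink_rate >= 0, saccade_rate >= 0)
  structure(list(fs_raw = fs_raw, irf_w = irf_w, irf_t_max = irf_t_max,
                 base_gains = base_gains, boxcar_amp = boxcar_amp,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 noise_exponent = noise_exponent, blink_rate = blink_rate,
                 saccade_rate = saccade_rate,
                 saccade_big_frac = saccade_big_frac),
            class = "synth_spec")
}

## ---- ground-truth kernels, defined in continuous time ---------------------

## Kernels are chosen to be (numerically) compactly supported inside the
## deconvolution windows; mass beyond the estimated lags would otherwise
## alias into collinear regressors and bias amplitude recovery.

## pre-choice decision bump on the choice window [-2, 1.5]
.kern_choice_bump <- function(t) exp(-(t + 0.3)^2 / (2 * 0.5^2))

## post-choice lobe (value-difference reversal after the choice)
.kern_post_choice <- function(t) ifelse(t > 0, exp(-(t - 0.7)^2 / (2 * 0.35^2)), 0)

## chosen-value kernel: pre-choice dilation plus a negative post-choice
## lobe, so the planted chosen-minus-unchosen difference flips sign at choice
.kern_qc_choice <- function(t) .kern_choice_bump(t) - 0.5 * .kern_post_choice(t)

## slow (late, ~2 s peak) feedback constriction component
.kern_slow <- function(t) exp(-(t - 2)^2 / (2 * 0.35^2))

## table of kernel function + window + amplitude for one phase
.synth_components <- function(trials, covars, spec, phase) {
  fast <- function(t) pupil_irf(t, spec$irf_w, spec$irf_t_max)
  g <- spec$base_gains
  e <- spec$effect_sizes
  zs <- function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  comp <- list(
    list(name = "fixation", events = trials$t_fixation, window = c(0, 3),
         kernel = fast, amps = rep(g[["fixation"]], nrow(trials))),
    list(name = "options_on", events = trials$t_options_on, window = c(0, 3),
         kernel = fast, amps = rep(g[["options_on"]], nrow(trials))),
    list(name = "choice_base", events = trials$t_choice, window = c(-2, 1.5),
         kernel = .kern_choice_bump, amps = rep(g[["choice"]], nrow(trials))),
    list(name = "options_off", events = trials$t_options_off, window = c(0, 3),
         kernel = fast, amps = rep(g[["options_off"]], nrow(trials))))
  if (phase == "learning") {
    comp <- c(comp, list(
      list(name = "feedback_fast", events = trials$t_feedback, window = c(0, 3),
           kernel = fast, amps = rep(g[["feedback_fast"]], nrow(trials))),
      list(name = "feedback_slow", events = trials$t_feedback, window = c(0, 3.2),
           kernel = .kern_slow, amps = rep(g[["feedback_slow"]], nrow(trials))),
      list(name = "cov_q_chosen_choice", events = trials$t_choice,
           window = c(-2, 1.5), kernel = .kern_qc_choice,
           amps = e[["q_chosen_choice"]] * zs(covars$q_chosen)),
      list(name = "cov_q_unchosen_choice", events = trials$t_choice,
           window = c(-2, 1.5), kernel = .kern_post_choice,
           amps = e[["q_unchosen_choice"]] * zs(covars$q_unchosen)),
      list(name = "cov_q_chosen_fb", events = trials$t_feedback,
           window = c(0, 3), kernel = fast,
           amps = e[["q_chosen_fb"]] * zs(covars$q_chosen)),
      list(name = "cov_q_unchosen_fb", events = trials$t_feedback,
           window = c(0, 3), kernel = fast,
           amps = e[["q_unchosen_fb"]] * zs(covars$q_unchosen)),
      list(name = "cov_rpe_fb", events = trials$t_feedback,
           window = c(0, 3.2), kernel = .kern_slow,
           amps = e[["rpe_fb"]] * zs(covars$rpe))))
  }
  # transfer: no feedback events and, by default, no planted value
  # modulation -- mirrors the learning/transfer dissociation under test
  comp
}

## ground-truth response of each deconvolution regressor at 20 Hz lags
.synth_truth <- function(spec, phase, fs_out = 20) {
  fast <- function(t) pupil_irf(t, spec$irf_w, spec$irf_t_max)
  g <- spec$base_gains
  e <- spec$effect_sizes
  lag <- function(w) seq(round(w[1] * fs_out), round(w[2] * fs_out)) / fs_out
  tr <- list()
  add <- function(name, lags, beta) {
    tr[[name]] <<- data.frame(regressor = name, lag = lags, beta = beta)
  }
  l_on <- lag(c(-0.5, 3)); l_ch <- lag(c(-2, 1.5))
  add("fixation", l_on, g[["fixation"]] * fast(l_on))
  add("options_on", l_on, g[["options_on"]] * fast(l_on))
  add("choice", l_ch, g[["choice"]] * .kern_choice_bump(l_ch))
  add("options_off", l_on, g[["options_off"]] * fast(l_on))
  if (phase == "learning") {
    add("feedback", l_on, g[["feedback_fast"]] * fast(l_on) +
          g[["feedback_slow"]] * .kern_slow(l_on))
    add("q_chosen_choice", l_ch,
        e[["q_chosen_choice"]] * .kern_qc_choice(l_ch))
    add("q_unchosen_choice", l_ch,
        e[["q_unchosen_choice"]] * .kern_post_choice(l_ch))
    add("q_chosen_fb", l_on, e[["q_chosen_fb"]] * fast(l_on))
    add("q_unchosen_fb", l_on, e[["q_unchosen_fb"]] * fast(l_on))
    add("rpe_fb", l_on, e[["rpe_fb"]] * .kern_slow(l_on))
  } else {
    add("q_chosen_choice", l_ch, 0 * l_ch)
    add("q_unchosen_choice", l_ch, 0 * l_ch)
  }
  do.call(rbind, c(tr, make.row.names = FALSE))
}

## full linear convolution via FFT, padded to a 2-3-5-smooth length
## (stats::convolve does not pad, which is quadratic at awkward lengths)
.fft_convolve <- function(x, k) {
  nfull <- length(x) + length(k) - 1L
  m <- stats::nextn(nfull, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(m - length(x))))
  K <- stats::fft(c(k, numeric(m - length(k))))
  Re(stats::fft(X * K, inverse = TRUE))[seq_len(nfull)] / m
}

## spectrally shaped Gaussian noise, exact target SD, zero mean
.one_over_f_noise <- function(n, sd, exponent) {
  if (sd == 0) return(numeric(n))
  n_out <- n
  n <- stats::nextn(n, c(2, 3, 5))   # smooth FFT length
  white <- stats::rnorm(n)
  f <- stats::fft(white)
  freq <- c(1, seq_len(n - 1))           # avoid dividing DC by zero
  freq <- pmin(freq, n - freq + 1)       # mirror for negative frequencies
  shape <- freq^(-exponent / 2)
  shape[1] <- 0                          # remove DC
  x <- Re(stats::fft(f * shape, inverse = TRUE))[seq_len(n_out)]
  sd * (x - mean(x)) / stats::sd(x)
}

#' Synthesize a raw pupil recording for one phase
#'
#' Builds the continuous pupil trace implied by the trial events of one
#' phase: event kernels with covariate-modulated amplitudes, the
#' sustained decision boxcar, 1/f noise, blink artifacts (sharp signal
#' drops plus a slow recovery response), and sub- and supra-threshold
#' saccades with small pupil responses. The true deconvolution
#' coefficients are returned alongside.
#'
#' @param trials Trial data frame of a single phase.
#' @param covars Matching covariate rows: [compute_trajectory()] output
#'   for the learning phase, [transfer_values()] output for the transfer
#'   phase (ignored then, since no modulation is planted).
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @return List with `ts` (raw [pupil_ts()]), `blinks`
#'   (`start`/`end`), `saccades` (`time`/`amplitude`), and
#'   `ground_truth` (data frame `regressor`, `lag`, `beta` at 20 Hz).
#' @export
generate_session <- function(trials, covars, spec = synth_spec(), seed = 1L) {
  stopifnot(inherits(spec, "synth_spec"))
  phase <- unique(trials$phase)
  if (length(phase) != 1) stop("trials must belong to a single phase")
  if (phase == "learning" && nrow(covars) != nrow(trials))
    stop("covars must have one row per trial")
  fs <- spec$fs_raw
  t_start <- floor(min(trials$t_fixation) - 3)
  t_end <- ceiling(max(trials$t_options_off, na.rm = TRUE) + 5)
  tt <- seq(t_start, t_end, by = 1 / fs)
  n <- length(tt)
  set.seed(seed)
  sig <- numeric(n)
  # each component is a stick train (with per-event amplitudes) convolved
  # with its sampled kernel; FFT convolution keeps this O(n log n)
  add_events <- function(events, window, kernel, amps) {
    shift <- round(window[1] * fs)
    lags <- seq(shift, round(window[2] * fs))
    kv <- kernel(lags / fs)
    stick <- numeric(n)
    idx <- round((events - t_start) * fs) + 1L
    ok <- idx >= 1 & idx <= n & amps != 0
    if (!any(ok)) return(invisible())
    for (j in which(ok)) stick[idx[j]] <- stick[idx[j]] + amps[j]
    y <- .fft_convolve(stick, kv)
    src <- seq_len(n) - shift            # sig[i] += y[i - shift]
    ok2 <- src >= 1 & src <= length(y)
    sig[ok2] <<- sig[ok2] + y[src[ok2]]
  }
  for (cp in .synth_components(trials, covars, spec, phase))
    add_events(cp$events, cp$window, cp$kernel, cp$amps)
  # sustained decision drive
  for (j in seq_len(nrow(trials))) {
    i0 <- round((trials$t_options_on[j] - t_start) * fs) + 1L
    i1 <- round((trials$t_choice[j] - t_start) * fs) + 1L
    sig[i0:i1] <- sig[i0:i1] + spec$boxcar_amp
  }
  sig <- sig + .one_over_f_noise(n, spec$noise_sd, spec$noise_exponent)

  dur_min <- (t_end - t_start) / 60
  # blinks: data-loss artifact (sharp drop) plus a slow recovery response
  n_blinks <- stats::rpois(1, spec$blink_rate * dur_min)
  blink_start <- sort(stats::runif(n_blinks, t_start + 2, t_end - 2))
  blink_dur <- stats::runif(n_blinks, 0.1, 0.25)
  blinks <- data.frame(start = blink_start, end = blink_start + blink_dur)
  for (j in seq_len(n_blinks)) {
    i0 <- round((blinks$start[j] - t_start) * fs) + 1L
    i1 <- round((blinks$end[j] - t_start) * fs) + 1L
    sig[i0:i1] <- sig[i0:i1] - 4
  }
  if (n_blinks > 0)
    add_events(blinks$end, c(0, 3),
               function(t) pupil_irf(t, spec$irf_w, spec$irf_t_max),
               rep(-0.3, n_blinks))
  # saccades: mostly small, a configurable fraction beyond threshold
  n_sac <- stats::rpois(1, spec$saccade_rate * dur_min)
  sac_time <- sort(stats::runif(n_sac, t_start + 2, t_end - 2))
  big <- stats::runif(n_sac) < spec$saccade_big_frac
  amp <- ifelse(big, stats::runif(n_sac, 3.5, 6),
                stats::runif(n_sac, 0.2, 2.5))
  saccades <- data.frame(time = sac_time, amplitude = amp)
  if (n_sac > 0)
    add_events(sac_time, c(0, 3),
               function(t) pupil_irf(t, spec$irf_w, spec$irf_t_max),
               rep(-0.1, n_sac))

  # run id per sample from the trial run boundaries
  run_starts <- tapply(trials$t_fixation, trials$run, min)
  run_id <- as.integer(names(run_starts))[
    pmax(1L, findInterval(tt, as.numeric(run_starts)))]
  list(ts = pupil_ts(tt, sig, fs, run_id), blinks = blinks,
       saccades = saccades,
       ground_truth = .synth_truth(spec, phase))
}

#' Generate a full synthetic cohort
#'
#' Samples per-subject agent parameters from the probit-normal
#' hierarchical generative model, simulates each subject's behavior on
#' the task, and synthesizes raw pupil recordings for the learning and
#' transfer phases. Optionally writes every artifact in the pipeline's
#' interchange formats.
#'
#' @param n_subjects Cohort size (default 34).
#' @param group List with `mu` and `delta`, the group-level mean and SD
#'   of the transformed parameters (defaults 0 and 1.2).
#' @param config A [task_config()].
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @param out_dir Output directory, or `NULL` to keep everything in
#'   memory.
#' @return List of class `synth_cohort`: per-subject entries with
#'   `params` (true [agent_params()]), `trials`, `trajectory`,
#'   `transfer`, `learning_pupil`, `transfer_pupil`; plus `config`,
#'   `spec`, `manifest`.
#' @export
generate_cohort <- function(n_subjects = 34,
                            group = list(mu = c(0, 0, 0),
                                         delta = c(1.2, 1.2, 1.2)),
                            config = task_config(), spec = synth_spec(),
                            seed = 1L, out_dir = NULL) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n_subjects * 3, rep(group$mu, each = n_subjects),
                           rep(group$delta, each = n_subjects)),
              n_subjects, 3)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    params <- probit_to_native(z[i, ])
    beh <- simulate_agent(params, config, seed = seed + 13L * i)
    learning <- beh$trials[beh$trials$phase == "learning", ]
    transfer <- beh$trials[beh$trials$phase == "transfer", ]
    pl <- generate_session(learning, beh$trajectory, spec,
                           seed = seed + 13L * i + 1L)
    pt <- if (nrow(transfer) > 0)
      generate_session(transfer, beh$transfer, spec,
                       seed = seed + 13L * i + 2L)
    else NULL
    subjects[[i]] <- list(subject = i, params = params, z_true = z[i, ],
                          trials = beh$trials, trajectory = beh$trajectory,
                          transfer = beh$transfer, final_q = beh$final_q,
                          learning_pupil = pl, transfer_pupil = pt)
  }
  manifest <- list(n_subjects = n_subjects, seed = seed,
                   group = group,
                   true_params = data.frame(
                     subject = seq_len(n_subjects),
                     alpha_gain = stats::pnorm(z[, 1]),
                     alpha_loss = stats::pnorm(z[, 2]),
                     beta = 100 * stats::pnorm(z[, 3])),
                   effect_sizes = as.list(spec$effect_sizes))
  cohort <- structure(list(subjects = subjects, config = config, spec = spec,
                           manifest = manifest),
                      class = "synth_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @exportS3Method base::print
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synth_cohort: %d subjects, seed %d\n",
              x$manifest$n_subjects, x$manifest$seed))
  invisible(x)
}
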