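#' Priors of the hierarchical Q-learning model
#'
#' Group-level means of the probit-transformed parameters receive a
#' normal prior; group-level standard deviations receive a uniform
#' prior. Defaults are a standard normal for the means and
#' `Uniform(1, 1.5)` for the SDs; all four literals are configurable.
#'
#' @param mu_mean,mu_sd Normal prior on each group mean.
#' @param sd_lower,sd_upper Uniform prior support for each group SD.
#' @return A list of class `hb_priors`.
#' @export
hb_priors <- function(mu_mean = 0, mu_sd = 1, sd_lower = 1, sd_upper = 1.5) {
  stopifnot(mu_sd > 0, sd_upper > sd_lower, sd_lower > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd,
                 sd_lower = sd_lower, sd_upper = sd_upper),
            class = "hb_priors")
}

#' MCMC sampler settings
#'
#' @param n_chains Number of independent chains (>= 2 for convergence
#'   diagnostics; default 4).
#' @param n_warmup Adaptation iterations discarded per chain (default
#'   1000).
#' @param n_draws Retained iterations per chain (default 1000).
#' @param seed Integer seed; chains derive their own sub-seeds from it.
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 1000L,
                           seed = 1L) {
  stopifnot(n_chains >= 2, n_warmup >= 0, n_draws >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

## parameter names per model variant
.hb_pnames <- function(variant) {
  if (variant == "two_alpha") c("alpha_gain", "alpha_loss", "beta") else c("alpha", "beta")
}

#' Probit transform to native parameter scale
#'
#' Maps unbounded latent parameters to their native bounds through the
#' standard normal CDF: learning rates to `[0, 1]`, the inverse
#' temperature to `[0, 100]`.
#'
#' @param z_prime Numeric vector of transformed parameters, ordered
#'   `(alpha_gain', alpha_loss', beta')` for the two-learning-rate model
#'   or `(alpha', beta')` for the single-rate variant.
#' @param variant `"two_alpha"` (default) or `"one_alpha"`.
#' @return An [agent_params()] object.
#' @export
probit_to_native <- function(z_prime, variant = c("two_alpha", "one_alpha")) {
  variant <- match.arg(variant)
  if (variant == "two_alpha") {
    stopifnot(length(z_prime) == 3)
    agent_params(stats::pnorm(z_prime[1]), stats::pnorm(z_prime[2]),
                 100 * stats::pnorm(z_prime[3]))
  } else {
    stopifnot(length(z_prime) == 2)
    a <- stats::pnorm(z_prime[1])
    agent_params(a, a, 100 * stats::pnorm(z_prime[2]))
  }
}

## encode one subject's learning trials once; reused at every MCMC step
.hb_encode <- function(trials, rt_window = c(0.15, 3.5)) {
  enc <- .ql_encode(trials)
  include <- if (!is.null(trials$rt)) {
    trials$rt >= rt_window[1] & trials$rt <= rt_window[2]
  } else rep(TRUE, nrow(trials))
  enc$include <- include
  enc$n_modeled <- sum(include)
  enc
}

## subject choice log-likelihood at latent z (native transform inside)
.hb_loglik <- function(enc, z, variant) {
  if (variant == "two_alpha") {
    ag <- stats::pnorm(z[1]); al <- stats::pnorm(z[2])
    b <- 100 * stats::pnorm(z[3])
  } else {
    ag <- al <- stats::pnorm(z[1])
    b <- 100 * stats::pnorm(z[2])
  }
  -ql_nll_cpp(enc$opt_a, enc$opt_b, enc$choice, enc$outcome, enc$include,
              ag, al, b, length(enc$options))
}

#' Log joint density of the hierarchical model
#'
#' Sum of the group-prior log densities, the per-subject
#' `Normal(z'_i | mu, delta)` log densities, and the per-subject choice
#' log-likelihoods at the probit-transformed parameters. Returns `-Inf`
#' when any group SD leaves the uniform prior support.
#'
#' @param data List of learning-phase trial data frames, one per
#'   subject (possibly empty).
#' @param latent Matrix of transformed parameters, subjects x
#'   parameters.
#' @param mu,delta Group-level means and SDs (one per parameter).
#' @param priors An [hb_priors()] object.
#' @param variant Model variant.
#' @return Scalar log density.
#' @export
hb_log_joint <- function(data, latent, mu, delta, priors = hb_priors(),
                         variant = c("two_alpha", "one_alpha")) {
  variant <- match.arg(variant)
  K <- length(.hb_pnames(variant))
  if (any(delta < priors$sd_lower | delta > priors$sd_upper)) return(-Inf)
  lp <- sum(stats::dnorm(mu, priors$mu_mean, priors$mu_sd, log = TRUE)) +
    sum(-log(priors$sd_upper - priors$sd_lower) * K)
  if (length(data) == 0) return(lp)
  latent <- matrix(latent, nrow = length(data), ncol = K)
  for (i in seq_along(data)) {
    enc <- .hb_encode(data[[i]])
    lp <- lp + sum(stats::dnorm(latent[i, ], mu, delta, log = TRUE)) +
      .hb_loglik(enc, latent[i, ], variant)
  }
  lp
}

#' Fit the hierarchical Q-learning model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampler: per-subject latent
#' parameter triples are updated with joint random-walk Metropolis
#' steps, group means with conjugate Gibbs draws, and group SDs with
#' reflected random-walk Metropolis inside their uniform support.
#' Proposal scales adapt toward a 30% acceptance rate during warmup
#' and are then frozen. Only trials with RT inside `rt_window` enter
#' the likelihood.
#'
#' @param data List of learning-phase trial data frames, one per
#'   subject.
#' @param sampler A [sampler_config()].
#' @param priors An [hb_priors()].
#' @param variant `"two_alpha"` (default) or `"one_alpha"`.
#' @param rt_window RT inclusion window in seconds.
#' @return An object of class `hb_fit` with elements `draws` (array
#'   iterations x chains x quantities, named `mu_*`, `delta_*`,
#'   `z[i]_*`), `rhat` (named vector), `converged` (all Rhat <= 1.05),
#'   `variant`, `priors`, `sampler`, `n_modeled` (per-subject modeled
#'   trial counts).
#' @export
fit_hierarchical <- function(data, sampler = sampler_config(),
                             priors = hb_priors(),
                             variant = c("two_alpha", "one_alpha"),
                             rt_window = c(0.15, 3.5)) {
  variant <- match.arg(variant)
  stopifnot(inherits(sampler, "sampler_config"), length(data) >= 1)
  pn <- .hb_pnames(variant)
  K <- length(pn)
  S <- length(data)
  encs <- lapply(data, .hb_encode, rt_window = rt_window)
  if (any(vapply(encs, `[[`, 0L, "n_modeled") == 0))
    stop("every subject needs at least one modeled trial")

  n_iter <- sampler$n_warmup + sampler$n_draws
  qnames <- c(paste0("mu_", pn), paste0("delta_", pn),
              paste0("z[", rep(seq_len(S), each = K), "]_", rep(pn, S)))
  draws <- array(NA_real_, c(sampler$n_draws, sampler$n_chains,
                             length(qnames)),
                 dimnames = list(NULL, NULL, qnames))

  for (ch in seq_len(sampler$n_chains)) {
    set.seed(sampler$seed + 7919L * ch)
    mu <- stats::rnorm(K, priors$mu_mean, priors$mu_sd / 2)
    delta <- stats::runif(K, priors$sd_lower, priors$sd_upper)
    z <- matrix(stats::rnorm(S * K, rep(mu, each = S), 0.5), S, K)
    ll <- vapply(seq_len(S), function(i) .hb_loglik(encs[[i]], z[i, ], variant), 0.0)
    s_z <- rep(0.25, S)
    s_d <- rep(0.1, K)
    acc_z <- integer(S); acc_d <- integer(K); tries <- 0L
    for (it in seq_len(n_iter)) {
      # subjects: joint random-walk on z_i, followed by an independence
      # proposal from the group distribution (acceptance reduces to the
      # likelihood ratio), which lets chains jump between the model's
      # learning-rate/temperature trade-off modes
      for (i in seq_len(S)) {
        zp <- z[i, ] + s_z[i] * stats::rnorm(K)
        llp <- .hb_loglik(encs[[i]], zp, variant)
        logr <- llp - ll[i] +
          sum(stats::dnorm(zp, mu, delta, log = TRUE)) -
          sum(stats::dnorm(z[i, ], mu, delta, log = TRUE))
        if (log(stats::runif(1)) < logr) {
          z[i, ] <- zp; ll[i] <- llp; acc_z[i] <- acc_z[i] + 1L
        }
        zp <- stats::rnorm(K, mu, delta)
        llp <- .hb_loglik(encs[[i]], zp, variant)
        if (log(stats::runif(1)) < llp - ll[i]) {
          z[i, ] <- zp; ll[i] <- llp
        }
      }
      # group means: conjugate normal given z and delta
      prec <- 1 / priors$mu_sd^2 + S / delta^2
      mean_post <- (priors$mu_mean / priors$mu_sd^2 + colSums(z) / delta^2) / prec
      mu <- stats::rnorm(K, mean_post, 1 / sqrt(prec))
      # group SDs: random-walk Metropolis inside the uniform support
      for (k in seq_len(K)) {
        dp <- delta[k] + s_d[k] * stats::rnorm(1)
        if (dp >= priors$sd_lower && dp <= priors$sd_upper) {
          logr <- sum(stats::dnorm(z[, k], mu[k], dp, log = TRUE)) -
            sum(stats::dnorm(z[, k], mu[k], delta[k], log = TRUE))
          if (log(stats::runif(1)) < logr) {
            delta[k] <- dp; acc_d[k] <- acc_d[k] + 1L
          }
        }
      }
      tries <- tries + 1L
      # adapt proposal scales during warmup
      if (it <= sampler$n_warmup && tries == 50L) {
        s_z <- s_z * exp(0.8 * (acc_z / tries - 0.3))
        s_d <- pmin(pmax(s_d * exp(0.8 * (acc_d / tries - 0.3)), 1e-3), 1)
        acc_z[] <- 0L; acc_d[] <- 0L; tries <- 0L
      } else if (tries == 50L) {
        acc_z[] <- 0L; acc_d[] <- 0L; tries <- 0L
      }
      if (it > sampler$n_warmup)
        draws[it - sampler$n_warmup, ch, ] <- c(mu, delta, as.vector(t(z)))
    }
  }
  rh <- apply(draws, 3L, rhat_split)
  structure(list(draws = draws, rhat = rh,
                 converged = all(rh <= 1.05, na.rm = TRUE),
                 variant = variant, priors = priors, sampler = sampler,
                 n_modeled = vapply(encs, `[[`, 0L, "n_modeled"),
                 n_subjects = S, pnames = pn),
            class = "hb_fit")
}

#' @exportS3Method base::print
print.hb_fit <- function(x, ...) {
  cat(sprintf("hb_fit (%s): %d subjects, %d chains x %d draws, max Rhat = %.3f%s\n",
              x$variant, x$n_subjects, dim(x$draws)[2],
              dim(x$draws)[1], max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Split-chain potential scale reduction statistic
#'
#' Gelman-Rubin Rhat computed on split chains: each chain is halved,
#' and the ratio of pooled to within-half variance is reported.
#'
#' @param x Matrix of draws, iterations x chains.
#' @return Scalar Rhat (`NA` for constant draws).
#' @export
rhat_split <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  w <- apply(sp, 2, stats::var)
  if (all(w == 0)) return(NA_real_)
  B <- half * stats::var(colMeans(sp))
  W <- mean(w)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Posterior mode via kernel density estimation
#'
#' Mode of a Gaussian KDE (Silverman's bandwidth) evaluated on a
#' 512-point grid spanning the sample range. Constant samples return
#' that constant.
#'
#' @param x Numeric sample (>= 500 draws recommended).
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0", n = 512, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Per-subject point estimates and information criteria
#'
#' Extracts posterior modes of each subject's native-scale parameters
#' (KDE mode over all chains' draws), evaluates the choice
#' negative log-likelihood at those modes, and computes
#' `AIC = 2k + 2 nll` and `BIC = k log(n) + 2 nll` with `k` free
#' per-subject parameters and `n` modeled trials.
#'
#' @param fit An [fit_hierarchical()] result.
#' @param data The same list of subject trial data frames used for the
#'   fit.
#' @return Data frame, one row per subject: parameter estimates, `nll`,
#'   `k`, `n`, `aic`, `bic`.
#' @export
fit_summary <- function(fit, data) {
  stopifnot(inherits(fit, "hb_fit"), length(data) == fit$n_subjects)
  pn <- fit$pnames
  K <- length(pn)
  S <- fit$n_subjects
  k_free <- if (fit$variant == "two_alpha") 3L else 2L
  rows <- vector("list", S)
  for (i in seq_len(S)) {
    est <- numeric(K)
    for (k in seq_len(K)) {
      zk <- as.vector(fit$draws[, , paste0("z[", i, "]_", pn[k])])
      native <- stats::pnorm(zk)
      if (pn[k] == "beta") native <- 100 * native
      est[k] <- posterior_mode(native)
    }
    params <- if (fit$variant == "two_alpha")
      agent_params(est[1], est[2], est[3])
    else agent_params(est[1], est[1], est[2])
    nll <- qlearn_nll(data[[i]], params)
    n <- fit$n_modeled[i]
    row <- as.list(est)
    names(row) <- pn
    rows[[i]] <- data.frame(subject = i, row, nll = nll, k = k_free, n = n,
                            aic = 2 * k_free + 2 * nll,
                            bic = k_free * log(n) + 2 * nll)
  }
  do.call(rbind, rows)
}

#' Posterior-predictive choice simulation
#'
#' Simulates each subject's session `n_reps` times at their posterior
#' modal parameters and averages choice accuracy by learning run and
#' pair, for comparison against the observed accuracy curves.
#'
#' @param fitsum A [fit_summary()] data frame (needs `alpha_gain`,
#'   `alpha_loss`, `beta` or `alpha`, `beta` columns).
#' @param config A [task_config()].
#' @param n_reps Simulations per subject (default 100).
#' @param seed Integer seed.
#' @return Data frame `subject`, `run`, `pair`, `accuracy` averaged over
#'   repetitions.
#' @export
simulate_from_fit <- function(fitsum, config, n_reps = 100, seed = 1L) {
  out <- vector("list", nrow(fitsum))
  for (i in seq_len(nrow(fitsum))) {
    params <- if ("alpha_gain" %in% names(fitsum))
      agent_params(fitsum$alpha_gain[i], fitsum$alpha_loss[i], fitsum$beta[i])
    else agent_params(fitsum$alpha[i], fitsum$alpha[i], fitsum$beta[i])
    acc <- NULL
    for (rep in seq_len(n_reps)) {
      sim <- simulate_agent(params, config,
                            seed = seed + 100003L * i + rep)
      a <- accuracy_by_run(sim$trials, config)
      acc <- if (is.null(acc)) a else {
        a2 <- acc; a2$accuracy <- a2$accuracy + a$accuracy; a2
      }
    }
    acc$accuracy <- acc$accuracy / n_reps
    acc$subject <- fitsum$subject[i]
    out[[i]] <- acc[, c("subject", "run", "pair", "accuracy")]
  }
  do.call(rbind, out)
}

#' Compare the one- and two-learning-rate model variants
#'
#' Fits both variants to the same data and tabulates per-subject AIC and
#' BIC at the posterior modal estimates (`k = 2` for the single-rate
#' model, `k = 3` for the asymmetric model).
#'
#' @param data List of subject trial data frames.
#' @param sampler A [sampler_config()] used for both fits.
#' @param priors An [hb_priors()].
#' @return List with `table` (per subject: aic/bic for both variants),
#'   `summaries` (both [fit_summary()] frames), `fits`.
#' @export
compare_models <- function(data, sampler = sampler_config(),
                           priors = hb_priors()) {
  fit2 <- fit_hierarchical(data, sampler, priors, variant = "two_alpha")
  fit1 <- fit_hierarchical(data, sampler, priors, variant = "one_alpha")
  s2 <- fit_summary(fit2, data)
  s1 <- fit_summary(fit1, data)
  tab <- data.frame(subject = s2$subject,
                    aic_one_alpha = s1$aic, aic_two_alpha = s2$aic,
                    bic_one_alpha = s1$bic, bic_two_alpha = s2$bic)
  list(table = tab, summaries = list(one_alpha = s1, two_alpha = s2),
       fits = list(one_alpha = fit1, two_alpha = fit2))
}
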