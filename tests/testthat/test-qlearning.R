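test_that("update_q implements the asymmetric delta rule", {
  expect_equal(update_q(0.5, 1, agent_params(0, 0.5, 1)), 0.5)
  expect_equal(update_q(0.5, 1, agent_params(0.5, 0.1, 1)), 0.75)
  expect_equal(update_q(0.5, 0, agent_params(0.5, 0.2, 1)), 0.40)
  expect_error(update_q(1.5, 1, agent_params(0.5, 0.5, 1)), "\\[0, 1\\]")
  expect_error(update_q(0.5, 2, agent_params(0.5, 0.5, 1)), "binary")
  expect_error(agent_params(1.2, 0.5, 1), "alpha_gain")
  expect_error(agent_params(0.5, 0.5, 150), "beta")
})

test_that("boundedness: values stay in [0,1] under any admissible sequence", {
  set.seed(1)
  for (rep in 1:20) {
    params <- agent_params(runif(1), runif(1), runif(1, 0, 100))
    q <- runif(1)
    for (t in 1:100) {
      q <- update_q(q, rbinom(1, 1, 0.5), params)
      expect_true(q >= 0 && q <= 1)
    }
  }
})

test_that("softmax choice probabilities are symmetric, stable, normalised", {
  expect_equal(choice_prob(0.3, 0.3, 17), 0.5)
  expect_equal(choice_prob(0.9, 0.1, 0), 0.5)
  expect_equal(choice_prob(0.8, 0.2, 5), 1 / (1 + exp(-3)))
  # stable and sane at the upper temperature bound
  expect_equal(choice_prob(1, 0, 100), 1 / (1 + exp(-100)))
  set.seed(2)
  qa <- runif(200); qb <- runif(200); b <- runif(200, 0, 100)
  expect_equal(choice_prob(qa, qb, b) + choice_prob(qb, qa, b),
               rep(1, 200), tolerance = 1e-15)
  p <- choice_prob(qa, qb, b)
  expect_true(all(p >= 0 & p <= 1))
  # strictly interior whenever the exponent gap is representable
  mid <- abs(b * (qa - qb)) < 30
  expect_true(all(p[mid] > 0 & p[mid] < 1))
})

test_that("likelihood matches hand and brute-force computation", {
  one <- data.frame(pair = "AB", choice = "A", outcome = 1)
  expect_equal(qlearn_nll(one, agent_params(0.3, 0.3, 10)), log(2))
  many <- random_trials(40, seed = 3)
  expect_equal(qlearn_nll(many, agent_params(0.4, 0.2, 0)), 40 * log(2))
  # three-trial chain, hand-traced: A rewarded, A unrewarded, B rewarded
  tr3 <- data.frame(pair = c("AB", "AB", "AB"),
                    choice = c("A", "A", "B"), outcome = c(1, 0, 1))
  ag <- 0.5; al <- 0.2; b <- 3
  # t1: qA = qB = 0.5 -> p = 0.5; qA <- 0.75
  # t2: p(A) = e^(3*.75)/(e^(3*.75)+e^(3*.5)); qA <- 0.75 - 0.2*0.75 = 0.6
  # t3: p(B) = e^(3*.5)/(e^(3*.6)+e^(3*.5))
  hand <- -(log(0.5) +
            log(exp(b * 0.75) / (exp(b * 0.75) + exp(b * 0.5))) +
            log(exp(b * 0.5) / (exp(b * 0.6) + exp(b * 0.5))))
  expect_equal(qlearn_nll(tr3, agent_params(ag, al, b)), hand)
  # random sequences against the independent loop oracle
  for (seed in 1:5) {
    trials <- random_trials(50, seed = seed, with_rt = TRUE)
    params <- agent_params(0.37, 0.12, 6.5)
    expect_equal(qlearn_nll(trials, params),
                 oracle_nll(trials, 0.37, 0.12, 6.5), tolerance = 1e-10)
  }
  expect_error(qlearn_nll(data.frame(pair = "AB", choice = "A",
                                     outcome = NA), agent_params(1, 1, 1)),
               "outcomes")
})

test_that("RT-excluded trials drop from the likelihood but still update", {
  trials <- data.frame(pair = c("AB", "AB"), choice = c("A", "A"),
                       outcome = c(1, 1), rt = c(0.05, 1.0))
  params <- agent_params(0.5, 0.5, 4)
  # first trial excluded (rt below floor) but its reward moves qA to 0.75
  expected <- -log(exp(4 * 0.75) / (exp(4 * 0.75) + exp(4 * 0.5)))
  expect_equal(qlearn_nll(trials, params), expected)
})

test_that("trajectory matches the brute-force oracle and its invariants", {
  trials <- random_trials(50, seed = 11)
  params <- agent_params(0.45, 0.15, 9)
  traj <- compute_trajectory(trials, params)
  orc <- oracle_trajectory(trials, 0.45, 0.15)
  expect_equal(traj$q_chosen, orc$q_chosen, tolerance = 1e-12)
  expect_equal(traj$q_unchosen, orc$q_unchosen, tolerance = 1e-12)
  expect_equal(traj$rpe, orc$rpe, tolerance = 1e-12)
  expect_equal(attr(traj, "final_q"), attr(orc, "final_q"),
               tolerance = 1e-12)
  # initialisation at one half and rpe definition on the first trial
  expect_equal(traj$q_chosen[1], 0.5)
  expect_equal(traj$rpe[1], trials$outcome[1] - 0.5)
  expect_equal(traj$delta_value, traj$q_chosen - traj$q_unchosen)
  # full updating: chosen value equals the option's last outcome
  traj1 <- compute_trajectory(trials, agent_params(1, 1, 9))
  qbo <- attr(traj1, "q_by_option")
  for (t in 2:nrow(trials)) {
    hits <- which(trials$choice[seq_len(t - 1)] == trials$choice[t])
    if (length(hits))
      expect_equal(traj1$q_chosen[t], as.numeric(trials$outcome[max(hits)]))
  }
  # unchosen options never move
  moved <- apply(qbo, 2, function(col) which(diff(col) != 0) + 1L)
  for (opt in names(moved)) {
    if (length(moved[[opt]]))
      expect_true(all(trials$choice[moved[[opt]] - 1L] == opt))
  }
})

test_that("expected value converges to the option's reward probability", {
  # fixed alpha, option chosen and rewarded at p = 0.7 for 200 trials:
  # mean terminal value within 0.05 of p over 1000 sequences
  set.seed(21)
  n_seq <- 1000
  q <- rep(0.5, n_seq)
  alpha <- 0.3
  for (t in 1:200) {
    r <- rbinom(n_seq, 1, 0.7)
    q <- q + alpha * (r - q)
  }
  expect_lt(abs(mean(q) - 0.7), 0.05)
})

test_that("likelihood is minimised near the generating parameters", {
  cfg <- task_config(n_runs_learning = 6, trials_per_run = 60,
                     n_runs_transfer = 0)
  gen <- agent_params(0.4, 0.15, 12)
  sim <- simulate_agent(gen, cfg, seed = 31)
  learning <- sim$trials[sim$trials$phase == "learning", ]
  grid_ag <- c(0.05, 0.2, 0.4, 0.6, 0.9)
  nlls <- vapply(grid_ag, function(a)
    qlearn_nll(learning, agent_params(a, 0.15, 12)), 0.0)
  expect_equal(grid_ag[which.min(nlls)], 0.4)
  grid_b <- c(1, 5, 12, 30, 80)
  nllb <- vapply(grid_b, function(b)
    qlearn_nll(learning, agent_params(0.4, 0.15, b)), 0.0)
  expect_equal(grid_b[which.min(nllb)], 12)
})

test_that("transfer values are frozen lookups", {
  fq <- c(A = 0.9, B = 0.2, C = 0.7, D = 0.4, E = 0.6, F = 0.5)
  tt <- data.frame(pair = c("AC", "AC", "BF", "DE"),
                   choice = c("A", "C", "F", "D"))
  tv <- transfer_values(fq, tt)
  expect_equal(tv$q_chosen, c(0.9, 0.7, 0.5, 0.4))
  expect_equal(tv$q_unchosen, c(0.7, 0.9, 0.2, 0.6))
  # equal values: zero differences everywhere
  tv0 <- transfer_values(stats::setNames(rep(0.3, 6), LETTERS[1:6]), tt)
  expect_true(all(tv0$delta_value == 0))
  # repeats of the same pair/choice give identical values
  expect_equal(tv$q_chosen[1], 0.9)
  expect_error(transfer_values(fq[1:3], tt), "missing options")
})
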