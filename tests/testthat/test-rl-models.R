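test_that("value updates follow the chosen-option delta rules", {
  # RP: hand-computed single steps
  p <- rl_params(0.2, 0.4, 1, model = "RP")
  s <- init_state("RP")
  s1 <- update_state(s, "A", 1, p)
  expect_equal(unname(s1$v["A"]), 0.6)   # 0.5 + 0.2 * (1 - 0.5)
  expect_equal(unname(s1$v["B"]), 0.5)   # unchosen untouched
  s2 <- update_state(s, "A", 0, p)
  expect_equal(unname(s2$v["A"]), 0.3)   # 0.5 + 0.4 * (0 - 0.5)

  # zero learning rate freezes the value
  p0 <- rl_params(0, 0, 1, model = "RP")
  expect_equal(unname(update_state(s, "A", 1, p0)$v["A"]), 0.5)

  # EWA: n <- rho*n + 1; v <- (phi*n_prev*v + outcome)/n
  pe <- rl_params(0.5, 0.5, 1, phi = 0.9, rho = 0.8, model = "EWA")
  se <- update_state(init_state("EWA"), "A", 1, pe)
  expect_equal(se$n, 1.8)
  expect_equal(unname(se$v["A"]), (0.9 * 1 * 0.5 + 1) / 1.8)
  expect_equal(unname(se$v["B"]), 0.5)

  # RW refuses distinct learning rates
  expect_error(rl_params(0.2, 0.3, 1, model = "RW"), "single learning rate")
  expect_error(update_state(s, "A", 2, p), "outcome")
})

test_that("softmax choice probabilities are complementary, calibrated, and overflow-safe", {
  s <- init_state("RP")
  expect_equal(choice_probability(s, 5), 0.5)       # equal values
  s$v <- c(A = 0.9, B = 0.2)
  expect_equal(choice_probability(s, 0), 0.5)       # beta = 0: random
  s$v <- c(A = 1, B = 0.5)
  expect_equal(choice_probability(s, 2), 1 / (1 + exp(-1)), tolerance = 1e-9)

  # extreme drive stays finite
  s$v <- c(A = 700, B = 0)
  expect_equal(choice_probability(s, 1), 1)
  s$v <- c(A = 0, B = 700)
  expect_equal(choice_probability(s, 1), 0)

  # monotone in the value difference and, for vA > vB, in beta
  set.seed(5)
  for (i in 1:20) {
    dv <- sort(runif(2, -1, 1))
    b <- runif(1, 0, 10)
    p_lo <- choice_probability(list(v = c(A = dv[1], B = 0)), b)
    p_hi <- choice_probability(list(v = c(A = dv[2], B = 0)), b)
    expect_true(p_hi >= p_lo)
    p_b1 <- choice_probability(list(v = c(A = 0.5, B = 0)), b)
    p_b2 <- choice_probability(list(v = c(A = 0.5, B = 0)), b + 1)
    expect_true(p_b2 >= p_b1)
  }
})

test_that("likelihood matches hand calculations and the brute-force oracle", {
  p <- rl_params(0.5, 0.5, 1, model = "RP")
  one <- data.frame(choice = "A", outcome = 1)
  expect_equal(negative_log_likelihood(one, p), log(2), tolerance = 1e-12)

  # two-trial stepwise hand calculation: -log 0.5 - log(1/(1+e^-0.25))
  two <- data.frame(choice = c("A", "A"), outcome = c(1, 0))
  expect_equal(negative_log_likelihood(two, p),
               log(2) - log(1 / (1 + exp(-0.25))), tolerance = 1e-12)

  # beta = 0: every choice has probability one half
  pz <- rl_params(0.3, 0.7, 0, model = "RP")
  tr <- random_trials(17, seed = 2)
  expect_equal(negative_log_likelihood(tr, pz), 17 * log(2), tolerance = 1e-12)

  # brute-force trajectory oracle over 100 random 20-trial sequences
  set.seed(9)
  for (i in 1:100) {
    tr <- random_trials(20, seed = 1000 + i)
    ap <- runif(1); an <- runif(1); b <- runif(1, 0, 8)
    expect_equal(
      negative_log_likelihood(tr, rl_params(ap, an, b, model = "RP")),
      oracle_nll(tr$choice, tr$outcome, ap, an, b, "RP"),
      tolerance = 1e-12)
    phi <- runif(1); rho <- runif(1)
    expect_equal(
      negative_log_likelihood(tr, rl_params(0.5, 0.5, b, phi = phi,
                                            rho = rho, model = "EWA")),
      oracle_nll(tr$choice, tr$outcome, NA, NA, b, "EWA", phi, rho),
      tolerance = 1e-12)
  }

  # RW is RP with tied learning rates: identical likelihood on any sequence
  for (i in 1:10) {
    tr <- random_trials(20, seed = 2000 + i)
    a <- runif(1); b <- runif(1, 0, 8)
    expect_identical(
      negative_log_likelihood(tr, rl_params(a, a, b, model = "RW")),
      negative_log_likelihood(tr, rl_params(a, a, b, model = "RP")))
  }

  expect_error(negative_log_likelihood(two[0, ], p), "empty")
})

test_that("values stay in [0,1] and only the chosen option moves", {
  set.seed(31)
  for (i in 1:30) {
    p <- rl_params(runif(1), runif(1), 1, model = "RP")
    st <- init_state("RP")
    for (t in 1:50) {
      ch <- sample(c("A", "B"), 1)
      out <- sample(0:1, 1)
      st_new <- update_state(st, ch, out, p)
      other <- setdiff(c("A", "B"), ch)
      expect_identical(st_new$v[[other]], st$v[[other]])
      expect_true(all(st_new$v >= 0 & st_new$v <= 1))
      st <- st_new
    }
  }
})

test_that("simulated agents behave as their parameters dictate", {
  sched <- make_schedule(task_design(), seed = 5)

  # beta = 0: chance-level accuracy
  accs <- vapply(1:40, function(s) {
    sim <- simulate_choices(sched, rl_params(0.5, 0.5, 0), seed = s)
    choice_accuracy(sim[, c("trial", "choice")], sched)
  }, 0)
  expect_equal(mean(accs), 0.5, tolerance = 0.03)

  # a sharp, fast learner beats chance comfortably on the stable block
  st <- sched[sched$block == "stable", ]
  class(st) <- c("trial_schedule", "data.frame")
  accs <- vapply(1:200, function(s) {
    sim <- simulate_choices(st, rl_params(0.9, 0.9, 30), seed = s)
    choice_accuracy(sim[, c("trial", "choice")], st)
  }, 0)
  expect_gt(mean(accs), 0.65)

  # deterministic given the seed
  s1 <- simulate_choices(sched, rl_params(0.3, 0.3, 3), seed = 8)
  s2 <- simulate_choices(sched, rl_params(0.3, 0.3, 3), seed = 8)
  expect_identical(s1, s2)

  # degenerate limit: certain contingency, near-greedy agent converges to
  # the high shape
  cert <- make_schedule(task_design(stable_p_high = 1), seed = 2)
  cert_st <- cert[cert$block == "stable", ]
  class(cert_st) <- c("trial_schedule", "data.frame")
  sim <- simulate_choices(cert_st, rl_params(0.9, 0.9, 30), seed = 3)
  late <- sim[sim$trial >= 40, ]
  expect_true(mean(late$choice == late$high_shape) > 0.95)
})

test_that("choice accuracy counts optimal-shape choices, not rewards", {
  sched <- make_schedule(task_design(), seed = 1)
  all_high <- data.frame(trial = sched$trial, choice = sched$high_shape)
  expect_equal(choice_accuracy(all_high, sched), 1.0)

  alternating <- data.frame(trial = sched$trial[1:4],
                            choice = c("A", "B", "A", "B"))
  st4 <- sched[1:4, ]
  st4$high_shape <- c("A", "A", "A", "B")  # 3 of 4 correct
  expect_equal(choice_accuracy(alternating, st4), 0.75)

  expect_error(choice_accuracy(all_high[1:10, ], sched), "length")
})
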