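#' Reinforcement-learning model parameters
#'
#' Parameter container for the three trial-by-trial observation models:
#'
#' * `"RP"` (reward-punishment): separate learning rates for rewarded
#'   (`alpha_pos`) and unrewarded (`alpha_neg`) outcomes, plus a softmax
#'   inverse temperature `beta`. After positive feedback the chosen shape's
#'   expected value moves toward the outcome by `alpha_pos` times the
#'   prediction error; after negative feedback by `alpha_neg`.
#' * `"RW"` (Rescorla-Wagner delta): a single learning rate applied to both
#'   feedback types (`alpha_pos == alpha_neg`).
#' * `"EWA"` (experience-weighted attraction): adds a value decay `phi` and
#'   an experience decay `rho`; the chosen value is updated as a decaying
#'   experience-weighted average of past value and the new outcome.
#'
#' @param alpha_pos reward learning rate in \[0, 1\].
#' @param alpha_neg punishment learning rate in \[0, 1\]; for `"RW"` it must
#'   equal `alpha_pos` (it defaults to `alpha_pos`).
#' @param beta softmax inverse temperature, >= 0. Higher `beta` means more
#'   value-consistent (less random) choices.
#' @param phi,rho EWA value- and experience-decay parameters in \[0, 1\];
#'   ignored for RP/RW.
#' @param model one of `"RP"`, `"RW"`, `"EWA"`.
#' @return an `rl_params` object.
#' @export
rl_params <- function(alpha_pos, alpha_neg = alpha_pos, beta,
                      phi = NULL, rho = NULL,
                      model = c("RP", "RW", "EWA")) {
  model <- match.arg(model)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
      stop(sprintf("parameter '%s' must be in [0, 1]", nm), call. = FALSE)
    }
  }
  chk01(alpha_pos, "alpha_pos")
  chk01(alpha_neg, "alpha_neg")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0) {
    stop("parameter 'beta' must be >= 0", call. = FALSE)
  }
  if (model == "RW" && alpha_pos != alpha_neg) {
    stop("the RW model uses a single learning rate: alpha_pos must equal alpha_neg",
         call. = FALSE)
  }
  if (model == "EWA") {
    if (is.null(phi) || is.null(rho)) {
      stop("the EWA model requires 'phi' and 'rho'", call. = FALSE)
    }
    chk01(phi, "phi")
    chk01(rho, "rho")
  }
  structure(list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta,
                 phi = phi, rho = rho, model = model),
            class = "rl_params")
}

#' Initial value state of an RL model
#'
#' Expected values start at the midpoint of the binary outcome range,
#' `v_A = v_B = 0.5`, so the first-choice probability is 0.5 and the first
#' prediction error is symmetric for reward and punishment. The EWA model
#' additionally carries an experience weight starting at `n = 1`.
#'
#' @param model `"RP"`, `"RW"`, or `"EWA"`.
#' @param v0 initial expected value of both shapes (default 0.5).
#' @return a list with elements `v` (named numeric, shapes `A` and `B`) and,
#'   for EWA, `n`.
#' @export
init_state <- function(model = c("RP", "RW", "EWA"), v0 = 0.5) {
  model <- match.arg(model)
  st <- list(v = c(A = v0, B = v0))
  if (model == "EWA") st$n <- 1
  st
}

#' Advance the value state after one trial's feedback
#'
#' Only the chosen shape's value is updated; the unchosen value carries over
#' unchanged. For RP the learning rate is `alpha_pos` when the outcome is 1
#' (positive feedback) and `alpha_neg` when it is 0; RW uses its single
#' rate. EWA updates the experience weight `n <- rho * n + 1` and the chosen
#' value as `(phi * n_prev * v + outcome) / n`.
#'
#' @param state a value state from [init_state()] or a previous update.
#' @param choice `"A"` or `"B"`, the shape chosen on this trial.
#' @param outcome 0 or 1, the realized feedback.
#' @param params an [rl_params()] object.
#' @return the updated state.
#' @export
update_state <- function(state, choice, outcome, params) {
  stopifnot(inherits(params, "rl_params"))
  if (!choice %in% c("A", "B")) stop("choice must be 'A' or 'B'", call. = FALSE)
  if (!isTRUE(outcome %in% c(0, 1))) {
    stop("outcome must be 0 or 1", call. = FALSE)
  }
  v <- state$v
  if (params$model == "EWA") {
    n_prev <- state$n
    n_new <- params$rho * n_prev + 1
    v[choice] <- (params$phi * n_prev * v[choice] + outcome) / n_new
    state$n <- n_new
  } else {
    lr <- if (outcome == 1) params$alpha_pos else params$alpha_neg
    v[choice] <- v[choice] + lr * (outcome - v[choice])
  }
  state$v <- v
  state
}

#' Softmax probability of choosing shape A
#'
#' `P(A) = 1 / (1 + exp(-beta * (v_A - v_B)))`; `P(B) = 1 - P(A)`. Computed
#' in a shift-invariant, overflow-safe form (via `plogis`), valid for
#' arbitrarily large `|beta * (v_A - v_B)|`.
#'
#' @param state a value state.
#' @param beta inverse temperature, >= 0.
#' @return probability of choosing shape A.
#' @export
choice_probability <- function(state, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, beta >= 0)
  stats::plogis(beta * (state$v[["A"]] - state$v[["B"]]))
}

#' Negative log-likelihood of an observed choice sequence
#'
#' Sums `-log P(observed choice)` over trials, with the value state
#' initialized by [init_state()] and advanced by [update_state()] after each
#' trial's feedback.
#'
#' @param trials data.frame with columns `choice` (`"A"`/`"B"`) and
#'   `outcome` (0/1), ordered by trial, for a single subject and context.
#' @param params an [rl_params()] object.
#' @param v0 initial expected value passed to [init_state()].
#' @return scalar negative log-likelihood, >= 0.
#' @export
negative_log_likelihood <- function(trials, params, v0 = 0.5) {
  stopifnot(inherits(params, "rl_params"))
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("empty trial sequence", call. = FALSE)
  }
  if (anyNA(c(params$alpha_pos, params$alpha_neg, params$beta))) {
    stop("NaN parameters", call. = FALSE)
  }
  if (!all(trials$outcome %in% c(0, 1))) {
    stop("outcomes must be binary (0/1)", call. = FALSE)
  }
  state <- init_state(params$model, v0 = v0)
  nll <- 0
  for (i in seq_len(nrow(trials))) {
    p_a <- choice_probability(state, params$beta)
    p_obs <- if (trials$choice[i] == "A") p_a else 1 - p_a
    nll <- nll - log(p_obs)
    state <- update_state(state, trials$choice[i], trials$outcome[i], params)
  }
  unname(nll)
}

#' Simulate an agent's choices on a trial schedule
#'
#' Choices are sampled from the softmax choice probability; the outcome is 1
#' exactly when the chosen shape is the schedule's rewarded shape on that
#' trial. Deterministic given `seed`.
#'
#' @param schedule a `trial_schedule` from [make_schedule()].
#' @param params an [rl_params()] object.
#' @param seed integer seed for the choice draws.
#' @param v0 initial expected value.
#' @return a data.frame with the schedule columns plus `choice`, `outcome`,
#'   and the model's trial-wise choice probability `p_choose_A`.
#' @export
simulate_choices <- function(schedule, params, seed = 1L, v0 = 0.5) {
  stopifnot(inherits(params, "rl_params"))
  n <- nrow(schedule)
  u <- with_seed(seed, stats::runif(n))
  state <- init_state(params$model, v0 = v0)
  choice <- character(n)
  outcome <- integer(n)
  p_a_vec <- numeric(n)
  for (i in seq_len(n)) {
    p_a <- choice_probability(state, params$beta)
    p_a_vec[i] <- p_a
    choice[i] <- if (u[i] < p_a) "A" else "B"
    outcome[i] <- as.integer(choice[i] == schedule$rewarded_shape[i])
    state <- update_state(state, choice[i], outcome[i], params)
  }
  out <- as.data.frame(schedule)
  out$choice <- choice
  out$outcome <- outcome
  out$p_choose_A <- p_a_vec
  out
}

#' Choice accuracy: fraction of optimal-shape choices
#'
#' The optimal shape on a trial is the one currently carrying the high
#' reward probability (`high_shape`), not the realized rewarded shape.
#'
#' @param trials data.frame with columns `trial` and `choice`.
#' @param schedule matching `trial_schedule` (aligned by trial index).
#' @return fraction in \[0, 1\].
#' @export
choice_accuracy <- function(trials, schedule) {
  if (nrow(trials) != nrow(schedule)) {
    stop("trials and schedule have different lengths", call. = FALSE)
  }
  ord_t <- order(trials$trial)
  ord_s <- order(schedule$trial)
  if (!all(trials$trial[ord_t] == schedule$trial[ord_s])) {
    stop("trial indices of trials and schedule do not align", call. = FALSE)
  }
  mean(trials$choice[ord_t] == schedule$high_shape[ord_s])
}
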