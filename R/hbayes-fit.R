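#' Hyperprior specification for hierarchical fits
#'
#' Group-level location and scale hyperpriors on the unconstrained scale:
#' `mu ~ normal(mu_mean, mu_sd)` and `sigma ~ normal(0, sigma_sd)` truncated
#' at zero (a half-normal; a scale cannot be negative). The defaults are the
#' conventional weakly-informative choices `normal(0, 1)` for `mu` and
#' `normal(0, 0.2)` for `sigma`, one pair per model parameter.
#'
#' @param mu_mean,mu_sd location-hyperprior mean and sd.
#' @param sigma_sd scale-hyperprior sd (half-normal).
#' @return a `prior_spec` object.
#' @export
prior_spec <- function(mu_mean = 0, mu_sd = 1, sigma_sd = 0.2) {
  stopifnot(mu_sd > 0, sigma_sd > 0)
  structure(list(mu_mean = mu_mean, mu_sd = mu_sd, sigma_sd = sigma_sd),
            class = "prior_spec")
}

#' MCMC sampler configuration
#'
#' @param chains number of chains (>= 2, required for split-Rhat).
#' @param warmup adaptation + burn-in iterations per chain.
#' @param draws retained sampling iterations per chain.
#' @param seed integer seed; chain RNGs are derived deterministically from
#'   it, so a fit is bit-identical given the same seed.
#' @param beta_max upper bound of the inverse-temperature transform: the
#'   unconstrained subject deviate is mapped through the standard-normal CDF
#'   and scaled to `[0, beta_max]` (learning rates and decays map through
#'   the CDF alone to `[0, 1]`).
#' @return a `fit_config` object.
#' @export
fit_config <- function(chains = 4L, warmup = 1000L, draws = 1000L,
                       seed = 1L, beta_max = 10) {
  if (chains < 2L) stop_config("chains", "must be >= 2 (needed for split-Rhat)")
  if (warmup < 2L) stop_config("warmup", "must be >= 2")
  if (draws < 4L) stop_config("draws", "must be >= 4")
  if (beta_max <= 0) stop_config("beta_max", "must be > 0")
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 beta_max = beta_max),
            class = "fit_config")
}

# Native parameter names per model.
model_param_names <- function(model) {
  switch(model,
         RP = c("alpha_pos", "alpha_neg", "beta"),
         RW = c("alpha", "beta"),
         EWA = c("phi", "rho", "beta"),
         stop("unknown model tag: ", model, call. = FALSE))
}

# JAGS model code for one (group x context) cell. Non-centered subject
# deviates; learning rates and decays mapped to [0,1] via the
# standard-normal CDF, beta to [0, beta_max]. `loglik[s]` is the summed
# per-subject pointwise log-likelihood used for LOO.
jags_model_code <- function(model) {
  npar <- length(model_param_names(model))
  header <- sprintf("
model {
  for (p in 1:%d) {
    mu[p] ~ dnorm(mu_mean, pow(mu_sd, -2))
    sigma[p] ~ dnorm(0, pow(sigma_sd, -2)) T(0,)
  }
  for (s in 1:S) {
    for (p in 1:%d) { z[s,p] ~ dnorm(0, 1) }
", npar, npar)
  body <- switch(model,
    RP = "
    alpha_pos[s] <- phi(mu[1] + sigma[1] * z[s,1])
    alpha_neg[s] <- phi(mu[2] + sigma[2] * z[s,2])
    beta[s]      <- phi(mu[3] + sigma[3] * z[s,3]) * beta_max
    v[s,1,1] <- 0.5
    v[s,1,2] <- 0.5
    for (t in 1:Tn[s]) {
      pA[s,t] <- ilogit(beta[s] * (v[s,t,1] - v[s,t,2]))
      choice[s,t] ~ dbern(pA[s,t])
      lr[s,t] <- outcome[s,t] * alpha_pos[s] + (1 - outcome[s,t]) * alpha_neg[s]
      v[s,t+1,1] <- v[s,t,1] + choice[s,t] * lr[s,t] * (outcome[s,t] - v[s,t,1])
      v[s,t+1,2] <- v[s,t,2] + (1 - choice[s,t]) * lr[s,t] * (outcome[s,t] - v[s,t,2])
      ll[s,t] <- choice[s,t] * log(pA[s,t]) + (1 - choice[s,t]) * log(1 - pA[s,t])
    }
",
    RW = "
    alpha[s] <- phi(mu[1] + sigma[1] * z[s,1])
    beta[s]  <- phi(mu[2] + sigma[2] * z[s,2]) * beta_max
    v[s,1,1] <- 0.5
    v[s,1,2] <- 0.5
    for (t in 1:Tn[s]) {
      pA[s,t] <- ilogit(beta[s] * (v[s,t,1] - v[s,t,2]))
      choice[s,t] ~ dbern(pA[s,t])
      v[s,t+1,1] <- v[s,t,1] + choice[s,t] * alpha[s] * (outcome[s,t] - v[s,t,1])
      v[s,t+1,2] <- v[s,t,2] + (1 - choice[s,t]) * alpha[s] * (outcome[s,t] - v[s,t,2])
      ll[s,t] <- choice[s,t] * log(pA[s,t]) + (1 - choice[s,t]) * log(1 - pA[s,t])
    }
",
    EWA = "
    phi_v[s] <- phi(mu[1] + sigma[1] * z[s,1])
    rho_n[s] <- phi(mu[2] + sigma[2] * z[s,2])
    beta[s]  <- phi(mu[3] + sigma[3] * z[s,3]) * beta_max
    v[s,1,1] <- 0.5
    v[s,1,2] <- 0.5
    nw[s,1] <- 1
    for (t in 1:Tn[s]) {
      pA[s,t] <- ilogit(beta[s] * (v[s,t,1] - v[s,t,2]))
      choice[s,t] ~ dbern(pA[s,t])
      nw[s,t+1] <- rho_n[s] * nw[s,t] + 1
      v[s,t+1,1] <- choice[s,t] *
          ((phi_v[s] * nw[s,t] * v[s,t,1] + outcome[s,t]) / nw[s,t+1]) +
          (1 - choice[s,t]) * v[s,t,1]
      v[s,t+1,2] <- (1 - choice[s,t]) *
          ((phi_v[s] * nw[s,t] * v[s,t,2] + outcome[s,t]) / nw[s,t+1]) +
          choice[s,t] * v[s,t,2]
      ll[s,t] <- choice[s,t] * log(pA[s,t]) + (1 - choice[s,t]) * log(1 - pA[s,t])
    }
")
  footer <- "
    loglik[s] <- sum(ll[s, 1:Tn[s]])
  }
}
"
  paste0(header, body, footer)
}

# JAGS monitor names for the subject-level native parameters.
jags_native_monitors <- function(model) {
  switch(model,
         RP = c("alpha_pos", "alpha_neg", "beta"),
         RW = c("alpha", "beta"),
         EWA = c("phi_v", "rho_n", "beta"))
}

#' Fit a hierarchical RL model to one group-by-context cell by MCMC
#'
#' Fits the chosen observation model to all subjects of a single treatment
#' group in a single learning context, with partial pooling: each model
#' parameter has a group-level location `mu` and scale `sigma` on the
#' unconstrained scale, and non-centered subject deviates mapped to the
#' native range (learning rates/decays to \[0,1\] via the standard-normal
#' CDF; `beta` to `[0, beta_max]`). Sampling uses JAGS. Non-convergence does
#' not raise: split-Rhat is reported per parameter and left to the caller.
#'
#' @param data data.frame of trials for one cell with columns `subject`,
#'   `choice` (`"A"`/`"B"`), `outcome` (0/1), and optionally `trial`,
#'   `group`, `context`; at least 2 subjects with at least 1 trial each.
#' @param model `"RP"`, `"RW"`, or `"EWA"`.
#' @param priors a [prior_spec()].
#' @param config a [fit_config()].
#' @return a `posterior_fit`: posterior draws (iterations x chains x
#'   parameters), split-Rhat per monitored parameter, a per-subject
#'   pointwise log-likelihood matrix for LOO, subject ids, the fitted cell
#'   label, model tag, and a hash of the input data.
#' @export
fit_hierarchical <- function(data, model = c("RP", "RW", "EWA"),
                             priors = prior_spec(), config = fit_config()) {
  model <- match.arg(model)
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "fit_config"))
  need <- c("subject", "choice", "outcome")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("data missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(data$outcome %in% c(0, 1))) {
    stop("outcomes must be binary (0/1)", call. = FALSE)
  }
  if (!all(data$choice %in% c("A", "B"))) {
    stop("choices must be 'A' or 'B'", call. = FALSE)
  }
  if (!is.null(data$trial)) {
    data <- data[order(data$subject, data$trial), , drop = FALSE]
  }
  subjects <- unique(data$subject)
  S <- length(subjects)
  if (S < 2L) {
    stop("hierarchical fit requires >= 2 subjects (got ", S, ")",
         call. = FALSE)
  }
  cell <- list(
    group = if (!is.null(data$group)) unique(as.character(data$group)) else NA_character_,
    context = if (!is.null(data$context)) unique(as.character(data$context)) else NA_character_)
  if (length(cell$group) != 1L || length(cell$context) != 1L) {
    stop("data must come from a single group x context cell", call. = FALSE)
  }

  Tn <- vapply(subjects, function(s) sum(data$subject == s), 0L)
  Tmax <- max(Tn)
  choice_m <- outcome_m <- matrix(NA_real_, S, Tmax)
  for (i in seq_len(S)) {
    rows <- data$subject == subjects[i]
    choice_m[i, seq_len(Tn[i])] <- as.integer(data$choice[rows] == "A")
    outcome_m[i, seq_len(Tn[i])] <- as.numeric(data$outcome[rows])
  }

  npar <- length(model_param_names(model))
  jdata <- list(S = S, Tn = as.integer(Tn), choice = choice_m,
                outcome = outcome_m, beta_max = config$beta_max,
                mu_mean = priors$mu_mean, mu_sd = priors$mu_sd,
                sigma_sd = priors$sigma_sd)
  inits <- lapply(seq_len(config$chains), function(i) {
    list(mu = rep(0, npar), sigma = rep(0.1, npar),
         z = matrix(0, S, npar),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(config$seed, paste0("chain", i)))
  })
  n_adapt <- max(100L, config$warmup %/% 2L)
  n_burn <- config$warmup - n_adapt
  jm <- rjags::jags.model(textConnection(jags_model_code(model)),
                          data = jdata, inits = inits,
                          n.chains = config$chains, n.adapt = n_adapt,
                          quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  monitors <- c("mu", "sigma", jags_native_monitors(model), "loglik")
  samp <- rjags::coda.samples(jm, monitors, n.iter = config$draws,
                              progress.bar = "none")

  par_names <- coda::varnames(samp)
  draws <- array(NA_real_,
                 dim = c(config$draws, config$chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(config$chains)) draws[, ch, ] <- as.matrix(samp[[ch]])

  keep <- !grepl("^loglik\\[", par_names)
  rhat <- vapply(par_names[keep],
                 function(p) split_rhat(draws[, , p]), 0)
  ll_names <- sprintf("loglik[%d]", seq_len(S))
  loglik <- apply(draws[, , ll_names, drop = FALSE], 3, as.vector)
  colnames(loglik) <- as.character(subjects)

  structure(list(model = model, cell = cell, subjects = subjects,
                 draws = draws[, , keep, drop = FALSE],
                 rhat = rhat, loglik = loglik,
                 priors = priors, config = config,
                 data_hash = hash_object(data[, need])),
            class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s fit: cell %s/%s, %d subjects\n",
              x$model, x$cell$group, x$cell$context, length(x$subjects)))
  cat(sprintf("  %d chains x %d draws; max split-Rhat (group-level) = %.4f\n",
              x$config$chains, x$config$draws, max(group_level_rhat(x))))
  invisible(x)
}

#' Split-Rhat of the group-level hyperparameters of a fit
#' @param fit a `posterior_fit`.
#' @return named vector of split-Rhat values for the `mu` and `sigma`
#'   hyperparameters.
#' @export
group_level_rhat <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  fit$rhat[grepl("^(mu|sigma)\\[", names(fit$rhat))]
}

#' Posterior summary of group-level parameters
#'
#' Reports the unconstrained hyperparameters and, for each model parameter,
#' the native-scale group mean obtained by pushing the `mu` draws through
#' the parameter's transform (CDF to \[0,1\]; CDF times `beta_max` for
#' `beta`).
#'
#' @param fit a `posterior_fit`.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`, `rhat`.
#' @export
posterior_summary <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  pars <- model_param_names(fit$model)
  rows <- list()
  flat <- function(p) as.vector(fit$draws[, , p])
  for (i in seq_along(pars)) {
    for (kind in c("mu", "sigma")) {
      nm <- sprintf("%s[%d]", kind, i)
      x <- flat(nm)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = sprintf("%s_%s", kind, pars[i]),
        mean = mean(x), sd = stats::sd(x),
        q2.5 = unname(stats::quantile(x, 0.025)),
        q97.5 = unname(stats::quantile(x, 0.975)),
        rhat = unname(fit$rhat[nm]))
    }
    scale <- if (pars[i] == "beta") fit$config$beta_max else 1
    x <- stats::pnorm(flat(sprintf("mu[%d]", i))) * scale
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = sprintf("mu_native_%s", pars[i]),
      mean = mean(x), sd = stats::sd(x),
      q2.5 = unname(stats::quantile(x, 0.025)),
      q97.5 = unname(stats::quantile(x, 0.975)),
      rhat = unname(fit$rhat[sprintf("mu[%d]", i)]))
  }
  do.call(rbind, rows)
}

#' Posterior means of subject-level native parameters
#'
#' @param fit a `posterior_fit`.
#' @return data.frame with one row per subject and one column per native
#'   model parameter (plus `subject`).
#' @export
subject_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "posterior_fit"))
  mons <- jags_native_monitors(fit$model)
  pars <- model_param_names(fit$model)
  S <- length(fit$subjects)
  out <- data.frame(subject = fit$subjects)
  for (j in seq_along(mons)) {
    out[[pars[j]]] <- vapply(seq_len(S), function(s) {
      mean(fit$draws[, , sprintf("%s[%d]", mons[j], s)])
    }, 0)
  }
  out
}

#' Classic split-Rhat convergence diagnostic
#'
#' Each chain is split in half; the potential scale reduction factor is
#' `sqrt(((n-1)/n * W + B/n) / W)` where `W` is the mean within-half-chain
#' variance and `B` the between-half-chain variance of the half means.
#' Values near 1 indicate mixing; values above 1.1 conventionally indicate
#' non-convergence.
#'
#' @param draws iterations x chains matrix of posterior draws for one
#'   parameter.
#' @return scalar split-Rhat; `NA_real_` (a flagged sentinel, not an error)
#'   when the draws are constant and the diagnostic is undefined.
#' @export
split_rhat <- function(draws) {
  if (is.null(dim(draws))) draws <- matrix(draws, ncol = 1L)
  if (ncol(draws) < 2L) {
    stop("split-Rhat requires >= 2 chains", call. = FALSE)
  }
  niter <- nrow(draws)
  if (niter < 4L) stop("split-Rhat requires >= 4 draws per chain", call. = FALSE)
  n <- niter %/% 2L
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(ch) {
    cbind(draws[seq_len(n), ch], draws[seq.int(niter - n + 1L, niter), ch])
  }))
  w <- mean(apply(halves, 2, stats::var))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * w + b / n) / w)
}
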