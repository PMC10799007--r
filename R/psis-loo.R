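# PSIS-LOO model comparison: Pareto-smoothed importance-sampling estimate of
# leave-one-out predictive accuracy, with the generalized-Pareto tail fit of
# Zhang & Stephens (2009) and the smoothing scheme of Vehtari, Gelman &
# Gabry (2017).

# Profile-likelihood GPD fit to exceedances x (sorted ascending, > 0).
# Returns shape k and scale sigma in the (k, sigma) parameterization with
# quantile function sigma/k * ((1-p)^(-k) - 1).
gpd_fit <- function(x) {
  n <- length(x)
  if (n < 5L || !all(is.finite(x)) || max(x) <= 0) {
    return(list(k = NA_real_, sigma = NA_real_))
  }
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) return(list(k = NA_real_, sigma = NA_real_))
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  prof <- vapply(b, function(bb) {
    k <- mean(log1p(-bb * x))
    n * (log(-bb / k) - k - 1)
  }, 0)
  w <- 1 / vapply(jj, function(j) sum(exp(prof - prof[j])), 0)
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))
  sigma_hat <- -k_hat / b_hat
  # weakly-informative shape prior, stabilizes small tails
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)
  list(k = k_hat, sigma = sigma_hat)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance ratios; returns the smoothed,
# max-shifted log weights and the fitted tail shape k.
psis_smooth <- function(lw) {
  s <- length(lw)
  lw <- lw - max(lw)
  m <- ceiling(min(0.2 * s, 3 * sqrt(s)))
  if (m < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  tail_ids <- ord[seq.int(s - m + 1L, s)]
  cut_lw <- lw[ord[s - m]]
  exc <- sort(exp(lw[tail_ids]) - exp(cut_lw))
  fit <- gpd_fit(exc)
  if (is.finite(fit$k)) {
    p <- (seq_len(m) - 0.5) / m
    smoothed <- vapply(p, gpd_quantile, 0, k = fit$k, sigma = fit$sigma) +
      exp(cut_lw)
    lw[tail_ids[order(lw[tail_ids])]] <- log(smoothed)
    lw <- pmin(lw, 0)  # cap at the largest raw weight
  }
  list(lw = lw, k = fit$k)
}

#' PSIS-LOO estimate of out-of-sample predictive accuracy
#'
#' Computes the Pareto-smoothed importance-sampling leave-one-out expected
#' log predictive density (elpd) from a pointwise log-likelihood matrix, and
#' the LOO information criterion `LOOIC = -2 * elpd_loo` on the deviance
#' scale (lower LOOIC indicates better expected fit). The per-point Pareto
#' tail-shape diagnostics `k` are returned; points with `k > 0.7` have
#' unreliable importance-sampling estimates, and a warning is attached when
#' more than half the points exceed that threshold.
#'
#' @param loglik matrix of pointwise log-likelihood values, posterior draws
#'   in rows and leave-one-out units (here: subjects, each entry the sum of
#'   that subject's trial log-likelihoods) in columns. At least 100 draws.
#' @return a `psis_loo` object: list with `elpd_loo`, `looic`, `pareto_k`,
#'   `pointwise` (per-unit elpd), and `n_draws`.
#' @export
psis_loo <- function(loglik) {
  loglik <- as.matrix(loglik)
  if (!all(is.finite(loglik))) {
    stop("pointwise log-likelihood matrix must be finite", call. = FALSE)
  }
  if (nrow(loglik) < 100L) {
    stop("psis_loo requires >= 100 posterior draws (got ", nrow(loglik), ")",
         call. = FALSE)
  }
  n <- ncol(loglik)
  pointwise <- numeric(n)
  k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw - logsumexp(sm$lw)
    pointwise[i] <- logsumexp(lw + ll)
    k[i] <- sm$k
  }
  out <- structure(list(elpd_loo = sum(pointwise),
                        looic = -2 * sum(pointwise),
                        pareto_k = k, pointwise = pointwise,
                        n_draws = nrow(loglik)),
                   class = "psis_loo")
  bad <- mean(k > 0.7, na.rm = TRUE)
  if (is.finite(bad) && bad > 0.5) {
    out$warning <- sprintf(
      "%.0f%% of Pareto k diagnostics exceed 0.7; PSIS-LOO estimates unreliable",
      100 * bad)
    warning(out$warning, call. = FALSE)
  }
  out
}

#' @export
print.psis_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO over %d units (%d draws)\n",
              length(x$pointwise), x$n_draws))
  cat(sprintf("  elpd_loo = %.1f, LOOIC = %.1f, max Pareto k = %.2f\n",
              x$elpd_loo, x$looic, max(x$pareto_k, na.rm = TRUE)))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' LOOIC comparison table across models and cells
#'
#' Builds the model-by-cell LOOIC table from a list of fitted
#' `posterior_fit` objects (one fit per model per group-by-context cell)
#' and flags the winning (lowest-LOOIC) model within each cell. All fits
#' within a cell must have been computed on identical data; mismatched data
#' hashes raise an error.
#'
#' @param fits list of `posterior_fit` objects.
#' @return data.frame with columns `model`, `cell`, `looic`, `elpd_loo`,
#'   `winner` (logical; `NA` when a cell holds a single model), and `tie`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, "posterior_fit")))
  tab <- do.call(rbind, lapply(fits, function(f) {
    loo <- suppressWarnings(psis_loo(f$loglik))
    data.frame(model = f$model,
               cell = paste(f$cell$context, f$cell$group, sep = "_"),
               looic = loo$looic, elpd_loo = loo$elpd_loo,
               data_hash = f$data_hash,
               stringsAsFactors = FALSE)
  }))
  tab$winner <- NA
  tab$tie <- FALSE
  for (cl in unique(tab$cell)) {
    rows <- which(tab$cell == cl)
    if (length(unique(tab$data_hash[rows])) != 1L) {
      stop("fits for cell '", cl, "' were computed on different data",
           call. = FALSE)
    }
    if (length(rows) < 2L) next
    best <- min(tab$looic[rows])
    is_best <- abs(tab$looic[rows] - best) < 1e-8
    tab$winner[rows] <- is_best
    if (sum(is_best) > 1L) tab$tie[rows[is_best]] <- TRUE
  }
  tab$data_hash <- NULL
  tab
}

#' Posterior predictive check: trial-wise optimal-choice probability
#'
#' For a subsample of posterior draws, simulates every subject's choices on
#' the given schedule with that draw's subject-level native parameters, and
#' averages the optimal-choice (high-probability shape chosen) indicator
#' over draws and subjects per trial. A well-fitting model reproduces the
#' empirical learning curve, including accuracy dips after reversals in the
#' volatile context.
#'
#' @param fit a `posterior_fit`.
#' @param schedule a `trial_schedule` the subjects are simulated on.
#' @param n_draws number of posterior draws to simulate (subsampled evenly).
#' @param seed integer seed for the simulated choice draws.
#' @return numeric vector, one mean optimal-choice probability per trial.
#' @export
posterior_predictive_accuracy <- function(fit, schedule, n_draws = 100L,
                                          seed = 1L) {
  stopifnot(inherits(fit, "posterior_fit"))
  mons <- jags_native_monitors(fit$model)
  pars <- model_param_names(fit$model)
  total <- dim(fit$draws)[1] * dim(fit$draws)[2]
  n_draws <- min(n_draws, total)
  idx <- unique(round(seq(1L, total, length.out = n_draws)))
  S <- length(fit$subjects)
  acc <- matrix(0, nrow(schedule), length(idx) * S)
  col <- 0L
  for (d in seq_along(idx)) {
    for (s in seq_len(S)) {
      val <- vapply(mons, function(m) {
        as.vector(fit$draws[, , sprintf("%s[%d]", m, s)])[idx[d]]
      }, 0)
      names(val) <- pars
      prm <- switch(fit$model,
        RP = rl_params(val[["alpha_pos"]], val[["alpha_neg"]], val[["beta"]],
                       model = "RP"),
        RW = rl_params(val[["alpha"]], val[["alpha"]], val[["beta"]],
                       model = "RW"),
        EWA = rl_params(0.5, 0.5, val[["beta"]], phi = val[["phi"]],
                        rho = val[["rho"]], model = "EWA"))
      sim <- simulate_choices(schedule, prm,
                              seed = derive_seed(seed, sprintf("ppc-%d-%d", d, s)))
      col <- col + 1L
      acc[, col] <- as.numeric(sim$choice == schedule$high_shape)
    }
  }
  rowMeans(acc[, seq_len(col), drop = FALSE])
}

#' Unnormalized hierarchical log posterior density
#'
#' Validation utility composing the model's joint density from its parts:
#' hyperpriors on `(mu, sigma)`, standard-normal subject deviates `z`, and
#' the per-subject choice likelihood from [negative_log_likelihood()]. The
#' subject-level native parameters are
#' `transform(mu + sigma * z)` with the CDF transforms used by
#' [fit_hierarchical()].
#'
#' @param mu,sigma numeric vectors, one entry per model parameter.
#' @param z matrix of subject deviates (subjects x parameters).
#' @param data cell trial data as in [fit_hierarchical()].
#' @param model `"RP"`, `"RW"`, or `"EWA"`.
#' @param priors a [prior_spec()].
#' @param beta_max inverse-temperature transform bound.
#' @return scalar log density (up to the half-normal normalizing constant).
#' @export
hierarchical_log_density <- function(mu, sigma, z, data,
                                     model = c("RP", "RW", "EWA"),
                                     priors = prior_spec(), beta_max = 10) {
  model <- match.arg(model)
  pars <- model_param_names(model)
  stopifnot(length(mu) == length(pars), length(sigma) == length(pars),
            ncol(z) == length(pars), all(sigma > 0))
  lp <- sum(stats::dnorm(mu, priors$mu_mean, priors$mu_sd, log = TRUE)) +
    sum(stats::dnorm(sigma, 0, priors$sigma_sd, log = TRUE)) +
    sum(stats::dnorm(z, 0, 1, log = TRUE))
  subjects <- unique(data$subject)
  for (i in seq_along(subjects)) {
    theta <- stats::pnorm(mu + sigma * z[i, ])
    names(theta) <- pars
    prm <- switch(model,
      RP = rl_params(theta[["alpha_pos"]], theta[["alpha_neg"]],
                     theta[["beta"]] * beta_max, model = "RP"),
      RW = rl_params(theta[["alpha"]], theta[["alpha"]],
                     theta[["beta"]] * beta_max, model = "RW"),
      EWA = rl_params(0.5, 0.5, theta[["beta"]] * beta_max,
                      phi = theta[["phi"]], rho = theta[["rho"]],
                      model = "EWA"))
    rows <- data[data$subject == subjects[i], , drop = FALSE]
    lp <- lp - negative_log_likelihood(rows, prm)
  }
  lp
}
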