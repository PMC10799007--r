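# Independent straight-line oracles used to cross-check the package
# implementations. These deliberately share no code with the package.

# Trajectory-enumerating negative log-likelihood for all three observation
# models, written as one flat loop.
oracle_nll <- function(choice, outcome, alpha_pos, alpha_neg, beta,
                       model = "RP", phi = NA, rho = NA) {
  vA <- 0.5; vB <- 0.5; nw <- 1; nll <- 0
  for (t in seq_along(choice)) {
    pA <- 1 / (1 + exp(-beta * (vA - vB)))
    pr <- if (choice[t] == "A") pA else 1 - pA
    nll <- nll - log(pr)
    if (model == "EWA") {
      nn <- rho * nw + 1
      if (choice[t] == "A") {
        vA <- (phi * nw * vA + outcome[t]) / nn
      } else {
        vB <- (phi * nw * vB + outcome[t]) / nn
      }
      nw <- nn
    } else {
      lr <- if (outcome[t] == 1) alpha_pos else alpha_neg
      if (choice[t] == "A") {
        vA <- vA + lr * (outcome[t] - vA)
      } else {
        vB <- vB + lr * (outcome[t] - vB)
      }
    }
  }
  nll
}

# Textbook split-half potential scale reduction factor.
oracle_split_rhat <- function(mat) {
  n2 <- floor(nrow(mat) / 2)
  cols <- list()
  for (ch in seq_len(ncol(mat))) {
    cols <- c(cols, list(mat[seq_len(n2), ch]),
              list(mat[seq.int(nrow(mat) - n2 + 1, nrow(mat)), ch]))
  }
  m <- length(cols)
  means <- vapply(cols, mean, 0)
  W <- mean(vapply(cols, stats::var, 0))
  B <- n2 / (m - 1) * sum((means - mean(means))^2)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# Cell-means sums-of-squares decomposition for the 2 (between) x 2 (within)
# mixed design, allowing unequal group sizes.
oracle_mixed_anova <- function(tab) {
  tab$subject <- as.character(tab$subject)
  tab$group <- as.character(tab$group)
  tab$context <- as.character(tab$context)
  subs <- unique(tab$subject)
  grand <- mean(tab$value)
  subj_mean <- tapply(tab$value, tab$subject, mean)
  grp_of <- tapply(tab$group, tab$subject, `[`, 1)
  grp_mean <- tapply(tab$value, tab$group, mean)
  ctx_mean <- tapply(tab$value, tab$context, mean)
  cell_mean <- tapply(tab$value, list(tab$group, tab$context), mean)
  n_g <- table(grp_of)
  N <- length(subs)
  ss_between_subj <- 2 * sum((subj_mean - grand)^2)
  ss_group <- sum(2 * n_g[names(grp_mean)] * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_ctx <- sum(N * (ctx_mean - grand)^2)
  ss_int <- 0
  for (g in names(grp_mean)) {
    for (cx in names(ctx_mean)) {
      ss_int <- ss_int + n_g[[g]] *
        (cell_mean[g, cx] - grp_mean[[g]] - ctx_mean[[cx]] + grand)^2
    }
  }
  ss_total <- sum((tab$value - grand)^2)
  ss_resid <- ss_total - ss_between_subj - ss_ctx - ss_int
  f_and_p <- function(ss_e, df_e, ss_r, df_r) {
    f <- (ss_e / df_e) / (ss_r / df_r)
    c(F = f, p = stats::pf(f, df_e, df_r, lower.tail = FALSE),
      pes = ss_e / (ss_e + ss_r))
  }
  list(treatment = f_and_p(ss_group, 1, ss_subj_within, N - 2),
       context = f_and_p(ss_ctx, 1, ss_resid, N - 2),
       interaction = f_and_p(ss_int, 1, ss_resid, N - 2))
}

# Pooled-variance and Welch t statistics from the textbook formulas.
oracle_t <- function(x, y, variant = "student") {
  n1 <- length(x); n2 <- length(y)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- var(x) / n1 + var(y) / n2
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / n1)^2 / (n1 - 1) + (var(y) / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Random RP trial sequence for likelihood cross-checks.
random_trials <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(choice = sample(c("A", "B"), n, replace = TRUE),
             outcome = sample(0:1, n, replace = TRUE))
}

# Minimal epoch_set fixture: deterministic signal builder.
make_epochs <- function(n_epochs, channels = c("FCz", "Pz", "PO7", "PO8"),
                        sfreq = 250, tmin = -200, tmax = 800,
                        labels = NULL, fill = 0) {
  nsamp <- round((tmax - tmin) / 1000 * sfreq) + 1L
  dat <- array(fill, dim = c(n_epochs, length(channels), nsamp))
  epoch_set(dat, sfreq = sfreq, tmin_ms = tmin, channels = channels,
            labels = labels, lock = "stimulus")
}

gauss_bump <- function(times, center, width, amplitude) {
  amplitude * exp(-0.5 * ((times - center) / width)^2)
}
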