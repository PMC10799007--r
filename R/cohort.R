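#' Generative configuration of a synthetic two-group study cohort
#'
#' Defines the group-level generative model for a synthetic cohort: group
#' sizes, per-cell (group x context) means and spreads of the native-scale
#' RL parameters, the trait-anxiety/choice-consistency correlation, and ERP
#' component effect sizes. Subject parameters are drawn from truncated
#' normals bounded to their native ranges.
#'
#' @param n_ot,n_plc group sizes (default 37 and 36).
#' @param param_means 3 x 2 x 2 array (parameter x group x context) of
#'   native-scale cell means; dimnames
#'   `(alpha_pos, alpha_neg, beta) x (OT, PLC) x (stable, volatile)`.
#' @param param_sds matching array of within-cell SDs (> 0, or 0 for the
#'   degenerate no-dispersion limit).
#' @param anxiety_beta_cor correlation in (-1, 1) between the unit-scaled
#'   trait-anxiety score and the latent choice-consistency deviate shared
#'   across contexts (default -0.27: more anxious subjects choose less
#'   consistently).
#' @param beta_max truncation bound of the inverse temperature.
#' @param erp list of ERP injection settings: `means` and `sds`
#'   (component x group matrices, microvolts), `noise_sd` (white-noise SD
#'   per sample, microvolts), `artifact_rate` (fraction of epochs given a
#'   +/-100 microvolt excursion).
#' @return a `cohort_spec` object.
#' @seealso [default_effect_config()], [draw_cohort()]
#' @export
cohort_spec <- function(n_ot = 37L, n_plc = 36L,
                        param_means, param_sds = NULL,
                        anxiety_beta_cor = -0.27,
                        beta_max = 10,
                        erp = NULL) {
  if (n_ot < 2L || n_plc < 2L) stop_config("n_ot/n_plc", "must be >= 2")
  if (abs(anxiety_beta_cor) >= 1) {
    stop_config("anxiety_beta_cor", "must lie in (-1, 1)")
  }
  dn <- list(c("alpha_pos", "alpha_neg", "beta"), c("OT", "PLC"),
             c("stable", "volatile"))
  stopifnot(is.array(param_means), all(dim(param_means) == c(3, 2, 2)))
  dimnames(param_means) <- dn
  if (is.null(param_sds)) {
    param_sds <- array(rep(c(0.10, 0.10, 1.0), 4), dim = c(3, 2, 2))
  }
  stopifnot(all(dim(param_sds) == c(3, 2, 2)))
  dimnames(param_sds) <- dn
  if (any(param_sds < 0)) stop_config("param_sds", "must be >= 0")
  if (is.null(erp)) {
    comp <- c("ERN", "FRN", "P300", "N2pc")
    erp <- list(
      means = matrix(c(-4.0, -4.0, -3.0, -3.0, 3.75, 5.57, -0.29, 0.18),
                     nrow = 4, byrow = TRUE,
                     dimnames = list(comp, c("OT", "PLC"))),
      sds = matrix(c(1.5, 1.5, 1.5, 1.5, 2.59, 3.31, 0.59, 0.70),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(comp, c("OT", "PLC"))),
      noise_sd = 1, artifact_rate = 0)
  }
  if (erp$noise_sd < 0) stop_config("erp$noise_sd", "must be >= 0")
  structure(list(n_ot = as.integer(n_ot), n_plc = as.integer(n_plc),
                 param_means = param_means, param_sds = param_sds,
                 anxiety_beta_cor = anxiety_beta_cor,
                 beta_max = beta_max, erp = erp),
            class = "cohort_spec")
}

#' Default effect configuration of the synthetic cohort
#'
#' Cell means chosen to embody the qualitative effect pattern of a two-group
#' oxytocin-vs-placebo learning study: both learning rates higher under
#' volatility in both groups; the OT group's reward learning rate exceeding
#' placebo in the volatile context only; its punishment learning rate
#' exceeding placebo in the volatile context but falling below it in the
#' stable one; and choice consistency (inverse temperature) higher in the
#' stable context in both groups, with an OT advantage in the stable
#' context only. The numeric means are implementation choices with moderate
#' effect sizes, not published values (no native-scale means are printed in
#' the study being emulated); only their orderings are anchored. ERP
#' injection means use the published group means where available (P300 3.75
#' vs 5.57 microvolts; N2pc difference -0.29 vs 0.18 microvolts).
#'
#' @param null if `TRUE`, return the zero-effect variant: all cells share
#'   one mean per parameter and ERP means are equal across groups (used for
#'   calibration checks).
#' @return a [cohort_spec()].
#' @export
default_effect_config <- function(null = FALSE) {
  if (null) {
    means <- array(rep(c(0.30, 0.30, 3.0), 4), dim = c(3, 2, 2))
    spec <- cohort_spec(param_means = means)
    spec$erp$means[] <- rowMeans(spec$erp$means)
    spec$erp$sds[] <- rowMeans(spec$erp$sds)
    return(spec)
  }
  means <- array(NA_real_, dim = c(3, 2, 2),
                 dimnames = list(c("alpha_pos", "alpha_neg", "beta"),
                                 c("OT", "PLC"), c("stable", "volatile")))
  means["alpha_pos", "OT", ] <- c(stable = 0.15, volatile = 0.45)
  means["alpha_pos", "PLC", ] <- c(stable = 0.15, volatile = 0.35)
  means["alpha_neg", "OT", ] <- c(stable = 0.10, volatile = 0.45)
  means["alpha_neg", "PLC", ] <- c(stable = 0.18, volatile = 0.35)
  means["beta", "OT", ] <- c(stable = 4.5, volatile = 2.0)
  means["beta", "PLC", ] <- c(stable = 3.5, volatile = 2.0)
  cohort_spec(param_means = means)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d OT + %d PLC subjects, anxiety-beta cor %.2f\n",
              x$n_ot, x$n_plc, x$anxiety_beta_cor))
  cat("cell means (parameter x group x context):\n")
  print(x$param_means)
  invisible(x)
}

# Quantile of a normal(mean, sd) truncated to [lo, hi]; sd = 0 collapses to
# the mean (degenerate limit).
qtrunc_norm <- function(u, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, length(u)))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Draw the subject-level parameters and anxiety scores of a cohort
#'
#' Subject parameters are drawn per cell from normals truncated to their
#' native ranges (learning rates to \[0,1\], inverse temperature to
#' `[0, beta_max]`). The trait-anxiety score (unit scale) and a latent
#' choice-consistency deviate shared across contexts are drawn jointly with
#' the spec's correlation (Gaussian copula), so anxiety correlates
#' negatively with the inverse temperature in both contexts.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the study is reproducible from spec + seed.
#' @return a `synthetic_study`: list with `subjects` (subject, group,
#'   anxiety), `params` (true native parameters per subject x context),
#'   `spec`, and `seed`. Behavior and epochs are added by
#'   [generate_behavior()] and [generate_epochs()].
#' @export
draw_cohort <- function(spec = default_effect_config(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("OT", spec$n_ot), rep("PLC", spec$n_plc))
  ids <- c(sprintf("OT%02d", seq_len(spec$n_ot)),
           sprintf("PLC%02d", seq_len(spec$n_plc)))
  n <- length(ids)
  r <- spec$anxiety_beta_cor
  draws <- with_seed(seed, {
    z_anx <- stats::rnorm(n)
    z_beta <- r * z_anx + sqrt(1 - r^2) * stats::rnorm(n)
    u_alpha <- array(stats::runif(n * 2 * 2), dim = c(n, 2, 2))
    list(z_anx = z_anx, z_beta = z_beta, u_alpha = u_alpha)
  })
  params <- do.call(rbind, lapply(c("stable", "volatile"), function(ctx) {
    ci <- (ctx == "volatile") + 1L
    draw_par <- function(par, u, hi) {
      vapply(seq_len(n), function(i) {
        qtrunc_norm(u[i], spec$param_means[par, groups[i], ctx],
                    spec$param_sds[par, groups[i], ctx], 0, hi)
      }, 0)
    }
    data.frame(subject = ids, group = groups, context = ctx,
               alpha_pos = draw_par("alpha_pos", draws$u_alpha[, 1, ci], 1),
               alpha_neg = draw_par("alpha_neg", draws$u_alpha[, 2, ci], 1),
               beta = draw_par("beta", stats::pnorm(draws$z_beta),
                               spec$beta_max),
               stringsAsFactors = FALSE)
  }))
  rownames(params) <- NULL
  structure(list(subjects = data.frame(subject = ids, group = groups,
                                       anxiety = draws$z_anx,
                                       stringsAsFactors = FALSE),
                 params = params, spec = spec, seed = as.integer(seed)),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d subjects (seed %d)%s%s\n",
              nrow(x$subjects), x$seed,
              if (!is.null(x$behavior)) ", with behavior" else "",
              if (!is.null(x$epochs)) ", with epochs" else ""))
  invisible(x)
}

#' Simulate the cohort's trial-level behavior
#'
#' For every subject a fresh 180-trial schedule is realized from the task
#' design (stable 80-trial 75/25 block plus volatile 100-trial 80/20 block)
#' and choices are simulated blockwise with the subject's context-specific
#' parameters under the RP observation model, starting each context from
#' the symmetric initial state.
#'
#' @param study a `synthetic_study` from [draw_cohort()].
#' @param design a [task_design()] (default: the canonical 180-trial task).
#' @param seed integer seed.
#' @return the study with `$behavior` (subject, group, context, trial
#'   0-based within context, choice, outcome, high_shape, rewarded_shape)
#'   and `$schedules` (per-subject `trial_schedule`) attached.
#' @export
generate_behavior <- function(study, design = task_design(), seed = 1L) {
  stopifnot(inherits(study, "synthetic_study"))
  ids <- study$subjects$subject
  schedules <- list()
  rows <- vector("list", length(ids) * 2L)
  k <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    sched <- make_schedule(design, seed = derive_seed(seed, paste0("sched/", id)))
    schedules[[id]] <- sched
    for (ctx in c("stable", "volatile")) {
      block <- sched[sched$block == ctx, , drop = FALSE]
      block$trial <- seq_len(nrow(block)) - 1L
      p <- study$params[study$params$subject == id &
                          study$params$context == ctx, ]
      prm <- rl_params(p$alpha_pos, p$alpha_neg, p$beta, model = "RP")
      sim <- simulate_choices(block, prm,
                              seed = derive_seed(seed, paste0("beh/", id, "/", ctx)))
      k <- k + 1L
      rows[[k]] <- data.frame(subject = id, group = study$subjects$group[i],
                              context = ctx, trial = block$trial,
                              choice = sim$choice, outcome = sim$outcome,
                              high_shape = block$high_shape,
                              rewarded_shape = block$rewarded_shape,
                              stringsAsFactors = FALSE)
    }
  }
  study$behavior <- do.call(rbind, rows[seq_len(k)])
  rownames(study$behavior) <- NULL
  study$schedules <- schedules
  study
}

#' Per-subject choice accuracy from a behavior table
#'
#' @param behavior behavior table with columns `subject`, `group`,
#'   `context`, `choice`, `high_shape`.
#' @return data.frame subject x context with the fraction of optimal-shape
#'   choices.
#' @export
accuracy_by_subject <- function(behavior) {
  agg <- stats::aggregate(
    list(accuracy = behavior$choice == behavior$high_shape),
    by = list(subject = behavior$subject, group = behavior$group,
              context = behavior$context),
    FUN = mean)
  agg[order(agg$subject, agg$context), ]
}

# Internal per-component epoch geometry and injection site.
erp_component_templates <- function() {
  list(
    # bump centers sit on the 250 Hz sample grid of their epoch, inside the
    # component's measurement window
    ERN = list(lock = "response", tmin = -800, tmax = 500, channel = "FCz",
               center = 32, width = 12, label_col = "correctness",
               bump_level = "incorrect", levels = c("correct", "incorrect")),
    FRN = list(lock = "feedback", tmin = -200, tmax = 1000, channel = "FCz",
               center = 300, width = 20, label_col = "feedback",
               bump_level = "negative", levels = c("positive", "negative")),
    P300 = list(lock = "stimulus", tmin = -200, tmax = 1000, channel = "Pz",
                center = 448, width = 50, label_col = "correctness",
                bump_level = "correct", levels = c("correct", "correct")),
    N2pc = list(lock = "stimulus", tmin = -100, tmax = 400,
                channel = c("PO7", "PO8"), center = 224, width = 12,
                label_col = "target_side", bump_level = "contra",
                levels = c("left", "right")))
}

# Build one subject's epoch_set for one component: Gaussian-bump template of
# the given amplitude on the component's channel(s) plus white noise.
build_component_epochs <- function(component, amplitude, noise_sd,
                                   epochs_per_condition, sfreq = 250,
                                   artifact_rate = 0, seed = 1L) {
  tpl <- erp_component_templates()[[component]]
  channels <- c("FCz", "Pz", "PO7", "PO8")
  nsamp <- round((tpl$tmax - tpl$tmin) / 1000 * sfreq) + 1L
  tms <- tpl$tmin + (seq_len(nsamp) - 1L) * 1000 / sfreq
  bump <- exp(-0.5 * ((tms - tpl$center) / tpl$width)^2)
  n_ep <- 2L * epochs_per_condition
  cond <- rep(tpl$levels, each = epochs_per_condition)
  with_seed(seed, {
    dat <- array(stats::rnorm(n_ep * length(channels) * nsamp, 0, noise_sd),
                 dim = c(n_ep, length(channels), nsamp))
    if (component == "N2pc") {
      # contralateral channel carries the bump: PO8 for left targets,
      # PO7 for right targets
      for (e in seq_len(n_ep)) {
        contra_ch <- if (cond[e] == "left") "PO8" else "PO7"
        ci <- match(contra_ch, channels)
        dat[e, ci, ] <- dat[e, ci, ] + amplitude * bump
      }
    } else {
      ci <- match(tpl$channel, channels)
      hit <- cond == tpl$bump_level
      for (e in which(hit)) dat[e, ci, ] <- dat[e, ci, ] + amplitude * bump
    }
    if (artifact_rate > 0) {
      n_art <- stats::rbinom(1, n_ep, artifact_rate)
      if (n_art > 0) {
        art <- sample.int(n_ep, n_art)
        for (e in art) dat[e, , sample.int(nsamp, 1)] <- 100
      }
    }
    labels <- data.frame(row.names = seq_len(n_ep))
    labels[[tpl$label_col]] <- cond
    if (tpl$label_col != "correctness") labels$correctness <- "correct"
    epoch_set(dat, sfreq = sfreq, tmin_ms = tpl$tmin, channels = channels,
              labels = labels, lock = tpl$lock)
  })
}

#' Generate synthetic ERP epochs for cohort subjects
#'
#' Per subject and component, epochs are the sum of a Gaussian-bump
#' component template (amplitude drawn once per subject around the group
#' mean; latency centered inside the component's analysis window) and
#' zero-mean white Gaussian noise on channels FCz, Pz, PO7 and PO8 at
#' 250 Hz, with the appropriate condition labels attached. Memory grows
#' linearly in subjects and epochs; for cohort-scale scoring prefer
#' [cohort_erp_scores()], which streams subjects.
#'
#' @param study a `synthetic_study`.
#' @param components components to generate (default all four).
#' @param epochs_per_condition epochs per condition level (default 60).
#' @param seed integer seed.
#' @param subjects subset of subject ids (default all).
#' @return an `epoch_bundle`: list with `epochs` (subject -> component ->
#'   `epoch_set`) and `amplitudes` (the injected per-subject amplitudes).
#' @export
generate_epochs <- function(study, components = c("ERN", "FRN", "P300", "N2pc"),
                            epochs_per_condition = 60L, seed = 1L,
                            subjects = NULL) {
  stopifnot(inherits(study, "synthetic_study"))
  components <- match.arg(components, several.ok = TRUE)
  subjects <- subjects %||% study$subjects$subject
  amps <- draw_erp_amplitudes(study, components, seed)
  amps <- amps[amps$subject %in% subjects, , drop = FALSE]
  ep <- lapply(subjects, function(id) {
    out <- lapply(components, function(cmp) {
      a <- amps$amplitude[amps$subject == id & amps$component == cmp]
      build_component_epochs(cmp, a, study$spec$erp$noise_sd,
                             epochs_per_condition,
                             artifact_rate = study$spec$erp$artifact_rate,
                             seed = derive_seed(seed, paste0("ep/", id, "/", cmp)))
    })
    names(out) <- components
    out
  })
  names(ep) <- subjects
  structure(list(epochs = ep, amplitudes = amps,
                 epochs_per_condition = as.integer(epochs_per_condition)),
            class = "epoch_bundle")
}

#' Injected ERP amplitudes for every subject
#'
#' @param study a `synthetic_study`.
#' @param components component subset.
#' @param seed seed shared with [generate_epochs()] so amplitudes match.
#' @return data.frame subject, group, component, amplitude (microvolts).
#' @export
draw_erp_amplitudes <- function(study,
                                components = c("ERN", "FRN", "P300", "N2pc"),
                                seed = 1L) {
  components <- match.arg(components, several.ok = TRUE)
  rows <- list()
  for (cmp in components) {
    for (i in seq_len(nrow(study$subjects))) {
      id <- study$subjects$subject[i]
      g <- study$subjects$group[i]
      a <- with_seed(derive_seed(seed, paste0("amp/", id, "/", cmp)),
                     stats::rnorm(1, study$spec$erp$means[cmp, g],
                                  study$spec$erp$sds[cmp, g]))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = id, group = g, component = cmp, amplitude = a,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Extract component scores for a whole cohort, streaming subjects
#'
#' Generates each subject's epochs, scores them with the standard component
#' rules, and discards the raw arrays, keeping memory flat in cohort size.
#'
#' @param study a `synthetic_study`.
#' @param components components to score.
#' @param epochs_per_condition epochs per condition level.
#' @param seed integer seed (amplitudes and noise reproducible).
#' @param threshold artifact-rejection threshold in microvolts.
#' @return data.frame subject, group, component, injected amplitude, and
#'   extracted `score`.
#' @export
cohort_erp_scores <- function(study,
                              components = c("ERN", "FRN", "P300", "N2pc"),
                              epochs_per_condition = 60L, seed = 1L,
                              threshold = 80) {
  components <- match.arg(components, several.ok = TRUE)
  specs <- default_component_specs()
  amps <- draw_erp_amplitudes(study, components, seed)
  rows <- vector("list", nrow(amps))
  for (j in seq_len(nrow(amps))) {
    id <- amps$subject[j]
    cmp <- amps$component[j]
    eset <- build_component_epochs(cmp, amps$amplitude[j],
                                   study$spec$erp$noise_sd,
                                   epochs_per_condition,
                                   artifact_rate = study$spec$erp$artifact_rate,
                                   seed = derive_seed(seed, paste0("ep/", id, "/", cmp)))
    sc <- component_score(eset, specs[[cmp]], threshold = threshold)
    rows[[j]] <- data.frame(subject = id, group = amps$group[j],
                            component = cmp, amplitude = amps$amplitude[j],
                            score = sc$score, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
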