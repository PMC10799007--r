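#' Read and validate a trial-level behavior table
#'
#' Reads delimited text (TSV for `.tsv`/`.tab`, otherwise CSV) with the
#' required columns `subject`, `group`, `context`, `trial`, `choice`,
#' `outcome`. Non-response/invalid trials — rows with a missing or empty
#' choice or a missing outcome — are dropped with a message reporting the
#' count, mirroring the exclusion of no-response trials before fitting.
#'
#' @param path file path.
#' @return validated data.frame of trial records.
#' @export
read_trial_table <- function(path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  x <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("subject", "group", "context", "trial", "choice", "outcome")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("trial table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invalid <- is.na(x$choice) | x$choice == "" | x$choice == "none" |
    is.na(x$outcome)
  if (any(invalid)) {
    message("dropping ", sum(invalid), " non-response/invalid trial(s)")
    x <- x[!invalid, , drop = FALSE]
  }
  bad <- which(!x$outcome %in% c(0, 1))
  if (length(bad)) {
    stop("non-binary outcome in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad_choice <- which(!x$choice %in% c("A", "B"))
  if (length(bad_choice)) {
    stop("choice must be 'A' or 'B'; offending row(s): ",
         paste(utils::head(bad_choice, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$subject, x$context, x$trial)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, context, trial) key(s), e.g. ",
         key[anyDuplicated(key)][1], call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Write a trial table as CSV
#' @param x trial table data.frame.
#' @param path file path.
#' @export
write_trial_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Configuration of an end-to-end pipeline run
#'
#' @param out_dir output directory for the run's artifacts.
#' @param cohort a [cohort_spec()]; defaults to the standard effect
#'   configuration with the sizes overridden by `n_ot`/`n_plc`.
#' @param n_ot,n_plc group sizes of the synthetic cohort.
#' @param models models to fit per cell (subset of `"RP"`, `"RW"`, `"EWA"`).
#' @param chains,warmup,draws MCMC settings (see [fit_config()]).
#' @param erp_components ERP components to score (`character(0)` skips the
#'   ERP stage).
#' @param epochs_per_condition synthetic epochs per condition level.
#' @param seed global seed; per-stage child seeds are derived
#'   deterministically from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(out_dir,
                            cohort = NULL,
                            n_ot = 8L, n_plc = 8L,
                            models = "RP",
                            chains = 2L, warmup = 300L, draws = 300L,
                            erp_components = c("P300", "N2pc"),
                            epochs_per_condition = 20L,
                            seed = 1L) {
  bad <- setdiff(models, c("RP", "RW", "EWA"))
  if (length(bad)) {
    stop_config("models", paste("contains unknown model tag(s):",
                                paste(bad, collapse = ", ")))
  }
  if (length(erp_components)) {
    bad <- setdiff(erp_components, c("ERN", "FRN", "P300", "N2pc"))
    if (length(bad)) {
      stop_config("erp_components", paste("unknown component(s):",
                                          paste(bad, collapse = ", ")))
    }
  }
  if (is.null(cohort)) {
    cohort <- default_effect_config()
    cohort$n_ot <- as.integer(n_ot)
    cohort$n_plc <- as.integer(n_plc)
  }
  stopifnot(inherits(cohort, "cohort_spec"))
  structure(list(out_dir = out_dir, cohort = cohort, models = models,
                 chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws),
                 erp_components = erp_components,
                 epochs_per_condition = as.integer(epochs_per_condition),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full synthetic-study analysis pipeline
#'
#' Chains cohort synthesis, behavior simulation, per-cell hierarchical
#' fitting, LOOIC model comparison, ERP scoring, and group statistics into
#' one reproducible report directory. Rerunning with the same configuration
#' reproduces every numeric output (the manifest records per-file hashes).
#'
#' Artifacts written to `out_dir`: `params.csv` and `anxiety.csv` (true
#' subject parameters and covariate), `behavior.csv`,
#' `schedule_example.tsv`, `rhat.csv`, `subject_estimates.csv`,
#' `looic_long.csv` and `looic_table.csv` (models x cells), `erp_scores.csv`,
#' `anova_effects.csv`, `correlations.csv`, and `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the path of the report directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  wcsv <- function(x, f) utils::write.csv(x, out(f), row.names = FALSE)
  seed <- config$seed

  study <- run_stage("cohort", {
    st <- draw_cohort(config$cohort, seed = derive_seed(seed, "cohort"))
    wcsv(st$params, "params.csv")
    wcsv(st$subjects, "anxiety.csv")
    st
  })

  study <- run_stage("behavior", {
    st <- generate_behavior(study, seed = derive_seed(seed, "behavior"))
    write_trial_table(st$behavior, out("behavior.csv"))
    write_schedule(st$schedules[[1]], out("schedule_example.tsv"))
    st
  })

  fits <- run_stage("fit", {
    cells <- expand.grid(group = c("OT", "PLC"),
                         context = c("stable", "volatile"),
                         stringsAsFactors = FALSE)
    fits <- list()
    for (i in seq_len(nrow(cells))) {
      cell_data <- study$behavior[
        study$behavior$group == cells$group[i] &
          study$behavior$context == cells$context[i], ]
      for (m in config$models) {
        cfg <- fit_config(chains = config$chains, warmup = config$warmup,
                          draws = config$draws,
                          seed = derive_seed(seed, paste("fit", m,
                                                         cells$group[i],
                                                         cells$context[i])))
        fits[[paste(m, cells$group[i], cells$context[i], sep = "_")]] <-
          fit_hierarchical(cell_data, model = m, config = cfg)
      }
    }
    rhat_tab <- do.call(rbind, lapply(names(fits), function(nm) {
      r <- group_level_rhat(fits[[nm]])
      data.frame(fit = nm, parameter = names(r), rhat = unname(r))
    }))
    wcsv(rhat_tab, "rhat.csv")
    est <- do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (f$model != "RP") return(NULL)
      cbind(group = f$cell$group, context = f$cell$context,
            subject_posterior_means(f))
    }))
    wcsv(est, "subject_estimates.csv")
    fits
  })

  run_stage("compare", {
    cmp <- compare_models(fits)
    wcsv(cmp, "looic_long.csv")
    wide <- stats::reshape(cmp[, c("model", "cell", "looic")],
                           idvar = "model", timevar = "cell",
                           direction = "wide")
    names(wide) <- sub("^looic\\.", "", names(wide))
    wcsv(wide, "looic_table.csv")
  })

  erp_scores <- run_stage("erp", {
    if (!length(config$erp_components)) return(NULL)
    sc <- cohort_erp_scores(study, components = config$erp_components,
                            epochs_per_condition = config$epochs_per_condition,
                            seed = derive_seed(seed, "erp"))
    wcsv(sc, "erp_scores.csv")
    sc
  })

  run_stage("stats", {
    est <- do.call(rbind, lapply(fits, function(f) {
      if (f$model != "RP") return(NULL)
      cbind(group = f$cell$group, context = f$cell$context,
            subject_posterior_means(f))
    }))
    acc <- accuracy_by_subject(study$behavior)
    effects <- list()
    add_anova <- function(measure, tab) {
      a <- mixed_anova_2x2(tab)
      a$measure <- measure
      effects[[length(effects) + 1L]] <<- a
    }
    add_anova("accuracy", data.frame(subject = acc$subject, group = acc$group,
                                     context = acc$context,
                                     value = acc$accuracy))
    if (!is.null(est)) {
      for (par in c("alpha_pos", "alpha_neg", "beta")) {
        add_anova(par, data.frame(subject = est$subject, group = est$group,
                                  context = est$context, value = est[[par]]))
      }
    }
    wcsv(do.call(rbind, effects), "anova_effects.csv")

    cors <- list()
    if (!is.null(est)) {
      anx <- study$subjects
      for (ctx in c("stable", "volatile")) {
        sub <- est[est$context == ctx, ]
        m <- merge(sub, anx, by = c("subject", "group"))
        ct <- correlation(m$anxiety, m$beta, "spearman")
        cors[[length(cors) + 1L]] <- data.frame(
          measure = "anxiety_vs_beta", context = ctx, group = "all",
          method = "spearman", r = ct$r, p = ct$p, n = ct$n)
        per_group <- lapply(c("OT", "PLC"), function(g) {
          mg <- m[m$group == g, ]
          c(correlation(mg$anxiety, mg$beta, "spearman")[c("r", "n")])
        })
        fz1 <- fisher_z_compare(per_group[[1]]$r, per_group[[1]]$n,
                                per_group[[2]]$r, per_group[[2]]$n)
        cors[[length(cors) + 1L]] <- data.frame(
          measure = "anxiety_vs_beta_fisher_z_OT_minus_PLC", context = ctx,
          group = "OT-PLC", method = "fisher_z", r = fz1$z, p = fz1$p,
          n = per_group[[1]]$n + per_group[[2]]$n)
      }
    }
    if (length(cors)) wcsv(do.call(rbind, cors), "correlations.csv")
  })

  run_stage("manifest", {
    files <- setdiff(list.files(config$out_dir), "manifest.json")
    hashes <- vapply(files, function(f) unname(tools::md5sum(out(f))), "")
    manifest <- list(
      seed = seed,
      stage_seeds = list(cohort = derive_seed(seed, "cohort"),
                         behavior = derive_seed(seed, "behavior"),
                         erp = derive_seed(seed, "erp")),
      config = list(n_ot = config$cohort$n_ot, n_plc = config$cohort$n_plc,
                    models = config$models, chains = config$chains,
                    warmup = config$warmup, draws = config$draws,
                    erp_components = config$erp_components,
                    epochs_per_condition = config$epochs_per_condition),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("volatileRL")),
      file_hashes = as.list(hashes))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })

  invisible(config$out_dir)
}
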