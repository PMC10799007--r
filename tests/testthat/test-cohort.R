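test_that("the default effect configuration satisfies the study's orderings", {
  m <- default_effect_config()$param_means
  # both learning rates: volatile > stable in both groups
  for (g in c("OT", "PLC")) {
    expect_gt(m["alpha_pos", g, "volatile"], m["alpha_pos", g, "stable"])
    expect_gt(m["alpha_neg", g, "volatile"], m["alpha_neg", g, "stable"])
    # consistency: stable > volatile in both groups
    expect_gt(m["beta", g, "stable"], m["beta", g, "volatile"])
  }
  # reward rate: OT advantage only under volatility
  expect_gt(m["alpha_pos", "OT", "volatile"], m["alpha_pos", "PLC", "volatile"])
  expect_equal(m["alpha_pos", "OT", "stable"], m["alpha_pos", "PLC", "stable"])
  # punishment rate: OT above PLC when volatile, below when stable
  expect_gt(m["alpha_neg", "OT", "volatile"], m["alpha_neg", "PLC", "volatile"])
  expect_lt(m["alpha_neg", "OT", "stable"], m["alpha_neg", "PLC", "stable"])
  # consistency: OT advantage only when stable
  expect_gt(m["beta", "OT", "stable"], m["beta", "PLC", "stable"])

  # null variant: one mean per parameter everywhere, ERP effects removed
  null <- default_effect_config(null = TRUE)
  for (p in rownames(null$param_means)) {
    expect_length(unique(as.vector(null$param_means[p, , ])), 1L)
  }
  expect_equal(null$erp$means[, "OT"], null$erp$means[, "PLC"])

  # the spec round-trips through serialization unchanged
  tf <- tempfile()
  saveRDS(default_effect_config(), tf)
  expect_identical(readRDS(tf), default_effect_config())
  unlink(tf)
})

test_that("cohort draws respect the anxiety-consistency correlation", {
  spec <- default_effect_config()
  spec$n_ot <- 500L; spec$n_plc <- 500L
  st <- draw_cohort(spec, seed = 17)
  for (ctx in c("stable", "volatile")) {
    p <- st$params[st$params$context == ctx, ]
    m <- merge(p, st$subjects, by = c("subject", "group"))
    expect_lt(abs(cor(m$anxiety, m$beta) - spec$anxiety_beta_cor), 0.05)
  }

  spec0 <- spec; spec0$anxiety_beta_cor <- 0
  st0 <- draw_cohort(spec0, seed = 18)
  m0 <- merge(st0$params[st0$params$context == "stable", ], st0$subjects,
              by = c("subject", "group"))
  expect_lt(abs(cor(m0$anxiety, m0$beta)), 0.08)

  # degenerate limit: zero dispersion puts every subject at the cell mean
  specd <- default_effect_config()
  specd$param_sds[, , ] <- 0
  std <- draw_cohort(specd, seed = 19)
  ot_stable <- std$params[std$params$group == "OT" &
                            std$params$context == "stable", ]
  expect_true(all(ot_stable$alpha_pos == specd$param_means["alpha_pos", "OT", "stable"]))
  expect_true(all(ot_stable$beta == specd$param_means["beta", "OT", "stable"]))

  expect_error(cohort_spec(param_means = specd$param_means,
                           anxiety_beta_cor = 1.2), "anxiety_beta_cor")
  expect_error(cohort_spec(n_ot = 1, param_means = specd$param_means),
               "n_ot")
})

test_that("simulated behavior has the right shape and context-accuracy ordering", {
  spec <- default_effect_config()
  spec$n_ot <- 8L; spec$n_plc <- 8L
  st <- generate_behavior(draw_cohort(spec, seed = 23), seed = 24)
  expect_equal(nrow(st$behavior), 16L * 180L)
  expect_true(all(table(st$behavior$subject) == 180L))

  # stable-context accuracy exceeds volatile-context accuracy on average
  # across replicate cohorts
  diffs <- vapply(1:20, function(s) {
    sti <- generate_behavior(draw_cohort(spec, seed = 100 + s),
                             seed = 200 + s)
    acc <- accuracy_by_subject(sti$behavior)
    mean(acc$accuracy[acc$context == "stable"]) -
      mean(acc$accuracy[acc$context == "volatile"])
  }, 0)
  expect_gt(mean(diffs > 0), 0.9)
  expect_gt(mean(diffs), 0.05)

  # reproducibility: identical study from spec + seed
  a <- generate_behavior(draw_cohort(spec, seed = 31), seed = 32)
  b <- generate_behavior(draw_cohort(spec, seed = 31), seed = 32)
  expect_identical(volatileRL:::hash_object(a), volatileRL:::hash_object(b))
})

test_that("the null cohort induces no group difference in accuracy", {
  spec <- default_effect_config(null = TRUE)
  spec$n_ot <- 12L; spec$n_plc <- 12L
  diffs <- vapply(1:10, function(s) {
    st <- generate_behavior(draw_cohort(spec, seed = 300 + s),
                            seed = 400 + s)
    acc <- accuracy_by_subject(st$behavior)
    mean(acc$accuracy[acc$group == "OT"]) -
      mean(acc$accuracy[acc$group == "PLC"])
  }, 0)
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("noiseless epochs return the injected amplitudes exactly", {
  spec <- default_effect_config()
  spec$n_ot <- 2L; spec$n_plc <- 2L
  spec$erp$noise_sd <- 0
  st <- draw_cohort(spec, seed = 41)
  bundle <- generate_epochs(st, epochs_per_condition = 8L, seed = 42)
  specs <- default_component_specs()
  for (id in st$subjects$subject) {
    for (cmp in c("ERN", "FRN", "P300")) {
      a <- bundle$amplitudes$amplitude[bundle$amplitudes$subject == id &
                                         bundle$amplitudes$component == cmp]
      sc <- component_score(bundle$epochs[[id]][[cmp]], specs[[cmp]])
      expect_equal(sc$score, a, tolerance = 1e-9)
    }
    # N2pc peak picking recovers negative injections; a positive injection
    # floors at the window minimum (near zero without noise)
    a <- bundle$amplitudes$amplitude[bundle$amplitudes$subject == id &
                                       bundle$amplitudes$component == "N2pc"]
    sc <- component_score(bundle$epochs[[id]][["N2pc"]], specs$N2pc)
    if (a < 0) {
      expect_equal(sc$score, a, tolerance = 1e-9)
    } else {
      # a positive injection has no negative peak: the window minimum is the
      # bump's smaller edge value, between 0 and the injected amplitude
      expect_gte(sc$score, 0)
      expect_lte(sc$score, a)
    }
  }

  # epochs with large injected artifacts are rejected downstream
  spec$erp$artifact_rate <- 0.3
  st2 <- draw_cohort(spec, seed = 43)
  b2 <- generate_epochs(st2, components = "P300", epochs_per_condition = 20L,
                        seed = 44, subjects = st2$subjects$subject[1])
  sc <- component_score(b2$epochs[[1]]$P300, specs$P300)
  expect_gt(sc$rejected_fraction, 0)
})
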