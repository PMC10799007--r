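test_that("baseline correction removes offsets and preserves shape", {
  # constant epochs go to zero
  ep <- make_epochs(3, fill = 2.5)
  bc <- baseline_correct(ep, c(-200, 0))
  expect_true(all(bc$data == 0))

  # offset + bump: the bump survives sample-wise, the offset does not
  ep <- make_epochs(1, channels = "FCz", tmin = -200, tmax = 800)
  tms <- epoch_times(ep)
  bump <- gauss_bump(tms, 400, 30, 5)
  ep$data[1, 1, ] <- 3 + bump
  bc <- baseline_correct(ep, c(-200, -100))
  expect_equal(bc$data[1, 1, ], bump, tolerance = 1e-9)

  # an epoch whose baseline already averages zero is untouched
  ep$data[1, 1, ] <- bump  # baseline window is flat zero there
  expect_equal(baseline_correct(ep, c(-200, -100))$data, ep$data,
               tolerance = 1e-12)

  expect_error(baseline_correct(ep, c(-900, -800)), "outside")
})

test_that("artifact rejection uses a strict threshold and is idempotent", {
  ep <- make_epochs(10, channels = "FCz", tmin = 0, tmax = 400)
  ep$data[3, 1, 10] <- 100
  ep$data[7, 1, 50] <- -100
  res <- reject_artifacts(ep, 80)
  expect_equal(res$rejected_fraction, 0.2)
  expect_equal(dim(res$epochs$data)[1], 8L)

  # boundary epochs (exactly +/-80) are retained: "exceeding" is strict
  ep2 <- make_epochs(4, channels = "FCz", tmin = 0, tmax = 400)
  ep2$data[2, 1, 5] <- 80
  ep2$data[3, 1, 5] <- -80
  expect_equal(reject_artifacts(ep2, 80)$rejected_fraction, 0)

  # infinite threshold removes nothing; rejection is idempotent
  expect_equal(reject_artifacts(ep, Inf)$rejected_fraction, 0)
  twice <- reject_artifacts(res$epochs, 80)
  expect_equal(twice$rejected_fraction, 0)
  expect_identical(twice$epochs$data, res$epochs$data)

  ep3 <- make_epochs(2, channels = "FCz", tmin = 0, tmax = 400, fill = 90)
  expect_error(reject_artifacts(ep3, 80), "all epochs")
})

test_that("condition averages are pointwise means over the selected epochs", {
  labs <- data.frame(correctness = c("correct", "incorrect"))
  ep <- make_epochs(2, channels = "FCz", labels = labs)
  ep$data[1, 1, ] <- 1
  ep$data[2, 1, ] <- 3
  expect_true(all(condition_average(ep, c(correctness = "correct")) == 1))
  expect_true(all(condition_average(ep) == 2))

  # +x and -x cancel
  ep$data[2, 1, ] <- -1
  expect_true(all(condition_average(ep) == 0))

  # 50 noisy copies of a template: average within a few noise sd / sqrt(50)
  set.seed(61)
  ep <- make_epochs(50, channels = "FCz", tmin = -200, tmax = 800)
  tms <- epoch_times(ep)
  tpl <- gauss_bump(tms, 300, 40, 4)
  for (e in 1:50) ep$data[e, 1, ] <- tpl + rnorm(length(tms))
  avg <- condition_average(ep)["FCz", ]
  expect_lt(max(abs(avg - tpl)), 5 / sqrt(50))

  expect_error(condition_average(ep, c(correctness = "correct")),
               "missing condition label")
})

test_that("peak measurement finds the signed extremum with earliest-tie latency", {
  tms <- seq(-200, 800, by = 4)
  flat <- rep(0, length(tms))
  expect_equal(peak_measure(flat, tms, c(300, 600), "positive")$amplitude, 0)

  bump <- gauss_bump(tms, 400, 50, 5)
  pk <- peak_measure(bump, tms, c(300, 600), "positive")
  expect_equal(pk$amplitude, 5)
  expect_equal(pk$latency_ms, 400)

  # window excluding the true peak returns a smaller edge value
  edge <- peak_measure(bump, tms, c(500, 700), "positive")
  expect_lt(edge$amplitude, 5)

  neg <- peak_measure(-bump, tms, c(300, 600), "negative")
  expect_equal(neg$amplitude, -5)

  # exact tie: two equal maxima, earliest wins
  two <- flat; two[tms == 352] <- 2; two[tms == 500] <- 2
  expect_equal(peak_measure(two, tms, c(300, 600), "positive")$latency_ms, 352)

  expect_error(peak_measure(bump, tms, c(700, 900), "positive"), "outside")
})

test_that("difference components score injected condition effects", {
  specs <- default_component_specs()
  labs <- data.frame(correctness = rep(c("correct", "incorrect"), each = 10))
  ep <- make_epochs(20, channels = c("FCz", "Pz", "PO7", "PO8"),
                    tmin = -800, tmax = 500)
  ep$labels <- labs
  ep$lock <- "response"
  tms <- epoch_times(ep)
  # identical conditions: zero difference score
  expect_equal(component_score(ep, specs$ERN)$score, 0)

  # -4 uV bump only in incorrect trials at the ERN latency
  bump <- gauss_bump(tms, 32, 12, -4)
  for (e in 11:20) ep$data[e, 1, ] <- ep$data[e, 1, ] + bump
  sc <- component_score(ep, specs$ERN)
  expect_equal(sc$score, -4, tolerance = 1e-9)
  expect_equal(sc$latency_ms, 32)

  # peak-difference reading: peak(incorrect) - peak(correct)
  sc2 <- component_score(ep, specs$ERN, peak_mode = "peak_difference")
  expect_equal(sc2$score, -4, tolerance = 1e-9)

  # P300: positive peak of the correct-trial average at Pz
  ep3 <- make_epochs(10, tmin = -200, tmax = 1000)
  ep3$labels <- data.frame(correctness = rep("correct", 10))
  tms3 <- epoch_times(ep3)
  for (e in 1:10) ep3$data[e, 2, ] <- gauss_bump(tms3, 448, 50, 5.57)
  expect_equal(component_score(ep3, specs$P300)$score, 5.57, tolerance = 1e-9)

  # an ERN score demands incorrect trials
  ep5 <- make_epochs(4, tmin = -800, tmax = 500)
  ep5$labels <- data.frame(correctness = rep("correct", 4))
  expect_error(component_score(ep5, specs$ERN), "no epochs match")
})

test_that("the N2pc contra/ipsi rule behaves under symmetry and relabeling", {
  tmin <- -100; tmax <- 400
  labs <- data.frame(target_side = rep(c("left", "right"), each = 6))
  ep <- make_epochs(12, tmin = tmin, tmax = tmax, labels = labs)
  tms <- epoch_times(ep)

  # identical PO7/PO8 signals: difference identically zero
  for (e in 1:12) {
    ep$data[e, 3, ] <- gauss_bump(tms, 224, 12, 1)
    ep$data[e, 4, ] <- gauss_bump(tms, 224, 12, 1)
  }
  res <- n2pc_score(ep)
  expect_true(all(abs(res$contra - res$ipsi) < 1e-12))
  expect_equal(res$score, 0)

  # -2 uV bump injected into contralateral channels only
  ep2 <- make_epochs(12, tmin = tmin, tmax = tmax, labels = labs)
  bump <- gauss_bump(tms, 224, 12, -2)
  for (e in 1:12) {
    contra_ch <- if (labs$target_side[e] == "left") 4 else 3  # PO8 / PO7
    ep2$data[e, contra_ch, ] <- bump
  }
  expect_equal(n2pc_score(ep2)$score, -2, tolerance = 1e-9)

  # swapping all target-side labels swaps contra and ipsi
  ep3 <- ep2
  ep3$labels$target_side <- ifelse(labs$target_side == "left", "right", "left")
  res2 <- n2pc_score(ep2)
  res3 <- n2pc_score(ep3)
  expect_equal(res3$contra, res2$ipsi, tolerance = 1e-12)
  expect_equal(res3$ipsi, res2$contra, tolerance = 1e-12)

  ep4 <- ep2; ep4$labels$target_side <- "left"
  expect_error(n2pc_score(ep4), "both target sides")
  expect_error(n2pc_score(make_epochs(2, channels = c("FCz", "Pz"),
                                      tmin = tmin, tmax = tmax)),
               "PO7")
})

test_that("baseline correction commutes with condition averaging", {
  set.seed(77)
  labs <- data.frame(correctness = rep("correct", 20))
  ep <- make_epochs(20, channels = "FCz", tmin = -200, tmax = 800)
  ep$labels <- labs
  for (e in 1:20) ep$data[e, 1, ] <- rnorm(dim(ep$data)[3], 1)
  avg_then_corr <- {
    avg <- condition_average(ep)["FCz", ]
    tms <- epoch_times(ep)
    idx <- tms >= -200 & tms <= 0
    avg - mean(avg[idx])
  }
  corr_then_avg <- condition_average(baseline_correct(ep, c(-200, 0)))["FCz", ]
  expect_equal(corr_then_avg, avg_then_corr, tolerance = 1e-10)
})

test_that("scores recover injected amplitudes through noise", {
  spec <- default_effect_config()
  spec$n_ot <- 2L; spec$n_plc <- 2L
  st <- draw_cohort(spec, seed = 83)
  sc <- cohort_erp_scores(st, epochs_per_condition = 60L, seed = 84)
  neg <- sc$component != "N2pc" | sc$amplitude < 0
  expect_lt(max(abs(sc$score - sc$amplitude)[neg]), 0.5)
})
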