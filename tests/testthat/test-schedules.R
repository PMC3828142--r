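test_that("clinical presets deliver the catalogue totals and timings", {
  conv <- build_preset("conventional")
  expect_equal(nrow(conv), 30)
  expect_equal(sum(conv$dose_gy), 60)
  expect_true(all(conv$dose_gy == 2))
  days <- conv$time_h / 24
  expect_true(all(days %% 7 %in% 0:4)) # weekdays only
  expect_equal(max(conv$time_h), (5 * 7 + 4) * 24) # six working weeks

  chart <- build_preset("CHART")
  expect_equal(nrow(chart), 36)
  expect_equal(sum(chart$dose_gy), 54)
  expect_true(all(chart$dose_gy == 1.5))
  expect_equal(unique(diff(chart$time_h)), 8) # 3/day, every day, 8 h apart
  expect_equal(max(chart$time_h), 11 * 24 + 16)
  # 4.5 Gy per 24 h while on treatment
  expect_equal(sum(chart$dose_gy) / (12 * 24) * 24, 4.5)

  hyp <- build_preset("accelerated-hyper")
  expect_equal(nrow(hyp), 60)
  expect_true(all(hyp$dose_gy == 1))
  expect_equal(sort(unique(diff(hyp$time_h))), c(12)) # 2/day, no gaps

  totals <- vapply(c("conventional", "accelerated-conventional",
                     "hypofractionated", "accelerated-hypo",
                     "hyperfractionated", "accelerated-hyper",
                     "split-course", "concomitant-boost"),
                   function(nm) sum(build_preset(nm)$dose_gy), numeric(1))
  expect_true(all(totals == 60))
  expect_error(build_preset("sbrt"))

  # split course: one 14-day gap, otherwise conventional
  sc <- build_preset("split-course")
  gaps <- diff(sc$time_h)
  expect_equal(max(gaps), (14 + 3) * 24) # gap spans the mid-course pause
})

test_that("constant-rate schedules keep dose per time fixed", {
  s <- build_constant_rate(2.5, 30, 60)
  expect_equal(nrow(s), 24)
  expect_equal(unique(diff(s$time_h)), 30)
  expect_equal(sum(s$dose_gy), 60)
  s2 <- build_constant_rate(2, 24, 60)
  expect_equal(nrow(s2), 30)
  expect_equal(attr(s2, "meta")$rate_gy_per_24h,
               attr(s, "meta")$rate_gy_per_24h)
  expect_warning(s3 <- build_constant_rate(3.5, 42, 60), "truncated")
  expect_equal(sum(s3$dose_gy), 60)
})

test_that("trigger/effector blocks respect the rate constraint", {
  s <- build_triggered_block(2, 4, 12)
  meta <- attr(s, "meta")
  expect_equal(meta$block_h, 72) # 6 Gy per block at 2 Gy/24 h
  expect_equal(sum(s$dose_gy), 60)
  expect_equal(s$time_h[1:4], c(0, 12, 72, 84))
  # with the effector placed at the ~24 h sensitivity peak, the pause to the
  # next trigger/effector block is 48 h
  s24 <- build_triggered_block(2, 4, 24)
  expect_equal(s24$time_h[3] - s24$time_h[2], 48)

  s11 <- build_triggered_block(1, 1, 12)
  expect_equal(attr(s11, "meta")$block_h, 24)

  expect_error(build_triggered_block(2, 4, 80), "unreachable")
})

test_that("automatic triggering doses plateaus when the budget allows", {
  pol <- trigger_policy(window_h = 12, d_min = 1)
  hist_up <- tibble::tibble(time_h = seq(0, 48, 2),
                            enhancement = seq(1, 2, length.out = 25))
  # strictly increasing: no peak, no dose
  expect_equal(auto_trigger_step(hist_up, 48, pol, delivered_so_far = 0), 0)

  hist_peak <- tibble::tibble(
    time_h = seq(0, 48, 2),
    enhancement = c(seq(1, 2, length.out = 18), rep(2, 7)))
  # plateau, budget 48 h * 2/24 = 4 Gy >= 1 Gy: deliver the budget
  expect_equal(auto_trigger_step(hist_peak, 48, pol, 0), 4)
  # plateau but budget below the minimum: withhold
  expect_equal(auto_trigger_step(hist_peak, 48, pol, 3.6), 0)

  # regression mode: non-positive fitted slope triggers
  pol_r <- trigger_policy(mode = "regression", regression_window_h = 12)
  hist_down <- tibble::tibble(time_h = seq(0, 48, 2),
                              enhancement = c(seq(1, 2, length.out = 20),
                                              seq(2, 1.8, length.out = 5)))
  expect_gt(auto_trigger_step(hist_down, 48, pol_r, 0), 0)
  expect_equal(auto_trigger_step(hist_up, 48, pol_r, 0), 0)
})
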