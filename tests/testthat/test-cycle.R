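test_that("phase durations follow the truncated normal family", {
  cp0 <- cycle_params(sigma_rel = 0)
  d0 <- sample_phase_durations(5, cp0)
  expect_equal(unname(as.matrix(d0)),
               matrix(rep(c(8, 6, 4.5, 1), each = 5), ncol = 4))

  set.seed(7)
  cp <- cycle_params()
  d <- sample_phase_durations(1e5, cp)
  # Monte-Carlo: symmetric truncation keeps the mean; 1% band at n = 1e5
  expect_lt(abs(mean(d$G1) - 8) / 8, 0.01)
  for (ph in names(cp$mean_durations)) {
    mu <- cp$mean_durations[[ph]]
    expect_true(all(d[[ph]] >= mu * (1 - 0.3 * 3) - 1e-12))
    expect_true(all(d[[ph]] <= mu * (1 + 0.3 * 3) + 1e-12))
    expect_true(all(d[[ph]] > 0))
  }
  expect_equal(sum(cp$mean_durations), 19.5)
  expect_error(cycle_params(sigma_rel = 0.5, cutoff = 3), "truncation")
})

test_that("phase-angle is active time over individual cycle length", {
  cp <- cycle_params(sigma_rel = 0)
  pop <- new_population(3, cp)
  expect_equal(phase_angle(pop), rep(0, 3)) # newborn

  pop$active_time <- c(8, 5, 0) # just completed G1 / mid-G1 / newborn
  expect_equal(phase_angle(pop), c(8 / 19.5, 5 / 19.5, 0))

  # quiescence freezes the angle: advancing a G0 cell changes nothing
  pop$phase <- c("G0", "G0", "G1")
  pop$pressure <- 1000
  pop$glucose <- 5
  for (i in 1:50) pop <- advance_cycle(pop, 0.1, cp)$population
  expect_equal(phase_angle(pop)[1:2], c(8 / 19.5, 5 / 19.5))

  pop$phase[1] <- "necrotic"
  expect_warning(a <- phase_angle(pop), "undefined")
  expect_true(is.na(a[1]))
})

test_that("checkpoints gate quiescence and necrosis", {
  cp <- cycle_params(sigma_rel = 0)
  pop <- new_population(2, cp)
  pop$glucose <- 5
  pop$clock <- 7.95 # just before the G1/S checkpoint
  pop$active_time <- 7.95
  pop$pressure <- c(250, 150)
  out <- advance_cycle(pop, 0.1, cp)$population
  expect_equal(out$phase, c("G0", "S")) # 250 Pa > 200 Pa critical pressure

  # G0 cell re-enters at the restriction point once pressure drops
  out$pressure <- c(100, 100)
  out2 <- advance_cycle(out, 0.1, cp)$population
  expect_equal(out2$phase[1], "S")
  expect_lte(out2$clock[1], 0.1) # restarts S at the restriction point

  # complete glucose depletion triggers necrosis in any phase
  pop2 <- make_population(c("G1", "S", "G0"))
  pop2$glucose <- 0
  out3 <- advance_cycle(pop2, 0.1, cp)$population
  expect_equal(out3$phase, rep("necrotic", 3))
  expect_true(all(out3$death_clock > 0))
})

test_that("undisturbed deterministic cells divide every 19.5 h", {
  cp <- cycle_params(sigma_rel = 0)
  pop <- new_population(1, cp)
  pop$glucose <- 5
  pop$pressure <- 0
  divisions <- numeric(0)
  t <- 0
  set.seed(1)
  for (i in 1:450) { # 45 h
    res <- advance_cycle(pop, 0.1, cp)
    pop <- res$population
    t <- t + 0.1
    if (length(res$divide_ids) > 0) {
      divisions <- c(divisions, t)
      pop <- divide_cells(pop, res$divide_ids, cp)$population
      pop$glucose <- 5; pop$pressure <- 0
    }
  }
  expect_equal(divisions[1], 19.5, tolerance = 0.11)
  expect_equal(divisions[2], 39.0, tolerance = 0.11)
})

test_that("division conserves volume and is isotropic", {
  cp <- cycle_params()
  expect_equal((cp$r_max / cp$r_min)^3, 2, tolerance = 2e-3)

  set.seed(3)
  n <- 1000
  pop <- new_population(n, cp)
  pop$phase <- "M"
  pop$radius <- cp$r_max
  out <- divide_cells(pop, pop$id, cp)$population
  expect_equal(nrow(out), 2 * n)
  # volume conserved per mother
  vol_d <- sum(out$radius^3)
  expect_equal(vol_d, n * cp$r_max^3, tolerance = 1e-10)
  # daughter pairs are symmetric about the mother position
  d1 <- out[seq_len(n), ]; d2 <- out[n + seq_len(n), ]
  expect_equal((d1$x + d2$x) / 2, pop$x, tolerance = 1e-10)
  # division axes uniform on the sphere: chi-square over octants
  ux <- d1$x - pop$x; uy <- d1$y - pop$y; uz <- d1$z - pop$z
  oct <- 1 + (ux > 0) + 2 * (uy > 0) + 4 * (uz > 0)
  p <- stats::chisq.test(tabulate(oct, 8))$p.value
  expect_gt(p, 0.001)
  expect_true(all(out$active_time == 0))
  expect_error(divide_cells(make_population("G1"), 1), "non-mitotic")
})

test_that("dying cells dissolve on the configured timescale", {
  cp <- cycle_params()
  set.seed(5)
  pop <- make_population(rep("apoptotic", 200))
  pop$death_clock <- spheroidrt:::rtrunc_norm(200, cp$t_apoptosis,
                                              cp$sigma_rel * cp$t_apoptosis,
                                              cp$cutoff)
  removed_at <- rep(NA_real_, 200)
  t <- 0
  while (any(is.na(removed_at)) && t < 40) {
    t <- t + 0.5
    pop$death_clock <- pop$death_clock - 0.5
    gone <- pop$death_clock <= 0 & is.na(removed_at[pop$id])
    removed_at[pop$id[gone]] <- t
    pop <- pop[pop$death_clock > 0, ]
  }
  expect_equal(mean(removed_at), cp$t_apoptosis, tolerance = 0.15)

  pop2 <- make_population("necrotic")
  pop2$death_clock <- 0.01
  res <- process_death(pop2, 0.1)
  expect_equal(nrow(res$population), 0)
  expect_equal(res$n_removed, 1)
})

test_that("a free-growing population desynchronises and approaches duration-weighted occupancy", {
  cp <- cycle_params()
  set.seed(11)
  pop <- new_population(50, cp)
  pop$glucose <- 5
  pop$pressure <- 0
  ord <- c(orderedness(pop)$orderedness)
  next_id <- 51L
  for (i in seq_len(800)) { # 80 h, > 4 mean cycles
    res <- advance_cycle(pop, 0.1, cp)
    pop <- res$population
    if (length(res$divide_ids) > 0) {
      dv <- divide_cells(pop, res$divide_ids, cp, next_id)
      pop <- dv$population
      next_id <- dv$next_id
      pop$glucose <- 5; pop$pressure <- 0
    }
    if (i %% 100 == 0) ord <- c(ord, orderedness(pop)$orderedness)
  }
  # synchrony decays from 1 towards 0 over successive cycles
  expect_equal(ord[1], 1)
  expect_lt(ord[length(ord)], 0.1)
  expect_lt(min(diff(ord)), 0) # strictly loses order overall
  expect_lt(ord[length(ord)], ord[2])
  # occupancy near duration proportions (age-structure bias tolerated)
  cd <- cycle_distribution(pop)
  expect_equal(cd$frac_g1, 8 / 19.5, tolerance = 0.35)
  expect_equal(cd$spf, 6 / 19.5, tolerance = 0.35)
  expect_gt(cd$frac_g1, cd$spf) # ordering preserved
  expect_gt(cd$spf, cd$frac_m)
})
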