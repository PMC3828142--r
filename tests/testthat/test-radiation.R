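# frozen hand-evaluations of the phase-specific LQ survival at 2 Gy
S_G1_2 <- 0.422316603913344
S_S_2 <- 0.696978998466873
S_G2_2 <- 0.204742947763428
S_EXP_2 <- 0.445461181272146

test_that("LQ survival matches hand-computed values", {
  expect_equal(lq_survival(c("G1", "S", "G2", "M", "G0"), 0), rep(1, 5))
  expect_equal(lq_survival("G2", 2), S_G2_2, tolerance = 1e-12)
  expect_equal(lq_survival("M", 2), S_G2_2, tolerance = 1e-12)
  # QRF = 1.5: a quiescent cell at 3 Gy sees the G1 response at 2 Gy
  expect_equal(lq_survival("G0", 3), S_G1_2, tolerance = 1e-12)
  expect_equal(lq_survival("G0", 3), lq_survival("G1", 2), tolerance = 1e-15)
  expect_error(lq_survival("G1", -1), "non-negative")
  expect_error(lq_survival("necrotic", 2), "dead")
})

test_that("expected survival is the duration-weighted phase mixture", {
  expect_equal(expected_survival(0), 1)
  expect_equal(expected_survival(2), S_EXP_2, tolerance = 1e-12)
  doses <- seq(0, 10, 0.5)
  expect_true(all(diff(expected_survival(doses)) < 0)) # strictly decreasing
})

test_that("irradiation kills binomially at the phase-specific survival", {
  set.seed(21)
  n <- 1e5
  pop <- make_population(rep("G1", n))
  res <- irradiate(pop, 2)
  surv <- sum(is_viable(res$population) & !res$population$damaged) / n
  se <- sqrt(S_G1_2 * (1 - S_G1_2) / n)
  expect_lt(abs(surv - S_G1_2), 3 * se)
  # committed cells split acute vs damaged near p_acute
  ev <- res$events
  expect_equal(ev$n_acute / (ev$n_acute + ev$n_slow), 0.66, tolerance = 0.02)
  # dose 0 commits nothing
  res0 <- irradiate(pop, 0)
  expect_equal(res0$events$n_acute + res0$events$n_slow, 0)
  expect_identical(res0$population$phase, pop$phase)
})

test_that("virtual dosing never mutates the population", {
  set.seed(8)
  pop <- make_population(sample(c("G1", "S", "G2", "M", "G0"), 500, TRUE),
                         angles = stats::runif(500))
  before <- pop
  s1 <- observed_survival(pop, 2)
  s2 <- observed_survival(pop, 2, mode = "sampling")
  expect_identical(pop, before) # bit-identical state
  expect_gt(s1, 0); expect_lt(s1, 1)
  # sampling mode converges to the expectation with population size
  set.seed(9)
  big <- make_population(rep(c("G1", "S", "G2"), each = 2e4))
  expect_equal(observed_survival(big, 2, mode = "sampling"),
               observed_survival(big, 2), tolerance = 0.01)
  expect_error(observed_survival(make_population("necrotic"), 2), "no viable")
})

test_that("enhancement compares the population against the uniform baseline", {
  # phases populated proportionally to durations (16:12:9:2 = 8:6:4.5:1)
  pop <- make_population(rep(c("G1", "S", "G2", "M"), c(160, 120, 90, 20)))
  expect_equal(enhancement(pop, 2), 1, tolerance = 1e-12)
  # a fully quiescent population is resistant at any dose
  g0 <- make_population(rep("G0", 100))
  for (d in c(1, 2, 8)) expect_lt(enhancement(g0, d), 1)
  # a G2/M-synchronised population is strongly sensitised
  g2 <- make_population(rep("G2", 100))
  expect_equal(enhancement(g2, 2), S_EXP_2 / S_G2_2, tolerance = 1e-12)
  expect_equal(enhancement(g2, 2), 2.1757, tolerance = 1e-4)
})

test_that("attainable enhancement spread widens with dose", {
  rp <- radiation_params()
  cp <- cycle_params()
  doses <- c(1, 2, 4, 8)
  spread <- vapply(doses, function(d) {
    s <- lq_survival(c("G1", "S", "G2", "M"), d, rp)
    e_hi <- expected_survival(d, cp, rp) / min(s)
    e_lo <- expected_survival(d, cp, rp) / max(s)
    e_hi - e_lo
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("a dose produces the G2 pile-up and G1/G2 inversion", {
  cp <- cycle_params()
  rp <- radiation_params()
  set.seed(31)
  # desynchronised active population
  pop <- make_population(rep(c("G1", "S", "G2", "M"), c(800, 600, 450, 100)))
  dur <- spheroidrt:::current_phase_duration(pop)
  pop$clock <- stats::runif(nrow(pop)) * dur
  pop$active_time <- pop$clock # approximate angles
  pop$glucose <- 5; pop$pressure <- 0
  before <- cycle_distribution(pop)
  pop <- irradiate(pop, 4, cp, rp)$population
  for (i in seq_len(160)) { # 16 h of free cycling
    res <- advance_cycle(pop, 0.1, cp, rp)
    pop <- res$population
    if (length(res$divide_ids) > 0) {
      pop <- divide_cells(pop, res$divide_ids, cp)$population
    }
    pop$glucose <- 5; pop$pressure <- 0
  }
  after <- cycle_distribution(pop)
  expect_gt(after$frac_g2, before$frac_g2) # transient G2 pile-up
  expect_gt(before$frac_g1 / before$frac_g2, 1)
  expect_lt(after$frac_g1 / after$frac_g2, 1) # ratio inverted
})
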