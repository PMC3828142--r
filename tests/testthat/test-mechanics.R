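two_cell_pop <- function(d, r = 10) {
  pop <- new_population(2, cycle_params())
  pop$x <- c(0, d); pop$y <- 0; pop$z <- 0
  pop$radius <- r
  pop
}

test_that("contact graph matches geometry and a brute-force oracle", {
  expect_equal(nrow(build_contacts(two_cell_pop(30))), 0) # 30 > 20 + skin
  cg <- build_contacts(two_cell_pop(15))
  expect_equal(nrow(cg), 1)
  expect_equal(cg$overlap, 5)

  set.seed(9)
  n <- 100
  pop <- new_population(n, cycle_params())
  pop$x <- stats::runif(n, 0, 80); pop$y <- stats::runif(n, 0, 80)
  pop$z <- stats::runif(n, 0, 80)
  pop$radius <- stats::runif(n, 7.94, 10)
  skin <- 3
  cg <- build_contacts(pop, skin)
  # O(N^2) oracle
  pairs <- t(utils::combn(n, 2))
  d <- sqrt((pop$x[pairs[, 1]] - pop$x[pairs[, 2]])^2 +
              (pop$y[pairs[, 1]] - pop$y[pairs[, 2]])^2 +
              (pop$z[pairs[, 1]] - pop$z[pairs[, 2]])^2)
  hit <- d < pop$radius[pairs[, 1]] + pop$radius[pairs[, 2]] + skin
  oracle <- pairs[hit, , drop = FALSE]
  got <- as.matrix(cg[, c("i", "j")])
  expect_equal(nrow(got), nrow(oracle))
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  expect_equal(key(got), key(oracle))
})

test_that("the force law is adhesive-repulsive with a unique equilibrium", {
  mp <- mechanics_params()
  # zero at and beyond the adhesion cutoff
  expect_equal(pair_force(-mp$delta_cut, 10, 10, mp), 0)
  expect_equal(pair_force(-5, 10, 10, mp), 0)
  # adhesive at touching, repulsive for deep overlap
  expect_lt(pair_force(0, 10, 10, mp), 0)
  expect_gt(pair_force(2, 10, 10, mp), 0)
  # continuous across the cutoff and zero crossing unique
  eps <- 1e-6
  expect_equal(pair_force(-mp$delta_cut + eps, 10, 10, mp),
               pair_force(-mp$delta_cut, 10, 10, mp), tolerance = 1e-10)
  root <- stats::uniroot(function(d) pair_force(d, 10, 10, mp), c(1e-9, 5))$root
  grid <- seq(root + 1e-3, 5, length.out = 200)
  expect_true(all(pair_force(grid, 10, 10, mp) > 0)) # no second crossing
})

test_that("overdamped motion relaxes overlaps and conserves momentum", {
  mp <- mechanics_params()
  # isolated cell does not move
  pop1 <- new_population(1, cycle_params())
  out1 <- integrate_motion(pop1, 0.1, mp)
  expect_equal(c(out1$x, out1$y, out1$z), c(pop1$x, pop1$y, pop1$z))

  # two overlapping cells separate monotonically toward equilibrium
  pop <- two_cell_pop(14)
  gaps <- numeric(120)
  for (i in 1:120) {
    pop <- integrate_motion(pop, 0.02, mp)
    gaps[i] <- pop$x[2] - pop$x[1]
  }
  expect_true(all(diff(gaps) >= -1e-9))
  eq_overlap <- stats::uniroot(function(d) pair_force(d, 10, 10, mp),
                               c(1e-9, 5))$root
  expect_equal(20 - gaps[120], eq_overlap, tolerance = 0.02)

  # internal forces are momentum-free: centre of mass is invariant
  set.seed(2)
  n <- 60
  cl <- new_population(n, cycle_params())
  cl$x <- stats::runif(n, 0, 60); cl$y <- stats::runif(n, 0, 60)
  cl$z <- stats::runif(n, 0, 60)
  out <- integrate_motion(cl, 0.001, mp)
  expect_equal(mean(out$x), mean(cl$x), tolerance = 1e-9)
  expect_equal(mean(out$y), mean(cl$y), tolerance = 1e-9)
  expect_equal(mean(out$z), mean(cl$z), tolerance = 1e-9)
})

test_that("relaxation dissipates the pair-potential energy", {
  set.seed(4)
  n <- 80
  pop <- new_population(n, cycle_params())
  pop$x <- stats::runif(n, 0, 50); pop$y <- stats::runif(n, 0, 50)
  pop$z <- stats::runif(n, 0, 50)
  mp <- mechanics_params(n_sub = 1)
  e <- numeric(20)
  for (i in 1:20) {
    pop <- integrate_motion(pop, 0.005, mp)
    e[i] <- attr(pop, "energy_after")
  }
  expect_true(all(diff(e) <= 1e-18)) # static population: energy non-increasing
})

test_that("pressure is the calibrated compressive force over surface area", {
  mp <- mechanics_params()
  pop1 <- new_population(1, cycle_params())
  expect_equal(compute_pressure(pop1, mp), 0) # isolated cell

  pop <- two_cell_pop(15, r = 10) # overlap 5 um, repulsive
  f <- pair_force(5, 10, 10, mp)
  expect_gt(f, 0)
  expected <- mp$pressure_calib * f / (4 * pi * (10e-6)^2)
  expect_equal(compute_pressure(pop, mp), rep(expected, 2), tolerance = 1e-10)
  # linear in the contact forces
  mp2 <- mechanics_params(pressure_calib = 2 * mp$pressure_calib)
  expect_equal(compute_pressure(pop, mp2), 2 * compute_pressure(pop, mp))
})

test_that("a grown spheroid has a compressed core and a low-pressure rim", {
  run <- desk_spheroid()
  pop <- run$population
  d <- sqrt(pop$x^2 + pop$y^2 + pop$z^2)
  core <- pop$pressure[d < stats::quantile(d, 0.2)]
  rim <- pop$pressure[d > stats::quantile(d, 0.9)]
  expect_gt(stats::median(core), stats::median(rim))
  expect_gt(stats::median(core), cycle_params()$p_crit)
  # single connected aggregate: every cell has a neighbour within skin
  cg <- build_contacts(pop)
  expect_gt(length(unique(c(cg$i, cg$j))) / nrow(pop), 0.99)
})
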