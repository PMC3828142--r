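small_params <- function(n = 9, h = 40) {
  nutrient_params(edge_um = n * h, h_um = h, max_sweeps = 2000, tol = 1e-10)
}

test_that("a sink-free field at the medium concentration is a steady state", {
  np <- small_params()
  f <- nutrient_field("glucose", np)
  pop <- new_population(1, cycle_params())
  sinks <- collect_sinks(pop[0, ], f, np) # empty population
  expect_true(all(sinks$sink == 0))
  f2 <- step_field(f, sinks, nutrients = np)
  expect_equal(f2$conc, f$conc)
})

test_that("steady state with a point sink matches a direct linear solve", {
  np <- small_params(n = 9)
  f <- nutrient_field("glucose", np)
  n <- f$n
  occupied <- array(FALSE, dim = c(n, n, n))
  mid <- (n + 1) / 2
  occ_idx <- which(abs(slice.index(occupied, 1) - mid) <= 1 &
                     abs(slice.index(occupied, 2) - mid) <= 1 &
                     abs(slice.index(occupied, 3) - mid) <= 1)
  occupied[occ_idx] <- TRUE
  sink <- array(0, dim = c(n, n, n))
  centre <- which(slice.index(sink, 1) == mid & slice.index(sink, 2) == mid &
                    slice.index(sink, 3) == mid)
  sink[centre] <- 50 # mM/h
  f2 <- step_field(f, list(sink = sink, occupied = occupied), nutrients = np)

  # oracle: solve D lap(c) = s on the occupied voxels directly
  occ <- which(occupied)
  m <- length(occ)
  a <- matrix(0, m, m)
  b <- numeric(m)
  coord <- arrayInd(occ, dim(occupied))
  for (p in seq_len(m)) {
    a[p, p] <- -6
    for (dirn in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                      c(0, 0, 1), c(0, 0, -1))) {
      nb <- coord[p, ] + dirn
      q <- which(coord[, 1] == nb[1] & coord[, 2] == nb[2] & coord[, 3] == nb[3])
      if (length(q) == 1) a[p, q] <- 1 else b[p] <- b[p] - f$c_boundary
    }
  }
  b <- b + sink[occ] * np$h_um^2 / np$d_glucose
  oracle <- solve(a, b)
  expect_equal(as.numeric(f2$conc[occ]), oracle, tolerance = 1e-6)
})

test_that("explicit stepping conserves mass: influx minus uptake equals storage change", {
  np <- small_params(n = 7)
  f <- nutrient_field("glucose", np)
  n <- f$n
  occupied <- array(FALSE, dim = c(n, n, n)); occupied[3:5, 3:5, 3:5] <- TRUE
  sink <- array(0, dim = c(n, n, n)); sink[occupied] <- 20
  dt <- 0.5 * f$h^2 / (6 * f$d)
  res <- spheroidrt:::cpp_step_field_explicit(
    as.numeric(f$conc), as.logical(occupied), as.numeric(sink),
    n, n, n, f$d, f$h, f$c_boundary, dt)
  d_mass <- sum(res$conc[as.logical(occupied)]) -
    sum(f$conc[occupied])
  expect_equal(res$influx + (-res$uptake), d_mass, tolerance = 1e-9)
})

test_that("trilinear sampling is exact at centres and linear between them", {
  np <- small_params()
  f <- nutrient_field("glucose", np)
  n <- f$n
  f$conc[] <- seq_len(n^3) / 100
  # voxel centre (i=2, j=3, k=4 zero-based)
  x <- f$corner[1] + 2.5 * f$h
  y <- f$corner[2] + 3.5 * f$h
  z <- f$corner[3] + 4.5 * f$h
  expect_equal(concentration_at(f, x, y, z), f$conc[3, 4, 5])
  # midpoint between two voxel centres averages them
  f$conc[] <- 0; f$conc[3, 4, 5] <- 2; f$conc[4, 4, 5] <- 4
  expect_equal(concentration_at(f, x + f$h / 2, y, z), 3)
  # constant field is constant everywhere, incl. outside the grid
  f$conc[] <- 5
  pts <- seq(-1000, 1000, length.out = 17)
  expect_equal(concentration_at(f, pts, pts / 2, pts / 3), rep(5, 17))
})

test_that("sinks aggregate phase-specific uptake per voxel", {
  np <- small_params()
  f <- nutrient_field("glucose", np)
  pop <- make_population(c("G1", "S", "G0", "necrotic"))
  pop$x <- c(0, 0, 100, 0); pop$y <- 0; pop$z <- 0
  sk <- collect_sinks(pop, f, np)
  rate_mm <- np$uptake_glucose * 3600 / 1e-18 / np$h_um^3
  # G1 + S share a voxel; G0 elsewhere at its multiplier; dead contribute 0
  expect_equal(sum(sk$sink > 0), 2)
  expect_equal(sum(sk$sink),
               rate_mm * (np$phase_mult[["G1"]] + np$phase_mult[["S"]] +
                            np$phase_mult[["G0"]]),
               tolerance = 1e-12)
  expect_true(sk$occupied[which.max(sk$sink)])
})

test_that("the grown spheroid develops an inward-decreasing glucose profile", {
  run <- desk_spheroid()
  pop <- run$population
  d <- sqrt(pop$x^2 + pop$y^2 + pop$z^2)
  centre <- mean(pop$glucose[d < stats::quantile(d, 0.1)])
  rim <- mean(pop$glucose[d > stats::quantile(d, 0.9)])
  expect_lt(centre, rim)
  bins <- cut(d, breaks = stats::quantile(d, seq(0, 1, 0.25)),
              include.lowest = TRUE)
  prof <- tapply(pop$glucose, bins, mean)
  expect_true(all(diff(prof) > 0)) # monotone from core to rim
})
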