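# Shared simulation fixtures, built once per test session. Sizes follow the
# reduced "desk" profile: coarse 40 um grid, dt = 0.1 h, ~10^3-10^4 cells.
fixture_cache <- new.env(parent = emptyenv())

with_fixture <- function(name, build) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- build()
  fixture_cache[[name]]
}

# day-8 desk spheroid: compact, quiescent shell forming (~3e3 cells)
desk_spheroid <- function() {
  with_fixture("grow8", function() {
    simulate_growth(sim_config(profile = "desk", seed = 42, grow_days = 8))
  })
}

# a synthetic population with prescribed phases/angles, bypassing simulation
make_population <- function(phases, angles = NULL, cycle = cycle_params()) {
  n <- length(phases)
  pop <- new_population(n, cycle)
  pop$phase <- phases
  if (!is.null(angles)) pop$active_time <- angles * pop$cycle_length
  pop
}

single_dose_schedule <- function(dose, at_h = 0) {
  spheroidrt:::new_schedule(at_h, dose, sprintf("single %g Gy", dose))
}
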