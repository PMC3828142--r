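#' Sample per-cell phase durations
#'
#' Each duration is drawn independently from a normal distribution with the
#' phase mean and standard deviation `sigma_rel * mean`, truncated at
#' `cutoff` standard deviations by resampling, so draws lie inside
#' `mean * (1 +/- sigma_rel * cutoff)` and are strictly positive.
#'
#' @param n Number of cells to sample for.
#' @param cycle A [cycle_params()] block.
#' @return A tibble with columns `G1`, `S`, `G2`, `M` (hours).
#' @export
#' @examples
#' set.seed(1)
#' d <- sample_phase_durations(1000, cycle_params())
#' colMeans(d)
sample_phase_durations <- function(n, cycle = cycle_params()) {
  draws <- lapply(cycle$mean_durations, function(mu) {
    rtrunc_norm(n, mu, cycle$sigma_rel * mu, cycle$cutoff)
  })
  tibble::as_tibble(draws)
}

# truncated-normal sampler (resampling), bound = cutoff standard deviations
rtrunc_norm <- function(n, mean, sd, cutoff) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  lo <- mean - cutoff * sd
  hi <- mean + cutoff * sd
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Cell phase-angle
#'
#' The fraction of an individual cell's total cycle time already spent in the
#' active phases: `active_time / cycle_length`, in `[0, 1)`. Quiescent cells
#' do not accumulate active time, so their angle is frozen; the angle resets
#' to zero at division.
#'
#' @param population A population tibble.
#' @return Numeric vector of phase-angles; `NA` (with a warning) for
#'   necrotic/apoptotic cells, for which the angle is undefined.
#' @export
phase_angle <- function(population) {
  ang <- population$active_time / population$cycle_length
  dead <- population$phase %in% DEAD_PHASES
  if (any(dead)) {
    warning("phase-angle undefined for dead cells; returning NA")
    ang[dead] <- NA_real_
  }
  ang
}

# current-phase sampled duration, by phase name
current_phase_duration <- function(pop) {
  dur <- rep(NA_real_, nrow(pop))
  dur[pop$phase == "G1"] <- pop$t_g1[pop$phase == "G1"]
  dur[pop$phase == "S"] <- pop$t_s[pop$phase == "S"]
  dur[pop$phase == "G2"] <- pop$t_g2[pop$phase == "G2"]
  dur[pop$phase == "M"] <- pop$t_m[pop$phase == "M"]
  dur
}

#' Advance the cell cycle by one time step
#'
#' Implements the cycle state machine: glucose-gated necrosis commitment (any
#' phase, any time), slow death of damage-arrested cells at the G2/M
#' checkpoint, clock advancement with linear volume growth across G1 and G2,
#' the pressure-gated G1/S quiescence checkpoint (entry when the local
#' integral pressure exceeds `p_crit`; re-entry through the restriction point
#' checked every step while quiescent), the G2/M damage arrest, and completed
#' mitoses (returned as division events; see [divide_cells()]).
#'
#' @param population A population tibble whose `pressure`, `glucose` columns
#'   reflect the current environment.
#' @param dt Time step, h; must be positive and below the shortest mean phase
#'   duration.
#' @param cycle A [cycle_params()] block.
#' @param radiation A [radiation_params()] block (slow-death hazard and
#'   checkpoint-slip probability for damaged cells).
#' @return A list with `population` (advanced, divisions not yet executed) and
#'   `divide_ids` (ids of cells that completed mitosis this step).
#' @export
advance_cycle <- function(population, dt, cycle = cycle_params(),
                          radiation = radiation_params()) {
  if (dt <= 0) stop("dt must be positive")
  if (dt >= min(cycle$mean_durations)) stop("dt must be below the shortest mean phase duration")
  pop <- population

  ## glucose-gated necrosis commitment (any viable phase, any time)
  starving <- is_viable(pop) & !is.na(pop$glucose) &
    pop$glucose <= cycle$glucose_necrosis + 1e-9
  if (any(starving)) {
    n_st <- sum(starving)
    pop$phase[starving] <- "necrotic"
    pop$death_clock[starving] <- rtrunc_norm(n_st, cycle$t_necrosis,
                                             cycle$sigma_rel * cycle$t_necrosis,
                                             cycle$cutoff)
  }

  dur <- current_phase_duration(pop)
  arrested <- pop$damaged & !is.na(dur) & pop$phase %in% c("G2", "M") &
    pop$clock >= dur - 1e-12

  ## constant-hazard slow death while arrested at the G2/M checkpoint
  if (any(arrested)) {
    die <- arrested & stats::runif(nrow(pop)) < 1 - exp(-radiation$r_slow * dt)
    if (any(die)) {
      pop$phase[die] <- "apoptotic"
      pop$death_clock[die] <- rtrunc_norm(sum(die), cycle$t_apoptosis,
                                          cycle$sigma_rel * cycle$t_apoptosis,
                                          cycle$cutoff)
      arrested <- arrested & !die
    }
  }

  ## quiescence exit: restriction point, re-checked every step
  reenter <- pop$phase == "G0" & pop$pressure <= cycle$p_crit
  if (any(reenter)) {
    pop$phase[reenter] <- "S"
    pop$clock[reenter] <- 0
  }

  ## advance clocks and grow (volume linear in time across G1 + G2)
  advancing <- pop$phase %in% ACTIVE_PHASES & !arrested
  pop$clock[advancing] <- pop$clock[advancing] + dt
  pop$active_time[advancing] <- pop$active_time[advancing] + dt
  growing <- advancing & pop$phase %in% c("G1", "G2")
  if (any(growing)) {
    gf <- pmin(1, pop$grown_frac[growing] +
                 dt / (pop$t_g1[growing] + pop$t_g2[growing]))
    pop$grown_frac[growing] <- gf
    pop$radius[growing] <- pmin(cycle$r_max * 1.01,
                                pop$r_birth[growing] * (1 + gf)^(1 / 3))
  }

  ## phase transitions (dt << durations, but allow a short M to be crossed)
  divide_ids <- integer(0)
  for (pass in 1:3) {
    ph0 <- pop$phase # frozen snapshot: one transition per cell per pass
    dur <- current_phase_duration(pop)
    done <- ph0 %in% ACTIVE_PHASES & !is.na(dur) & pop$clock >= dur
    if (!any(done)) break
    carry <- pop$clock - dur

    # G1/S checkpoint: pressure-gated quiescence entry
    g1done <- done & ph0 == "G1"
    toG0 <- g1done & pop$pressure > cycle$p_crit
    toS <- g1done & !toG0
    pop$phase[toG0] <- "G0"
    pop$clock[toG0] <- 0
    # quiescent cells do not advance their phase-angle: roll back the
    # overshoot beyond the end of G1
    pop$active_time[toG0] <- pop$active_time[toG0] - carry[toG0]
    pop$phase[toS] <- "S"
    pop$clock[toS] <- carry[toS]

    sdone <- done & ph0 == "S"
    pop$phase[sdone] <- "G2"
    pop$clock[sdone] <- carry[sdone]

    # G2/M checkpoint: damaged cells are held (arrest handled above)
    g2done <- done & ph0 == "G2" & !pop$damaged
    g2hold <- done & ph0 == "G2" & pop$damaged
    if (any(g2hold)) {
      slip <- g2hold & stats::runif(nrow(pop)) < radiation$p_checkpoint_slip
      pop$clock[g2hold & !slip] <- pop$t_g2[g2hold & !slip]
      pop$active_time[g2hold & !slip] <- pop$active_time[g2hold & !slip] -
        carry[g2hold & !slip]
      # slipped cells enter mitosis but die there (mitotic catastrophe)
      if (any(slip)) {
        pop$phase[slip] <- "apoptotic"
        pop$death_clock[slip] <- rtrunc_norm(sum(slip), cycle$t_apoptosis,
                                             cycle$sigma_rel * cycle$t_apoptosis,
                                             cycle$cutoff)
      }
    }
    pop$phase[g2done] <- "M"
    pop$clock[g2done] <- carry[g2done]

    mdone <- done & ph0 == "M"
    mhold <- mdone & pop$damaged
    if (any(mhold)) { # damaged cells cannot complete mitosis
      pop$clock[mhold] <- pop$t_m[mhold]
      pop$active_time[mhold] <- pop$active_time[mhold] - carry[mhold]
    }
    divide_ids <- c(divide_ids, pop$id[mdone & !pop$damaged])
  }

  list(population = restore_population_class(pop),
       divide_ids = unique(divide_ids))
}

#' Execute cell divisions
#'
#' Each mother at the end of mitosis is replaced by two daughters of half her
#' volume, placed symmetrically about her position along a random unit axis.
#' Daughters receive freshly sampled phase durations, a zero phase-angle and
#' no inherited damage; total cell volume is conserved.
#'
#' @param population A population tibble.
#' @param ids Ids of mothers to divide (from [advance_cycle()]).
#' @param cycle A [cycle_params()] block.
#' @param next_id Smallest unused cell id.
#' @return A list with `population` and `next_id`.
#' @export
divide_cells <- function(population, ids, cycle = cycle_params(),
                         next_id = max(population$id) + 1L) {
  if (length(ids) == 0) {
    return(list(population = population, next_id = next_id))
  }
  sel <- population$id %in% ids
  mothers <- population[sel, ]
  n <- nrow(mothers)
  if (any(!mothers$phase %in% "M")) stop("division of non-mitotic cell")
  # random unit axes (uniform on the sphere)
  u <- stats::rnorm(n); v <- stats::rnorm(n); w <- stats::rnorm(n)
  nrm <- sqrt(u^2 + v^2 + w^2)
  u <- u / nrm; v <- v / nrm; w <- w / nrm
  r_d <- (mothers$radius^3 / 2)^(1 / 3) # half the mother volume
  off <- 0.5 * r_d
  mk_daughters <- function(sgn, id0) {
    dur <- sample_phase_durations(n, cycle)
    tibble::new_tibble(list(
      id = id0 + seq_len(n) - 1L,
      x = mothers$x + sgn * off * u,
      y = mothers$y + sgn * off * v,
      z = mothers$z + sgn * off * w,
      radius = r_d,
      phase = rep("G1", n),
      clock = rep(0, n),
      t_g1 = dur$G1, t_s = dur$S, t_g2 = dur$G2, t_m = dur$M,
      active_time = rep(0, n),
      cycle_length = dur$G1 + dur$S + dur$G2 + dur$M,
      grown_frac = rep(0, n),
      r_birth = r_d,
      damaged = rep(FALSE, n),
      death_clock = rep(NA_real_, n),
      pressure = mothers$pressure,
      glucose = mothers$glucose,
      oxygen = mothers$oxygen
    ), nrow = n)
  }
  d1 <- mk_daughters(1, next_id)
  d2 <- mk_daughters(-1, next_id + n)
  out <- dplyr::bind_rows(population[!sel, ], d1, d2)
  list(population = restore_population_class(out),
       next_id = next_id + 2L * n)
}

#' Process dying cells
#'
#' Decrements the death clocks of necrotic and apoptotic cells and removes
#' (dissolves) those whose clock has run out; removed cells free their space
#' and stop consuming nutrients.
#'
#' @param population A population tibble.
#' @param dt Time step, h.
#' @return A list with `population` and `n_removed`.
#' @export
process_death <- function(population, dt) {
  dead <- population$phase %in% DEAD_PHASES
  population$death_clock[dead] <- population$death_clock[dead] - dt
  gone <- dead & population$death_clock <= 0
  list(population = restore_population_class(population[!gone, ]),
       n_removed = sum(gone))
}
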