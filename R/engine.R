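init_state <- function(config) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$pop <- new_population(config$n_seeder, config$cycle)
  st$next_id <- config$n_seeder + 1L
  st$time_h <- 0
  st$f_glc <- nutrient_field("glucose", config$nutrients)
  st$f_o2 <- nutrient_field("oxygen", config$nutrients)
  st$series <- list()
  st$events <- list()
  st$births <- 0L
  st$removed <- 0L
  st$step_count <- 0L
  st$sterilised_at <- NA_real_
  st
}

state_from_run <- function(run) {
  st <- new.env(parent = emptyenv())
  for (nm in c("config", "pop", "next_id", "time_h", "f_glc", "f_o2",
               "births", "removed", "step_count", "sterilised_at")) {
    st[[nm]] <- run$state[[nm]]
  }
  st$series <- list()
  st$events <- list()
  st
}

copy_state <- function(st) {
  st2 <- new.env(parent = emptyenv())
  for (nm in ls(st)) st2[[nm]] <- st[[nm]]
  st2
}

n_clonogenic <- function(pop) sum(is_viable(pop) & !pop$damaged)

refresh_nutrients <- function(st, species = "glucose") {
  cfg <- st$config
  if (species == "glucose") {
    sk <- collect_sinks(st$pop, st$f_glc, cfg$nutrients)
    st$f_glc <- step_field(st$f_glc, sk, nutrients = cfg$nutrients)
    st$pop$glucose <- concentration_at(st$f_glc, st$pop$x, st$pop$y, st$pop$z)
  } else {
    sk <- collect_sinks(st$pop, st$f_o2, cfg$nutrients)
    st$f_o2 <- step_field(st$f_o2, sk, nutrients = cfg$nutrients)
    st$pop$oxygen <- concentration_at(st$f_o2, st$pop$x, st$pop$y, st$pop$z)
  }
  invisible(st)
}

# one operator-split step: death -> nutrients -> mechanics -> cycle -> division
engine_step <- function(st) {
  cfg <- st$config
  if (nrow(st$pop) == 0) {
    st$time_h <- st$time_h + cfg$dt
    return(invisible(st))
  }
  if (any(st$pop$phase %in% DEAD_PHASES)) {
    pd <- process_death(st$pop, cfg$dt)
    st$pop <- pd$population
    st$removed <- st$removed + pd$n_removed
  }
  if (nrow(st$pop) > 0) {
    if (st$step_count %% cfg$nutrient_every == 0L) {
      refresh_nutrients(st, "glucose")
    } else {
      st$pop$glucose <- concentration_at(st$f_glc, st$pop$x, st$pop$y, st$pop$z)
    }
    if (nrow(st$pop) > 1) {
      st$pop <- integrate_motion(st$pop, cfg$dt, cfg$mechanics, cfg$cycle$r_min)
    }
    ac <- advance_cycle(st$pop, cfg$dt, cfg$cycle, cfg$radiation)
    st$pop <- ac$population
    if (length(ac$divide_ids) > 0) {
      dv <- divide_cells(st$pop, ac$divide_ids, cfg$cycle, st$next_id)
      st$pop <- dv$population
      st$next_id <- dv$next_id
      st$births <- st$births + 2L * length(ac$divide_ids)
      st$removed <- st$removed + length(ac$divide_ids) # mothers replaced
    }
  }
  st$time_h <- st$time_h + cfg$dt
  st$step_count <- st$step_count + 1L
  invisible(st)
}

record_sample <- function(st) {
  cfg <- st$config
  pop <- st$pop
  viable <- sum(is_viable(pop))
  row <- tibble::tibble(
    time_h = st$time_h,
    n_cells = nrow(pop),
    n_viable = viable,
    n_clonogenic = n_clonogenic(pop),
    n_g1 = sum(pop$phase == "G1"), n_s = sum(pop$phase == "S"),
    n_g2 = sum(pop$phase == "G2"), n_m = sum(pop$phase == "M"),
    n_g0 = sum(pop$phase == "G0"),
    n_necrotic = sum(pop$phase == "necrotic"),
    n_apoptotic = sum(pop$phase == "apoptotic"),
    n_damaged = sum(pop$damaged & is_viable(pop)),
    quiescent_fraction = if (viable > 0) sum(pop$phase == "G0") / viable else NA_real_,
    mi = if (viable > 0) sum(pop$phase == "M") / viable else NA_real_,
    spf = if (viable > 0) sum(pop$phase == "S") / viable else NA_real_,
    orderedness = if (viable > 0) orderedness(pop)$orderedness else NA_real_,
    enhancement = if (viable > 0) {
      enhancement(pop, cfg$probe_dose, cfg$cycle, cfg$radiation)
    } else NA_real_,
    diameter_um = spheroid_geometry(pop)$diameter_um
  )
  st$series[[length(st$series) + 1L]] <- row
  row
}

finish_run <- function(st, treatment_start = NA_real_) {
  series <- dplyr::bind_rows(st$series)
  events <- if (length(st$events) > 0) dplyr::bind_rows(st$events) else
    tibble::tibble(time_h = numeric(0), dose = numeric(0),
                   n_at_risk = integer(0), n_acute = integer(0),
                   n_slow = integer(0), s_obs = numeric(0),
                   enhancement_at_delivery = numeric(0))
  structure(list(
    series = series,
    events = events,
    population = st$pop,
    config = st$config,
    time_h = st$time_h,
    treatment_start = treatment_start,
    sterilised_at = st$sterilised_at,
    rng_state = get(".Random.seed", envir = globalenv()),
    state = st
  ), class = "spheroid_run")
}

#' Grow a tumour spheroid
#'
#' Seeds `n_seeder` cells at the grid centre and advances the coupled
#' nutrient/mechanics/cycle loop for `grow_days`. Early growth is
#' exponential (doubling near the 19.5 h mean cycle time); as the spheroid
#' compacts, core pressure drives cells into quiescence and central glucose
#' depletion produces necrosis and, after dissolution, a hollow core.
#'
#' @param config A [sim_config()].
#' @return A `spheroid_run`: time-series tibble (`$series`), final population
#'   (`$population`), fraction log (`$events`, empty for growth) and the full
#'   engine state for continuation with [simulate_treatment()].
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_config(profile = "desk", seed = 1, grow_days = 2)
#' run <- simulate_growth(cfg)
#' tail(run$series)
#' }
simulate_growth <- function(config) {
  set.seed(config$seed)
  st <- init_state(config)
  refresh_nutrients(st, "glucose")
  refresh_nutrients(st, "oxygen")
  record_sample(st)
  horizon <- config$grow_days * 24
  next_sample <- config$output_every
  while (st$time_h < horizon - 1e-9) {
    engine_step(st)
    if (st$time_h >= next_sample - 1e-9) {
      refresh_nutrients(st, "oxygen")
      record_sample(st)
      next_sample <- next_sample + config$output_every
    }
    if (nrow(st$pop) == 0) break
  }
  finish_run(st)
}

deliver_fraction <- function(st, dose) {
  cfg <- st$config
  viable <- any(is_viable(st$pop))
  s_obs <- if (viable) observed_survival(st$pop, dose, cfg$radiation) else NA_real_
  e <- if (viable) {
    expected_survival(dose, cfg$cycle, cfg$radiation) / s_obs
  } else NA_real_
  irr <- irradiate(st$pop, dose, cfg$cycle, cfg$radiation)
  st$pop <- irr$population
  st$events[[length(st$events) + 1L]] <- dplyr::mutate(
    irr$events, time_h = st$time_h, s_obs = s_obs,
    enhancement_at_delivery = e, .before = 1)
  invisible(st)
}

#' Treat a grown spheroid
#'
#' Continues a [simulate_growth()] run under a fractionation schedule, an
#' automatic enhancement-triggered policy, or the non-causal "manual optimal"
#' oracle. Scheduled doses land on the first step boundary at or past their
#' scheduled time; the policy is evaluated at the output cadence on the
#' recorded enhancement trace. Sterilisation is declared when no clonogenic
#' (viable, non-death-committed) cell remains.
#'
#' @param run A `spheroid_run` to continue.
#' @param schedule An `rt_schedule` (times relative to treatment start), or
#'   `NULL` when a `policy` is used.
#' @param policy A [trigger_policy()] for online dosing, or `NULL`.
#' @param horizon_days Treatment-phase duration to simulate, days.
#' @param until_sterilised If `TRUE`, stop as soon as the tumour is
#'   sterilised (used with open-ended schedules).
#' @param policy_mode `"auto"` (causal triggering) or `"oracle"`: a shadow
#'   copy of the simulation is run forward (without dosing) to locate the
#'   true next enhancement maximum, and the dose is placed there. The oracle
#'   is non-causal and exists only as an upper benchmark for the causal
#'   policy.
#' @param lookahead_h Oracle scan horizon, h.
#' @param reseed Optional integer: reseed the RNG stream at treatment start
#'   instead of continuing the growth stream (used for replicate treatment
#'   runs from one grown state).
#' @return A `spheroid_run` for the treatment phase (series starts at
#'   treatment start; `$events` logs every delivered fraction).
#' @export
simulate_treatment <- function(run, schedule = NULL, policy = NULL,
                               horizon_days = 30, until_sterilised = FALSE,
                               policy_mode = c("auto", "oracle"),
                               lookahead_h = 36, reseed = NULL) {
  policy_mode <- match.arg(policy_mode)
  stopifnot(inherits(run, "spheroid_run"))
  assign(".Random.seed", run$rng_state, envir = globalenv())
  if (!is.null(reseed)) set.seed(reseed)
  st <- state_from_run(run)
  cfg <- st$config
  t0 <- st$time_h
  horizon <- t0 + horizon_days * 24
  sched_t <- if (!is.null(schedule)) t0 + schedule$time_h else numeric(0)
  if (length(sched_t) > 0 && any(sched_t < t0 - 1e-9)) {
    stop("schedule contains times before the current state time")
  }
  sched_d <- if (!is.null(schedule)) schedule$dose_gy else numeric(0)
  next_frac <- 1L
  delivered <- 0
  oracle_dose_at <- NA_real_
  record_sample(st)
  next_sample <- t0 + cfg$output_every
  while (st$time_h < horizon - 1e-9) {
    # scheduled fractions land on the first step boundary >= scheduled time
    while (next_frac <= length(sched_t) && sched_t[next_frac] <= st$time_h + 1e-9) {
      deliver_fraction(st, sched_d[next_frac])
      delivered <- delivered + sched_d[next_frac]
      next_frac <- next_frac + 1L
    }
    if (!is.null(policy) && policy_mode == "oracle" &&
        is.na(oracle_dose_at) && nrow(st$pop) > 0) {
      budget <- policy$rate_gy_per_h * (st$time_h - t0) - delivered
      if (budget >= policy$d_min) {
        oracle_dose_at <- oracle_peak_time(st, lookahead_h)
      }
    }
    if (!is.na(oracle_dose_at) && st$time_h >= oracle_dose_at - 1e-9) {
      dose <- policy$rate_gy_per_h * (st$time_h - t0) - delivered
      if (dose > 0) {
        deliver_fraction(st, dose)
        delivered <- delivered + dose
      }
      oracle_dose_at <- NA_real_
    }
    engine_step(st)
    if (st$time_h >= next_sample - 1e-9) {
      refresh_nutrients(st, "oxygen")
      row <- record_sample(st)
      next_sample <- next_sample + cfg$output_every
      if (!is.null(policy) && policy_mode == "auto" && !is.na(row$enhancement)) {
        hist <- dplyr::bind_rows(st$series)[, c("time_h", "enhancement")]
        dose <- auto_trigger_step(hist, st$time_h, policy, delivered, t0)
        if (dose > 0) {
          deliver_fraction(st, dose)
          delivered <- delivered + dose
        }
      }
    }
    if (is.na(st$sterilised_at) && n_clonogenic(st$pop) == 0) {
      st$sterilised_at <- st$time_h
      if (until_sterilised) break
    }
    if (nrow(st$pop) == 0) break
    if (until_sterilised && next_frac > length(sched_t) && is.null(policy) &&
        length(sched_t) > 0 && is.na(st$sterilised_at) &&
        st$time_h > max(sched_t) + 1e-9) {
      break # schedule exhausted without sterilisation
    }
  }
  record_sample(st)
  finish_run(st, treatment_start = t0)
}

# non-causal scan: copy the state, run forward without dosing, return the
# time of the maximum enhancement; the main RNG stream is left untouched
oracle_peak_time <- function(st, lookahead_h) {
  seed_keep <- get(".Random.seed", envir = globalenv())
  sh <- copy_state(st)
  sh$series <- list()
  cfg <- sh$config
  times <- numeric(0); es <- numeric(0)
  t_end <- st$time_h + lookahead_h
  next_sample <- st$time_h + cfg$output_every
  while (sh$time_h < t_end - 1e-9 && nrow(sh$pop) > 0) {
    engine_step(sh)
    if (sh$time_h >= next_sample - 1e-9) {
      if (any(is_viable(sh$pop))) {
        times <- c(times, sh$time_h)
        es <- c(es, enhancement(sh$pop, cfg$probe_dose, cfg$cycle, cfg$radiation))
      }
      next_sample <- next_sample + cfg$output_every
    }
  }
  assign(".Random.seed", seed_keep, envir = globalenv())
  if (length(es) == 0) return(st$time_h)
  times[which.max(es)]
}

#' Sweep a schedule axis
#'
#' Runs matched-seed treatments from the same grown state across a set of
#' schedule-parameter values and measures either the tumour burden over a
#' window or the number of 3 Gy fractions needed for sterilisation (repeated
#' delivery at the given inter-fraction interval until no clonogenic cell
#' remains).
#'
#' @param run A grown `spheroid_run`.
#' @param axis `"interval"` (inter-fraction interval, h, at fixed
#'   `dose_per_fraction`) or `"dose_per_fraction"` (Gy, rate-matched to
#'   `rate_gy_per_24h`).
#' @param values Axis values.
#' @param replicates Treatment replicates per value; replicate `j` uses the
#'   same derived RNG stream for every axis value (matched seeds), and the
#'   reported measures are replicate means.
#' @param measure `"sterilisation"` (fractions to sterilisation) or
#'   `"burden"` (cell-days over `burden_window_days` from treatment start).
#' @param dose_per_fraction Fraction dose for the interval axis, Gy.
#' @param rate_gy_per_24h Dose rate for the dose-per-fraction axis.
#' @param total_dose Integral dose for burden runs, Gy.
#' @param horizon_days Simulation horizon per run, days.
#' @param burden_window_days Burden integration window, days from treatment
#'   start.
#' @param max_fractions Safety cap for sterilisation runs.
#' @return A tibble with one row per axis value: fractions delivered, total
#'   dose, sterilisation flag/time and burden.
#' @export
sweep_schedule <- function(run, axis = c("interval", "dose_per_fraction"),
                           values,
                           replicates = 1,
                           measure = c("sterilisation", "burden"),
                           dose_per_fraction = 3,
                           rate_gy_per_24h = 2,
                           total_dose = 60,
                           horizon_days = 40,
                           burden_window_days = 30,
                           max_fractions = 200) {
  axis <- match.arg(axis)
  measure <- match.arg(measure)
  purrr::map_dfr(values, function(v) {
    sched <- if (axis == "interval") {
      build_constant_rate(dose_per_fraction, v,
                          if (measure == "sterilisation")
                            dose_per_fraction * max_fractions else total_dose)
    } else {
      build_constant_rate(v, v / rate_gy_per_24h * 24, total_dose)
    }
    reps <- purrr::map_dfr(seq_len(replicates), function(j) {
      tr <- simulate_treatment(run, sched,
                               horizon_days = horizon_days,
                               until_sterilised = measure == "sterilisation",
                               reseed = if (replicates > 1) 10000L + j else NULL)
      burden <- tryCatch(
        tumour_burden(tr$series, tr$treatment_start,
                      min(tr$treatment_start + burden_window_days * 24,
                          max(tr$series$time_h))),
        error = function(e) NA_real_)
      tibble::tibble(
        n_fractions = nrow(tr$events),
        total_dose = sum(tr$events$dose),
        sterilised = !is.na(tr$sterilised_at),
        sterilised_at_h = tr$sterilised_at,
        burden_cell_days = burden
      )
    })
    tibble::tibble(
      value = v,
      n_fractions = mean(reps$n_fractions),
      total_dose = mean(reps$total_dose),
      sterilised = all(reps$sterilised),
      sterilised_at_h = mean(reps$sterilised_at_h),
      burden_cell_days = mean(reps$burden_cell_days)
    )
  })
}

#' @export
print.spheroid_run <- function(x, ...) {
  cat("<spheroid_run> ", nrow(x$series), " samples to t = ",
      round(x$time_h, 1), " h; ", nrow(x$events), " fractions (",
      sum(x$events$dose), " Gy)\n", sep = "")
  last <- x$series[nrow(x$series), ]
  cat("  final: ", last$n_viable, " viable cells, quiescent fraction ",
      round(last$quiescent_fraction, 3), "\n", sep = "")
  invisible(x)
}
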