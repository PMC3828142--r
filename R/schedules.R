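new_schedule <- function(time_h, dose_gy, name, meta = list()) {
  ord <- order(time_h)
  sched <- tibble::tibble(time_h = time_h[ord], dose_gy = dose_gy[ord])
  stopifnot(all(diff(sched$time_h) > 0), all(sched$dose_gy > 0))
  attr(sched, "name") <- name
  attr(sched, "meta") <- meta
  class(sched) <- c("rt_schedule", class(sched))
  sched
}

#' @export
print.rt_schedule <- function(x, ...) {
  cat("<rt_schedule> ", attr(x, "name"), ": ", nrow(x), " fractions, ",
      sum(x$dose_gy), " Gy over ", round(max(x$time_h) / 24, 1), " days\n",
      sep = "")
  NextMethod()
}

# weekday fraction days for `n` fractions at `per_day` fractions/day,
# `days_per_week` treatment days a week
fraction_days <- function(n_days, days_per_week) {
  if (days_per_week >= 7) return(seq_len(n_days) - 1)
  out <- integer(0); w <- 0
  while (length(out) < n_days) {
    out <- c(out, 7 * w + 0:(days_per_week - 1))
    w <- w + 1
  }
  out[seq_len(n_days)]
}

#' Clinical fractionation presets
#'
#' Standard fractionation schemes: daily conventional and hypofractionated
#' courses (weekdays only or accelerated to 7 days/week), twice-daily
#' hyperfractionation (12 h spacing), CHART (1.5 Gy thrice daily at 8 h
#' spacing, no weekend gaps, 54 Gy), a split course (conventional with a
#' 14-day mid-course gap) and a concomitant boost (conventional with a second
#' daily fraction in the final week, rescaled to 60 Gy). All presets total
#' 60 Gy except CHART (54 Gy).
#'
#' @param name Preset name (see Usage).
#' @param start_day Day offset of the first fraction from treatment start.
#' @return An `rt_schedule` tibble of `(time_h, dose_gy)` with metadata
#'   attributes.
#' @export
#' @examples
#' s <- build_preset("conventional")
#' nrow(s); sum(s$dose_gy) # 30 fractions of 2 Gy, 60 Gy
build_preset <- function(name = c("conventional", "accelerated-conventional",
                                  "hypofractionated", "accelerated-hypo",
                                  "hyperfractionated", "accelerated-hyper",
                                  "CHART", "split-course", "concomitant-boost"),
                         start_day = 0) {
  name <- match.arg(name)
  spec <- switch(name,
    "conventional" = list(dose = 2, n = 30, per_day = 1, dpw = 5),
    "accelerated-conventional" = list(dose = 2, n = 30, per_day = 1, dpw = 7),
    "hypofractionated" = list(dose = 4, n = 15, per_day = 1, dpw = 5),
    "accelerated-hypo" = list(dose = 4, n = 15, per_day = 1, dpw = 7),
    "hyperfractionated" = list(dose = 1, n = 60, per_day = 2, dpw = 5),
    "accelerated-hyper" = list(dose = 1, n = 60, per_day = 2, dpw = 7),
    "CHART" = list(dose = 1.5, n = 36, per_day = 3, dpw = 7),
    NULL)
  if (name == "split-course") {
    base <- build_preset("conventional")
    # 14-day gap after the first three treatment weeks
    t <- base$time_h
    t[t >= 20 * 24] <- t[t >= 20 * 24] + 14 * 24
    return(new_schedule(t + start_day * 24, base$dose_gy, name,
                        list(total = 60, dose_per_fraction = 2)))
  }
  if (name == "concomitant-boost") {
    days <- fraction_days(25, 5) # five weekday weeks of 2 Gy
    t <- days * 24
    boost_days <- utils::tail(days, 5) # second daily fraction, final week
    t <- c(t, boost_days * 24 + 12)
    return(new_schedule(t + start_day * 24, rep(2, 30), name,
                        list(total = 60, dose_per_fraction = 2)))
  }
  spacing <- switch(as.character(spec$per_day), "1" = 0, "2" = c(0, 12),
                    "3" = c(0, 8, 16))
  n_days <- ceiling(spec$n / spec$per_day)
  days <- fraction_days(n_days, spec$dpw)
  t <- as.numeric(outer(spacing, days * 24, `+`))[seq_len(spec$n)]
  new_schedule(t + start_day * 24, rep(spec$dose, spec$n), name,
               list(total = spec$dose * spec$n, dose_per_fraction = spec$dose,
                    per_day = spec$per_day, days_per_week = spec$dpw))
}

#' Constant dose-rate schedule
#'
#' Equally spaced fractions delivering `dose_per_fraction` every `interval_h`
#' hours until `total_dose` is reached, so the dose rate
#' `dose_per_fraction / interval_h` is constant (e.g. 2 Gy/24 h and
#' 2.5 Gy/30 h are rate-matched variants).
#'
#' @param dose_per_fraction Dose per fraction, Gy.
#' @param interval_h Inter-fraction interval, h.
#' @param total_dose Integral dose, Gy.
#' @param start_day Day offset of the first fraction.
#' @return An `rt_schedule`.
#' @export
build_constant_rate <- function(dose_per_fraction, interval_h, total_dose = 60,
                                start_day = 0) {
  stopifnot(dose_per_fraction > 0, interval_h > 0, total_dose > 0)
  n_full <- floor(total_dose / dose_per_fraction + 1e-9)
  rem <- total_dose - n_full * dose_per_fraction
  doses <- rep(dose_per_fraction, n_full)
  if (rem > 1e-9) {
    warning("total dose not divisible by fraction dose; final fraction truncated to ",
            signif(rem, 3), " Gy")
    doses <- c(doses, rem)
  }
  t <- (seq_along(doses) - 1) * interval_h
  new_schedule(t + start_day * 24, doses,
               sprintf("%g Gy/%g h", dose_per_fraction, interval_h),
               list(total = total_dose, dose_per_fraction = dose_per_fraction,
                    interval_h = interval_h,
                    rate_gy_per_24h = dose_per_fraction / interval_h * 24))
}

#' Trigger/effector block schedule
#'
#' Repeating blocks of a small trigger dose followed, after a fixed lag, by a
#' larger effector dose aimed at the induced sensitivity peak; each block is
#' padded with a pause so that the overall dose rate equals `rate_gy_per_h`
#' (default 2 Gy/24 h). A 2 Gy trigger + 4 Gy effector at that rate gives a
#' 72 h block: trigger, effector after the lag, then a pause to the next
#' block.
#'
#' @param trigger_dose,effector_dose Doses, Gy.
#' @param lag_h Trigger-to-effector lag, h.
#' @param rate_gy_per_h Overall dose rate, Gy/h.
#' @param total_dose Integral dose, Gy.
#' @param start_day Day offset of the first trigger.
#' @return An `rt_schedule`.
#' @export
#' @examples
#' s <- build_triggered_block(2, 4, 12)
#' attr(s, "meta")$block_h # 72: 6 Gy per block at 2 Gy/24 h
build_triggered_block <- function(trigger_dose, effector_dose, lag_h,
                                  rate_gy_per_h = 2 / 24, total_dose = 60,
                                  start_day = 0) {
  stopifnot(trigger_dose > 0, effector_dose > 0, lag_h > 0, rate_gy_per_h > 0)
  block_dose <- trigger_dose + effector_dose
  block_h <- block_dose / rate_gy_per_h
  if (lag_h >= block_h) {
    stop("dose rate unreachable: lag exceeds the block period implied by the rate")
  }
  n_blocks <- floor(total_dose / block_dose + 1e-9)
  if (n_blocks < 1) stop("total dose below one trigger/effector block")
  rem <- total_dose - n_blocks * block_dose
  t0 <- (seq_len(n_blocks) - 1) * block_h
  t <- as.numeric(rbind(t0, t0 + lag_h))
  d <- rep(c(trigger_dose, effector_dose), n_blocks)
  if (rem > 1e-9) {
    warning("total dose not divisible by block dose; trailing ",
            signif(rem, 3), " Gy delivered as a final trigger")
    t <- c(t, n_blocks * block_h)
    d <- c(d, rem)
  }
  new_schedule(t + start_day * 24, d,
               sprintf("trigger %g + effector %g Gy @ %g h",
                       trigger_dose, effector_dose, lag_h),
               list(total = total_dose, trigger = trigger_dose,
                    effector = effector_dose, lag_h = lag_h,
                    block_h = block_h, rate_gy_per_24h = rate_gy_per_h * 24))
}

#' Enhancement-triggered dosing policy
#'
#' Parameters for online dose triggering from the enhancement trace: a peak
#' is detected either by the absence of an increasing enhancement value over
#' a trailing window (`"plateau"`) or by a non-positive fitted slope over a
#' regression window (`"regression"`). On detection the candidate dose is
#' whatever keeps delivery on the target rate
#' (`rate * elapsed - delivered`), and is delivered only if at least
#' `d_min`.
#'
#' @param window_h Trailing window, h.
#' @param d_min Minimum deliverable dose, Gy.
#' @param rate_gy_per_h Target dose rate (default 2 Gy/24 h).
#' @param mode `"plateau"` or `"regression"`.
#' @param regression_window_h Window for the regression fit, h.
#' @param plateau_tol Relative tolerance below which a sample-to-sample
#'   change does not count as an increase.
#' @return A list of class `trigger_policy`.
#' @export
trigger_policy <- function(window_h = 12, d_min = 1, rate_gy_per_h = 2 / 24,
                           mode = c("plateau", "regression"),
                           regression_window_h = 12, plateau_tol = 0.01) {
  mode <- match.arg(mode)
  stopifnot(window_h > 0, d_min > 0, rate_gy_per_h > 0,
            regression_window_h > 0, plateau_tol >= 0)
  structure(list(window_h = window_h, d_min = d_min,
                 rate_gy_per_h = rate_gy_per_h, mode = mode,
                 regression_window_h = regression_window_h,
                 plateau_tol = plateau_tol),
            class = "trigger_policy")
}

#' One decision of the automatic triggering policy
#'
#' Examines the enhancement history up to `now` and decides whether to dose.
#' Budget accounting keeps the long-run delivered dose at or below
#' `rate * elapsed`: the candidate dose is the accumulated budget, withheld
#' until it reaches `d_min` and a peak is detected.
#'
#' @param history A tibble with columns `time_h` and `enhancement`, sampled
#'   at the engine cadence up to `now`.
#' @param now Current time, h.
#' @param policy A [trigger_policy()].
#' @param delivered_so_far Total dose delivered since `treatment_start`, Gy.
#' @param treatment_start Treatment start time, h.
#' @return Dose to deliver now (Gy); `0` means no dose.
#' @export
auto_trigger_step <- function(history, now, policy, delivered_so_far = 0,
                              treatment_start = 0) {
  candidate <- policy$rate_gy_per_h * (now - treatment_start) - delivered_so_far
  if (candidate < policy$d_min) return(0)
  w <- history[history$time_h >= now - policy$window_h &
                 history$time_h <= now, ]
  if (nrow(w) < 3 || min(history$time_h) > now - policy$window_h) return(0)
  peak <- if (policy$mode == "plateau") {
    de <- diff(w$enhancement)
    tol <- policy$plateau_tol * utils::tail(w$enhancement, 1)
    !any(de > tol) # no increasing value anywhere in the window
  } else {
    r <- history[history$time_h >= now - policy$regression_window_h &
                   history$time_h <= now, ]
    if (nrow(r) < 3) return(0)
    stats::coef(stats::lm(enhancement ~ time_h, data = r))[[2]] <= 0
  }
  if (peak) candidate else 0
}
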