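#' Cell-cycle parameters
#'
#' Mean durations of the four active cycle phases, the relative spread of the
#' individually sampled phase lengths, and the checkpoint thresholds that gate
#' quiescence and necrosis.
#'
#' Phase lengths are drawn per cell and per phase from a normal distribution
#' with mean `mean_durations` and standard deviation `sigma_rel * mean`,
#' truncated (by resampling) at `cutoff` standard deviations. With the default
#' means of 8, 6, 4.5 and 1 h for G1, S, G2 and M the expected cycle time is
#' 19.5 h. An integral contact pressure above `p_crit` sends a cell arriving at
#' the G1/S checkpoint into quiescence; local glucose at or below
#' `glucose_necrosis` commits it to necrosis at any time.
#'
#' @param mean_durations Named numeric of mean phase durations in hours
#'   (G1, S, G2, M).
#' @param sigma_rel Relative standard deviation of sampled phase lengths.
#' @param cutoff Truncation bound for sampled lengths, in standard deviations.
#' @param p_crit Critical pressure for quiescence, Pa.
#' @param glucose_necrosis Glucose concentration at/below which cells necrose, mM.
#' @param t_necrosis,t_apoptosis Mean durations (h) of the necrotic and
#'   apoptotic dissolution processes.
#' @param r_min,r_max Minimum (birth) and maximum (mitotic) cell radius, um.
#'   The defaults satisfy `(r_max / r_min)^3 = 2` so volume doubles per cycle.
#' @return A list of class `cycle_params`.
#' @export
#' @examples
#' cp <- cycle_params()
#' sum(cp$mean_durations) # 19.5 h expected cycle time
cycle_params <- function(mean_durations = c(G1 = 8, S = 6, G2 = 4.5, M = 1),
                         sigma_rel = 0.3,
                         cutoff = 3,
                         p_crit = 200,
                         glucose_necrosis = 0,
                         t_necrosis = 24,
                         t_apoptosis = 12,
                         r_min = 7.94,
                         r_max = 10) {
  stopifnot(length(mean_durations) == 4, all(mean_durations > 0),
            sigma_rel >= 0, cutoff > 0, r_min > 0, r_max >= r_min,
            t_necrosis > 0, t_apoptosis > 0)
  if (sigma_rel > 0 && 1 - sigma_rel * cutoff < 0) {
    stop("truncation admits non-positive phase durations; reduce sigma_rel or cutoff")
  }
  names(mean_durations) <- c("G1", "S", "G2", "M")
  structure(list(mean_durations = mean_durations, sigma_rel = sigma_rel,
                 cutoff = cutoff, p_crit = p_crit,
                 glucose_necrosis = glucose_necrosis,
                 t_necrosis = t_necrosis, t_apoptosis = t_apoptosis,
                 r_min = r_min, r_max = r_max),
            class = "cycle_params")
}

#' Cell-mechanics parameters
#'
#' Adhesive-repulsive pairwise interaction (extended Hertz repulsion with a
#' finite adhesive well) plus overdamped motion. Forces are evaluated in SI
#' units from micrometre geometry so that the per-cell contact pressure comes
#' out in pascals, comparable with the 200 Pa quiescence threshold.
#'
#' @param e_pair Effective pair elastic modulus, Pa.
#' @param w_adh Adhesion energy per area, N/m.
#' @param delta_cut Adhesive range beyond touching, um.
#' @param f_clamp Repulsive force clamp for deep overlaps, N.
#' @param gamma Drag coefficient, N s/m.
#' @param skin Contact-detection margin beyond radii sum, um.
#' @param n_sub Relaxation substeps per engine step.
#' @param cap_frac Displacement cap per substep, as a fraction of `r_min`.
#' @param pressure_calib Dimensionless calibration factor applied to the
#'   compressive-force/area pressure before comparison with `p_crit`
#'   (the integral pressure of the growth model is defined only up to the
#'   contact-area model; this factor is fixed by matching quiescence onset
#'   during spheroid growth).
#' @return A list of class `mechanics_params`.
#' @export
mechanics_params <- function(e_pair = 2500,
                             w_adh = 1e-4,
                             delta_cut = 2,
                             f_clamp = 5e-7,
                             gamma = 10,
                             skin = 3,
                             n_sub = 2,
                             cap_frac = 0.3,
                             pressure_calib = 25) {
  stopifnot(e_pair > 0, w_adh >= 0, delta_cut > 0, gamma > 0, skin >= 0,
            n_sub >= 1, cap_frac > 0, pressure_calib > 0)
  structure(list(e_pair = e_pair, w_adh = w_adh, delta_cut = delta_cut,
                 f_clamp = f_clamp, gamma = gamma, skin = skin,
                 n_sub = as.integer(n_sub), cap_frac = cap_frac,
                 pressure_calib = pressure_calib),
            class = "mechanics_params")
}

#' Radiation-response parameters
#'
#' Phase-specific linear-quadratic survival, the quiescence resistance factor,
#' and the fast/slow death-path split. Survival after a dose D is
#' `exp(-(alpha * D_eff + beta * D_eff^2))` with `D_eff = D` for active phases
#' and `D / qrf` for quiescent cells (which otherwise use the G1 coefficients).
#' Non-surviving cells die acutely (probability `p_acute`, apoptosis of mean
#' duration `t_acute`) or carry damage to the G2/M checkpoint, where they are
#' arrested and convert to apoptosis with constant hazard `r_slow`.
#'
#' @param alpha,beta Named numerics (G1, S, G2, M) of LQ coefficients in
#'   1/Gy and 1/Gy^2. Defaults are phase-resolved V79 x-ray measurements:
#'   G1 (0.351, 0.04), S (0.1235, 0.0285), G2 = M (0.793, 0).
#' @param qrf Quiescence resistance factor (dose divisor for G0 cells).
#' @param p_acute Probability that a committed cell takes the acute path.
#' @param r_slow Hazard (1/h) of death while arrested at G2/M.
#' @param t_acute Mean acute-death duration, h.
#' @param p_checkpoint_slip Probability that a damaged cell slips through the
#'   G2/M arrest into mitosis (then dies of mitotic catastrophe); default 0.
#' @return A list of class `radiation_params`.
#' @export
#' @examples
#' rp <- radiation_params()
#' exp(-(rp$alpha[["G2"]] * 2)) # G2 survival at 2 Gy, ~0.205
radiation_params <- function(alpha = c(G1 = 0.351, S = 0.1235, G2 = 0.793, M = 0.793),
                             beta = c(G1 = 0.04, S = 0.0285, G2 = 0, M = 0),
                             qrf = 1.5,
                             p_acute = 0.66,
                             r_slow = 0.05,
                             t_acute = 12,
                             p_checkpoint_slip = 0) {
  stopifnot(length(alpha) == 4, length(beta) == 4,
            all(alpha >= 0), all(beta >= 0), qrf >= 1,
            p_acute >= 0, p_acute <= 1, r_slow > 0, t_acute > 0,
            p_checkpoint_slip >= 0, p_checkpoint_slip <= 1)
  names(alpha) <- names(beta) <- c("G1", "S", "G2", "M")
  structure(list(alpha = alpha, beta = beta, qrf = qrf, p_acute = p_acute,
                 r_slow = r_slow, t_acute = t_acute,
                 p_checkpoint_slip = p_checkpoint_slip),
            class = "radiation_params")
}

#' Nutrient-field and uptake parameters
#'
#' Glucose and oxygen are solved on a cubic grid of edge `edge_um` as
#' quasi-steady reaction-diffusion fields with the cells as phase-specific
#' sinks; voxels not occupied by cells are held at the medium concentration.
#' Diffusivities and uptake magnitudes are calibrated (they are not printed
#' model constants) such that a spheroid of roughly 700 um diameter depletes
#' glucose centrally and develops a necrotic core.
#'
#' @param edge_um Grid edge length, um.
#' @param h_um Voxel spacing, um.
#' @param c_glucose,c_oxygen Medium concentrations, mM.
#' @param d_glucose,d_oxygen Diffusion coefficients, um^2/h.
#' @param uptake_glucose,uptake_oxygen Baseline uptake per cell, mol/(cell s).
#' @param phase_mult Named per-phase multipliers on the baseline uptake
#'   (G1, S, G2, M, G0); dead cells consume nothing.
#' @param max_sweeps,tol Gauss-Seidel iteration cap and convergence tolerance
#'   for the quasi-steady solve.
#' @return A list of class `nutrient_params`.
#' @export
nutrient_params <- function(edge_um = 1400,
                            h_um = 20,
                            c_glucose = 5,
                            c_oxygen = 0.13,
                            d_glucose = 1.1e-6 * 1e8 * 3600,
                            d_oxygen = 1.8e-5 * 1e8 * 3600,
                            uptake_glucose = 2.8e-16,
                            uptake_oxygen = 3.0e-17,
                            phase_mult = c(G1 = 1, S = 1.3, G2 = 1, M = 0.6, G0 = 0.5),
                            max_sweeps = 400,
                            tol = 1e-4) {
  stopifnot(edge_um > 0, h_um > 0, c_glucose >= 0, c_oxygen >= 0,
            d_glucose > 0, d_oxygen > 0, uptake_glucose >= 0,
            uptake_oxygen >= 0, all(phase_mult >= 0))
  names(phase_mult) <- c("G1", "S", "G2", "M", "G0")
  n_vox <- as.integer(round(edge_um / h_um))
  structure(list(edge_um = edge_um, h_um = h_um, n_vox = n_vox,
                 c_glucose = c_glucose, c_oxygen = c_oxygen,
                 d_glucose = d_glucose, d_oxygen = d_oxygen,
                 uptake_glucose = uptake_glucose, uptake_oxygen = uptake_oxygen,
                 phase_mult = phase_mult, max_sweeps = as.integer(max_sweeps),
                 tol = tol),
            class = "nutrient_params")
}

#' Simulation configuration
#'
#' Bundles all module parameter blocks with the run controls: time step,
#' growth horizon, number of seeder cells, output cadence, the probe dose used
#' for the enhancement observable and the master seed. Two profiles are
#' provided: `"full"` reproduces the 14-day, ~700 um spheroid regime on the
#' 1.4 mm / 20 um grid, while `"desk"` is a reduced-scale profile (coarser
#' grid, shorter growth, a few thousand cells) suitable for interactive work
#' and continuous testing.
#'
#' @param profile `"desk"` or `"full"`; chooses scale defaults which explicit
#'   arguments then override.
#' @param seed Master RNG seed; every stochastic draw in a run derives from it.
#' @param dt Engine time step, h.
#' @param grow_days Growth horizon before treatment, days.
#' @param n_seeder Number of seeder cells.
#' @param output_every Observable sampling cadence, h.
#' @param nutrient_every Steps between quasi-steady nutrient re-solves (the
#'   glucose landscape evolves on the hours timescale, so a small stride
#'   changes trajectories negligibly while saving substantial time).
#' @param probe_dose Virtual dose (Gy) at which enhancement is recorded.
#' @param cycle,mechanics,radiation,nutrients Module parameter blocks.
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(profile = "desk", seed = 1)
sim_config <- function(profile = c("desk", "full"),
                       seed = 1L,
                       dt = NULL,
                       grow_days = NULL,
                       n_seeder = 10,
                       output_every = 2,
                       nutrient_every = NULL,
                       probe_dose = 2,
                       cycle = cycle_params(),
                       mechanics = mechanics_params(),
                       radiation = radiation_params(),
                       nutrients = NULL) {
  profile <- match.arg(profile)
  if (is.null(dt)) dt <- if (profile == "desk") 0.1 else 0.05
  if (is.null(grow_days)) grow_days <- if (profile == "desk") 9 else 14
  if (is.null(nutrient_every)) nutrient_every <- if (profile == "desk") 3L else 5L
  if (is.null(nutrients)) {
    nutrients <- if (profile == "desk") {
      nutrient_params(edge_um = 1400, h_um = 40, max_sweeps = 200)
    } else {
      nutrient_params()
    }
  }
  stopifnot(dt > 0, dt < min(cycle$mean_durations), grow_days >= 0,
            n_seeder >= 1, output_every > 0, probe_dose >= 0)
  structure(list(profile = profile, seed = as.integer(seed), dt = dt,
                 grow_days = grow_days, n_seeder = as.integer(n_seeder),
                 output_every = output_every,
                 nutrient_every = as.integer(nutrient_every),
                 probe_dose = probe_dose,
                 cycle = cycle, mechanics = mechanics, radiation = radiation,
                 nutrients = nutrients),
            class = "sim_config")
}
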