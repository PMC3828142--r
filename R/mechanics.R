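#' Build the cell contact graph
#'
#' Symmetric neighbour list from a spatial binning search: two cells are in
#' contact when their centre distance is below `R_i + R_j + skin`. The
#' recorded overlap `R_i + R_j - d` may be negative inside the skin.
#'
#' @param population A population tibble (positions/radii in um).
#' @param skin Detection margin, um.
#' @return A tibble with columns `i`, `j` (row indices, `i < j`), `overlap`
#'   and `dist` (um).
#' @export
#' @examples
#' pop <- new_population(5, cycle_params())
#' build_contacts(pop)
build_contacts <- function(population, skin = mechanics_params()$skin) {
  stopifnot(all(is.finite(population$x)), all(is.finite(population$y)),
            all(is.finite(population$z)))
  cg <- cpp_build_contacts(population$x, population$y, population$z,
                           population$radius, skin)
  tibble::tibble(i = cg$i, j = cg$j, overlap = cg$overlap, dist = cg$dist)
}

#' Pairwise contact force
#'
#' Signed scalar force along the centre line as a function of overlap:
#' extended-Hertz repulsion (positive, pushing apart) for interpenetrating
#' cells, a finite adhesive well (negative) over a range `delta_cut` beyond
#' touching, zero past the cutoff, continuous throughout, and clamped at
#' `f_clamp` for deep overlaps.
#'
#' @param overlap Overlap `R_i + R_j - d`, um (may be negative).
#' @param r_i,r_j Cell radii, um.
#' @param mechanics A [mechanics_params()] block.
#' @return Force in newtons, positive = repulsive.
#' @export
pair_force <- function(overlap, r_i, r_j, mechanics = mechanics_params()) {
  n <- max(length(overlap), length(r_i), length(r_j))
  cpp_pair_force(rep_len(overlap, n), rep_len(r_i, n), rep_len(r_j, n),
                 mechanics$e_pair, mechanics$w_adh, mechanics$delta_cut,
                 mechanics$f_clamp)
}

#' Relax cell positions by overdamped dynamics
#'
#' Advances positions by `dx/dt = F_net / gamma` over `dt` (split into
#' `n_sub` substeps with the contact graph rebuilt each substep), with the
#' displacement per substep capped at `cap_frac * r_min`. Also computes each
#' cell's integral pressure: the calibrated sum of compressive normal contact
#' forces over the cell surface area, in Pa — zero for isolated cells.
#'
#' @param population A population tibble.
#' @param dt Time step, h.
#' @param mechanics A [mechanics_params()] block.
#' @param r_min Minimum cell radius (displacement cap reference), um.
#' @return The population with updated `x`, `y`, `z`, `pressure`, carrying
#'   attributes `energy_before`, `energy_after` (pair-potential, J) and
#'   `n_capped`.
#' @export
integrate_motion <- function(population, dt, mechanics = mechanics_params(),
                             r_min = cycle_params()$r_min) {
  res <- cpp_mech_step(population$x, population$y, population$z,
                       population$radius, mechanics$skin, mechanics$e_pair,
                       mechanics$w_adh, mechanics$delta_cut, mechanics$f_clamp,
                       mechanics$gamma, dt, mechanics$n_sub,
                       mechanics$cap_frac, r_min, mechanics$pressure_calib)
  population$x <- res$x
  population$y <- res$y
  population$z <- res$z
  population$pressure <- res$pressure
  attr(population, "energy_before") <- res$energy_before
  attr(population, "energy_after") <- res$energy_after
  attr(population, "n_capped") <- res$n_capped
  if (res$n_capped > 0.5 * nrow(population) * mechanics$n_sub) {
    warning("displacement cap triggered for most cells; step may be unstable")
  }
  population
}

#' Per-cell contact pressure
#'
#' Calibrated sum of compressive (repulsive) normal contact-force magnitudes
#' divided by the cell surface area. Computed without moving any cell.
#'
#' @inheritParams integrate_motion
#' @return Numeric vector of pressures, Pa.
#' @export
compute_pressure <- function(population, mechanics = mechanics_params()) {
  res <- cpp_mech_step(population$x, population$y, population$z,
                       population$radius, mechanics$skin, mechanics$e_pair,
                       mechanics$w_adh, mechanics$delta_cut, mechanics$f_clamp,
                       mechanics$gamma, 0, 1, mechanics$cap_frac, 1,
                       mechanics$pressure_calib)
  res$pressure
}
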