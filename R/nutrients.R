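#' Create a nutrient field
#'
#' A cubic concentration grid for one species, initialised at the medium
#' concentration. Voxel centres sit at `corner + (i + 1/2) * h` (0-based
#' indices); the grid is centred on the origin, where spheroids are seeded.
#'
#' @param species `"glucose"` or `"oxygen"`.
#' @param nutrients A [nutrient_params()] block.
#' @return A list of class `nutrient_field` with the concentration array
#'   (mM), grid geometry and species bookkeeping.
#' @export
#' @examples
#' f <- nutrient_field("glucose", nutrient_params(edge_um = 200, h_um = 40))
#' dim(f$conc)
nutrient_field <- function(species = c("glucose", "oxygen"),
                           nutrients = nutrient_params()) {
  species <- match.arg(species)
  n <- nutrients$n_vox
  c_b <- if (species == "glucose") nutrients$c_glucose else nutrients$c_oxygen
  d <- if (species == "glucose") nutrients$d_glucose else nutrients$d_oxygen
  structure(list(
    species = species,
    conc = array(c_b, dim = c(n, n, n)),
    n = n, h = nutrients$h_um,
    corner = rep(-nutrients$edge_um / 2, 3),
    c_boundary = c_b, d = d,
    starved = array(FALSE, dim = c(n, n, n))
  ), class = "nutrient_field")
}

# per-cell uptake in mM * um^3 / h (from mol/(cell s)); 1 mM = 1e-18 mol/um^3
uptake_rate_per_cell <- function(pop, species, nutrients) {
  base <- if (species == "glucose") nutrients$uptake_glucose else nutrients$uptake_oxygen
  base_mm <- base * 3600 / 1e-18
  mult <- rep(0, nrow(pop))
  for (ph in names(nutrients$phase_mult)) {
    mult[pop$phase == ph] <- nutrients$phase_mult[[ph]]
  }
  base_mm * mult # zero for necrotic/apoptotic cells
}

#' Collect per-voxel sink terms
#'
#' Maps each viable cell to its voxel and accumulates its phase-specific
#' uptake; quiescent cells consume at the `G0` multiplier and dead cells
#' consume nothing.
#'
#' @param population A population tibble.
#' @param field A [nutrient_field()].
#' @param nutrients A [nutrient_params()] block.
#' @return A list with `sink` (array, mM/h per voxel) and `occupied`
#'   (logical array: the tissue region that is solved rather than held at the
#'   medium concentration — voxels containing any cell, dead included, plus
#'   the interstitial and cavity voxels inside the spheroid envelope, which
#'   are diffusion-only and must not act as medium reservoirs).
#' @export
collect_sinks <- function(population, field, nutrients = nutrient_params()) {
  n <- field$n
  sink <- numeric(n^3)
  occupied <- logical(n^3)
  if (nrow(population) > 0) {
    vox <- cpp_voxel_of(population$x, population$y, population$z,
                        n, n, n, field$h,
                        field$corner[1], field$corner[2], field$corner[3])
    inside <- vox > 0
    occupied[vox[inside]] <- TRUE
    rate <- uptake_rate_per_cell(population, field$species, nutrients)
    acc <- rowsum(rate[inside], vox[inside])
    sink[as.integer(rownames(acc))] <- acc[, 1] / field$h^3
    # tissue envelope: interior gaps and the (hollow) core diffuse but are
    # not perfused, so they belong to the solved region too
    cx <- mean(population$x); cy <- mean(population$y); cz <- mean(population$z)
    d <- sqrt((population$x - cx)^2 + (population$y - cy)^2 +
                (population$z - cz)^2)
    r_tissue <- stats::quantile(d, 0.95, names = FALSE) +
      mean(population$radius)
    ax <- field$corner[1] + (seq_len(n) - 0.5) * field$h
    d2 <- outer(outer((ax - cx)^2, (ax - cy)^2, `+`), (ax - cz)^2, `+`)
    occupied[d2 <= r_tissue^2] <- TRUE
  }
  list(sink = array(sink, dim = c(n, n, n)),
       occupied = array(occupied, dim = c(n, n, n)))
}

#' Advance a nutrient field
#'
#' Solves the reaction-diffusion balance `dc/dt = D lap(c) - sinks` with
#' cell-free voxels (and everything beyond the grid) held at the medium
#' concentration. The default quasi-steady mode relaxes the field to the
#' steady state of the current sink configuration (nutrient diffusion is fast
#' relative to cycle timescales), warm-started from the passed field; the
#' explicit mode takes forward-Euler steps of `dt` and enforces the stability
#' bound. Concentrations are clamped at zero and clamped voxels are flagged
#' as starved.
#'
#' @param field A [nutrient_field()].
#' @param sinks Result of [collect_sinks()].
#' @param dt Time interval, h (explicit mode only).
#' @param nutrients A [nutrient_params()] block.
#' @param mode `"steady"` or `"explicit"`.
#' @return The updated field.
#' @export
step_field <- function(field, sinks, dt = NULL,
                       nutrients = nutrient_params(),
                       mode = c("steady", "explicit")) {
  mode <- match.arg(mode)
  n <- field$n
  if (mode == "steady") {
    res <- cpp_relax_field(as.numeric(field$conc), as.logical(sinks$occupied),
                           as.numeric(sinks$sink), n, n, n, field$d, field$h,
                           field$c_boundary, nutrients$max_sweeps, nutrients$tol)
    if (res$sweeps >= nutrients$max_sweeps && res$residual > 100 * nutrients$tol) {
      stop("nutrient solve failed to converge (residual ", signif(res$residual, 3), ")")
    }
    field$conc <- array(res$conc, dim = c(n, n, n))
    field$starved <- array(res$starved, dim = c(n, n, n))
  } else {
    if (is.null(dt)) stop("explicit mode needs dt")
    dt_stab <- field$h^2 / (6 * field$d)
    nsub <- max(1L, ceiling(dt / dt_stab))
    conc <- as.numeric(field$conc)
    for (k in seq_len(nsub)) {
      res <- cpp_step_field_explicit(conc, as.logical(sinks$occupied),
                                     as.numeric(sinks$sink), n, n, n,
                                     field$d, field$h, field$c_boundary,
                                     dt / nsub)
      conc <- res$conc
    }
    field$conc <- array(conc, dim = c(n, n, n))
    field$starved <- array(conc <= 0 & as.logical(sinks$occupied),
                           dim = c(n, n, n))
  }
  field
}

#' Sample a nutrient field at positions
#'
#' Trilinear interpolation between voxel centres; exact at centres, clamped
#' at the grid faces, and returning the medium concentration outside the grid.
#'
#' @param field A [nutrient_field()].
#' @param x,y,z Coordinates, um.
#' @return Non-negative concentrations, mM.
#' @export
concentration_at <- function(field, x, y, z) {
  cpp_trilinear(as.numeric(field$conc), field$n, field$n, field$n, field$h,
                field$corner[1], field$corner[2], field$corner[3],
                x, y, z, field$c_boundary)
}

#' Flatten a nutrient field to a voxel table
#'
#' @param field A [nutrient_field()].
#' @return A tibble with 0-based voxel indices `i`, `j`, `k`, voxel-centre
#'   coordinates (um) and concentration (mM).
#' @export
field_to_table <- function(field) {
  n <- field$n
  g <- expand.grid(i = 0:(n - 1), j = 0:(n - 1), k = 0:(n - 1))
  tibble::tibble(
    i = g$i, j = g$j, k = g$k,
    x = field$corner[1] + (g$i + 0.5) * field$h,
    y = field$corner[2] + (g$j + 0.5) * field$h,
    z = field$corner[3] + (g$k + 0.5) * field$h,
    conc = as.numeric(field$conc)
  )
}
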