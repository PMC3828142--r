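#' Tidy a simulation run
#'
#' Returns the observables time series as a tibble, one row per sample time:
#' counts by state, quiescent fraction, MI, SPF, orderedness, the enhancement
#' at the probe dose and the spheroid diameter.
#'
#' @param x A `spheroid_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.spheroid_run <- function(x, ...) {
  x$series
}

#' Summarise a simulation run
#'
#' @param x A `spheroid_run`.
#' @param ... Unused.
#' @return A one-row tibble: horizon, final composition, fractions and dose
#'   delivered, burden over the run, sterilisation status.
#' @export
glance.spheroid_run <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  burden <- tryCatch(tumour_burden(x$series), error = function(e) NA_real_)
  tibble::tibble(
    time_h = x$time_h,
    n_cells = last$n_cells,
    n_viable = last$n_viable,
    quiescent_fraction = last$quiescent_fraction,
    diameter_um = last$diameter_um,
    n_fractions = nrow(x$events),
    total_dose_gy = sum(x$events$dose),
    burden_cell_days = burden,
    sterilised = !is.na(x$sterilised_at)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot a simulation run
#'
#' Faceted time courses of the viable cell count, the cycle composition
#' (quiescent fraction, MI, SPF), the orderedness and the enhancement at the
#' probe dose; delivered fractions are marked on the enhancement panel.
#'
#' @param object A `spheroid_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spheroid_run <- function(object, ...) {
  s <- object$series
  long <- tidyr::pivot_longer(
    s[, c("time_h", "n_viable", "quiescent_fraction", "mi", "spf",
          "orderedness", "enhancement")],
    -"time_h", names_to = "observable", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_h / 24, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time [days]", y = NULL)
  if (nrow(object$events) > 0) {
    p <- p + ggplot2::geom_vline(
      data = tibble::tibble(time_h = object$events$time_h,
                            observable = "enhancement"),
      ggplot2::aes(xintercept = .data$time_h / 24),
      linetype = 3, colour = "grey50")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fractionation schedule
#'
#' Stem plot of fraction times and doses.
#'
#' @param object An `rt_schedule`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rt_schedule <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_h / 24, .data$dose_gy)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$time_h / 24, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time from treatment start [days]", y = "dose [Gy]",
                  title = attr(object, "name"))
}

#' Plot a lateral section of the spheroid
#'
#' Cells within a slab around the mid-plane, coloured by state — the model's
#' counterpart of a histological cut: proliferating rim, quiescent layer and
#' the necrotic/hollow core.
#'
#' @param population A population tibble.
#' @param slab_um Slab half-thickness, um.
#' @return A ggplot object.
#' @export
plot_section <- function(population, slab_um = 15) {
  cz <- stats::median(population$z)
  cut <- population[abs(population$z - cz) <= slab_um, ]
  ggplot2::ggplot(cut, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$radius,
                                     colour = .data$phase), alpha = 0.8) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [um]", y = "y [um]")
}
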