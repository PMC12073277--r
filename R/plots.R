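# ggplot2 graphics for fits and trajectory observables.

#' Plot a recovery fit
#'
#' Measured amplitudes (points) with the fitted recovery curve on a
#' logarithmic delay axis.
#'
#' @param object A `recovery_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.recovery_fit <- function(object, ...) {
  grid <- tibble(
    delay_s = exp(seq(log(min(object$data$delay_s)),
                      log(max(object$data$delay_s)), length.out = 200))
  )
  grid$amplitude <- recovery_model(grid$delay_s, object$m0,
                                   object$t1, object$fractions)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$delay_s, y = .data$amplitude)) +
    ggplot2::geom_point(size = 1.2, alpha = 0.8) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "recovery delay (s)", y = "magnetization (a.u.)",
                  title = sprintf("%d-component recovery fit", object$n_components))
}

#' Plot an FID decomposition
#'
#' @param object An `fid_fit`.
#' @param ... Unused.
#' @return A ggplot with the total fit and the rigid/mobile components.
#' @export
autoplot.fid_fit <- function(object, ...) {
  t <- seq(min(object$data$time_us), max(object$data$time_us), length.out = 300)
  comp <- dplyr::bind_rows(
    tibble(time_us = t, amplitude = fid_model(t, object$m0, object$gaussian_fraction,
                                              object$t2_gauss, object$t2_exp),
           part = "total"),
    tibble(time_us = t,
           amplitude = object$m0 * object$gaussian_fraction *
             exp(-t^2 / (2 * object$t2_gauss^2)),
           part = "rigid (Gaussian)"),
    tibble(time_us = t,
           amplitude = object$m0 * (1 - object$gaussian_fraction) *
             exp(-t / object$t2_exp),
           part = "mobile (exponential)")
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_us, y = .data$amplitude)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = comp, ggplot2::aes(colour = .data$part)) +
    ggplot2::labs(x = "time (µs)", y = "FID amplitude (a.u.)", colour = NULL)
}

#' Plot a BPP fit
#'
#' T1 against reciprocal temperature (1000/T) on a logarithmic T1 axis, with
#' the fitted multi-process model.
#'
#' @param object A `bpp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bpp_fit <- function(object, ...) {
  dat <- object$data
  tgrid <- seq(min(dat$temperature_K), max(dat$temperature_K), length.out = 300)
  omega0 <- 2 * pi * object$larmor_frequency
  bppproc <- object$processes[object$processes$mode == "bpp", , drop = FALSE]
  fitline <- NULL
  if (nrow(bppproc) == nrow(object$processes)) {
    fitline <- tibble(temperature_K = tgrid,
                      t1_s = t1_model(tgrid, bppproc, omega0))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = 1000 / .data$temperature_K,
                                         y = .data$t1_s)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "1000 / T (1/K)", y = expression(T[1] ~ "(s)"))
  if (!is.null(fitline)) {
    p <- p + ggplot2::geom_line(
      data = fitline,
      ggplot2::aes(x = 1000 / .data$temperature_K, y = .data$t1_s),
      colour = "firebrick"
    )
  }
  p
}

#' Plot a pair distribution function
#'
#' @param rdf A [pair_distribution()] result.
#' @return A ggplot of g(r).
#' @export
plot_rdf <- function(rdf) {
  ggplot2::ggplot(rdf, ggplot2::aes(x = .data$r, y = .data$g)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "r (Å)", y = "g(r)")
}

#' Plot an orientational distribution
#'
#' @param odf An [orientation_distribution()] result.
#' @return A ggplot of P(theta).
#' @export
plot_orientation <- function(odf) {
  ggplot2::ggplot(odf, ggplot2::aes(x = .data$angle_deg, y = .data$p)) +
    ggplot2::geom_col(width = diff(odf$angle_deg[1:2]) * 0.95) +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 60)) +
    ggplot2::labs(x = expression(Theta ~ "(degrees)"), y = expression(P(Theta)))
}

#' Plot an angular correlation function
#'
#' @param acf An [angular_correlation()] result.
#' @return A ggplot of the ACF vs lag with the fitted exponential, if any.
#' @export
plot_acf <- function(acf) {
  p <- ggplot2::ggplot(acf, ggplot2::aes(x = .data$lag_ns, y = .data$acf)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "lag (ns)", y = "ACF")
  tau <- attr(acf, "tau_ns")
  if (!is.null(tau) && is.finite(tau)) {
    fitline <- tibble(lag_ns = acf$lag_ns, acf = exp(-acf$lag_ns / tau))
    p <- p + ggplot2::geom_line(data = fitline, colour = "firebrick")
  }
  p
}

#' Plot a hydrogen-bond census
#'
#' @param census A [hb_count_distribution()] result.
#' @return A ggplot bar chart of the percentage of molecules per bond count.
#' @export
plot_census <- function(census) {
  ggplot2::ggplot(census, ggplot2::aes(x = .data$n_hb, y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "hydrogen bonds per molecule", y = "% of molecules")
}
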