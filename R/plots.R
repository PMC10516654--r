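#' Plot a coverage track with called peaks
#'
#' @param object A `coverage_track`.
#' @param peaks Optional `mrpr_peaks` to annotate summits.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_track <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos, y = .data$coverage)) +
    ggplot2::geom_step(linewidth = 0.2, colour = "grey30") +
    ggplot2::facet_wrap(~replicate, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "position (bp)", y = "coverage (reads)") +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_vline(data = peaks,
                                 ggplot2::aes(xintercept = .data$summit),
                                 colour = "firebrick", linetype = 2,
                                 linewidth = 0.3)
  }
  p
}

#' Sequence-logo style plot of a PWM
#'
#' Per-column information content split across bases (bar version of the
#' usual logo).
#'
#' @param object An `mrpr_pwm`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mrpr_pwm <- function(object, ...) {
  df <- tidy(object)
  ic <- dplyr::mutate(
    dplyr::group_by(df, .data$position),
    info = sum(.data$prob * log2(.data$prob / 0.25)),
    height = .data$prob * .data$info
  )
  ggplot2::ggplot(ic, ggplot2::aes(x = .data$position, y = .data$height,
                                   fill = .data$base)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::labs(x = "motif position", y = "information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot residue-level uptake profiles
#'
#' @param object An `hdx_residues` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hdx_residues <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$uptake,
                                       colour = factor(.data$timepoint))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "deuterium uptake (Da)",
                  colour = "time (s)") +
    ggplot2::theme_minimal()
}

#' Plot an ITC fit (observed vs model heats)
#'
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.itc_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$heat)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "molar ratio (titrant/macromolecule)",
                  y = "heat per injection (µcal)") +
    ggplot2::theme_minimal()
}

#' Plot a Boltzmann melt-curve fit
#'
#' @param object A `dsf_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dsf_fit <- function(object, ...) {
  df <- object$data
  df$fitted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$ratio), size = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$params$tm, linetype = 2) +
    ggplot2::labs(x = "temperature (°C)", y = "F350/F330 ratio") +
    ggplot2::theme_minimal()
}
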