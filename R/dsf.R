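#' Simulate a nanoDSF thermal-unfolding curve
#'
#' Generates an intrinsic-fluorescence ratio (F350/F330) melt curve from the
#' Boltzmann sigmoid
#' `ratio(T) = low + (high - low) / (1 + exp((tm - T) / slope))`
#' plus Gaussian noise. The melting temperature is the inflection point.
#'
#' @param tm Melting temperature (inflection point) in deg C.
#' @param slope Transition slope in deg C (non-zero; positive gives an
#'   unfolding-type rising curve).
#' @param low,high Pre- and post-transition baseline ratios.
#' @param t_range Temperature range `c(min, max)` in deg C.
#' @param step Grid step in deg C.
#' @param noise_sd Gaussian noise SD in ratio units.
#' @param seed Integer seed.
#' @return Tibble of class `melt_curve` with `temperature`, `ratio`; truth in
#'   `attr(, "true_params")`.
#' @export
simulate_dsf <- function(tm, slope = 2, low = 0.8, high = 1.0,
                         t_range = c(20, 95), step = 0.5, noise_sd = 0.002,
                         seed = 1) {
  if (slope == 0) abort("`slope` must be non-zero")
  if (diff(t_range) <= 0) abort("`t_range` must be increasing")
  temperature <- seq(t_range[1], t_range[2], by = step)
  ratio <- boltzmann(temperature, tm, slope, low, high)
  if (noise_sd > 0) {
    ratio <- ratio + with_seed(seed, rnorm(length(ratio), 0, noise_sd))
  }
  out <- tibble::tibble(temperature = temperature, ratio = ratio)
  attr(out, "true_params") <- list(tm = tm, slope = slope, low = low, high = high)
  class(out) <- c("melt_curve", class(out))
  out
}

boltzmann <- function(temperature, tm, slope, low, high) {
  low + (high - low) / (1 + exp((tm - temperature) / slope))
}

#' Fit the Boltzmann sigmoid to a melt curve
#'
#' Least-squares fit of the two-baseline Boltzmann unfolding model; the
#' reported melting temperature is the inflection point of the fitted
#' sigmoid. Initialization takes `tm` from the temperature of the largest
#' smoothed derivative of the ratio and the baselines from the curve ends.
#'
#' @param curve A `melt_curve` (tibble with strictly increasing
#'   `temperature` and `ratio`).
#' @return An object of class `dsf_fit`: `params` (tm, slope, low, high),
#'   `std_errors`, `residual_norm`, `fitted`, `data`.
#' @export
fit_dsf <- function(curve) {
  stopifnot(all(c("temperature", "ratio") %in% names(curve)))
  temperature <- curve$temperature
  ratio <- curve$ratio
  if (length(temperature) < 10) abort("need at least 10 points")
  if (any(diff(temperature) <= 0)) abort("`temperature` must be strictly increasing")

  d <- diff(stats::filter(ratio, rep(1 / 5, 5), sides = 2))
  d[is.na(d)] <- 0
  if (max(abs(d)) == 0 || diff(range(ratio)) < 1e-6 ||
      diff(range(ratio)) < 10 * stats::mad(diff(ratio))) {
    abort("no unfolding transition detected in the curve",
          class = "mrpr_fit_error")
  }
  i0 <- which.max(abs(d))
  tm0 <- temperature[i0]
  slope0 <- if (d[i0] >= 0) 2 else -2
  low0 <- ratio[1]
  high0 <- ratio[length(ratio)]

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ratio ~ low + (high - low) / (1 + exp((tm - temperature) / slope)),
      data = data.frame(temperature = temperature, ratio = ratio),
      start = list(tm = tm0, slope = slope0, low = low0, high = high0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) {
      abort(paste("Boltzmann fit failed:", conditionMessage(e)),
            class = "mrpr_fit_error")
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) {
    setNames(rep(NA_real_, 4), names(est))
  })
  structure(list(
    params = as.list(est),
    std_errors = se,
    residual_norm = sqrt(sum(stats::residuals(fit)^2)),
    fitted = stats::fitted(fit),
    data = tibble::as_tibble(curve)
  ), class = "dsf_fit")
}

#' @export
print.dsf_fit <- function(x, ...) {
  cat("<dsf_fit> Boltzmann sigmoid\n",
      sprintf("  Tm    = %.2f +/- %.2g degC\n", x$params$tm, x$std_errors["tm"]),
      sprintf("  slope = %.3g degC\n", x$params$slope),
      sprintf("  baselines %.4g -> %.4g\n", x$params$low, x$params$high),
      sep = "")
  invisible(x)
}

#' @export
tidy.dsf_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params),
    estimate = unlist(x$params, use.names = FALSE),
    std.error = unname(x$std_errors[names(x$params)])
  )
}

#' @export
glance.dsf_fit <- function(x, ...) {
  tibble::tibble(
    residual.norm = x$residual_norm,
    n.points = nrow(x$data)
  )
}
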