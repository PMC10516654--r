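#' Injection schedule for an ITC titration
#'
#' Defaults reproduce the standard micro-calorimetry protocol used for the
#' repressor-operator titrations: a 200 ul cell holding the DNA duplex at
#' 20 uM, titrated by protein from the syringe in 13 injections (a 0.4 ul
#' priming injection followed by twelve 3 ul injections).
#'
#' @param cell_volume Cell volume in ul.
#' @param injection_volumes Injection volumes in ul.
#' @param cell_conc Macromolecule (cell) concentration in uM.
#' @param syringe_conc Titrant (syringe) concentration in uM.
#' @return An `itc_schedule` list.
#' @export
itc_schedule <- function(cell_volume = 200,
                         injection_volumes = c(0.4, rep(3, 12)),
                         cell_conc = 20, syringe_conc = 250) {
  if (cell_volume <= 0 || any(injection_volumes <= 0) ||
      cell_conc <= 0 || syringe_conc < 0) {
    abort("volumes and the cell concentration must be > 0")
  }
  structure(list(cell_volume = cell_volume,
                 injection_volumes = injection_volumes,
                 cell_conc = cell_conc, syringe_conc = syringe_conc),
            class = "itc_schedule")
}

#' One-set-of-sites ITC model parameters
#'
#' @param n Stoichiometry (sites per macromolecule), > 0.
#' @param kd Dissociation constant in uM, > 0.
#' @param dh Molar binding enthalpy in kcal/mol.
#' @return An `itc_params` list.
#' @export
itc_params <- function(n = 1, kd = 0.238, dh = -10) {
  if (n <= 0 || kd <= 0) abort("`n` and `kd` must be > 0")
  structure(list(n = n, kd = kd, dh = dh), class = "itc_params")
}

# Cell concentrations after each injection under displaced-volume accounting:
# an injection of volume v expels v of (average pre/post) cell contents.
#   M_i = M_{i-1} (1 - d/2) / (1 + d/2),      d = v / V0
#   X_i = [X_{i-1} (1 - d/2) + d Xs] / (1 + d/2)
itc_concentrations <- function(schedule) {
  v0 <- schedule$cell_volume
  m <- schedule$cell_conc
  x <- 0
  M <- X <- numeric(length(schedule$injection_volumes))
  for (i in seq_along(schedule$injection_volumes)) {
    d <- schedule$injection_volumes[i] / v0
    m <- m * (1 - d / 2) / (1 + d / 2)
    x <- (x * (1 - d / 2) + d * schedule$syringe_conc) / (1 + d / 2)
    M[i] <- m; X[i] <- x
  }
  list(M = M, X = X)
}

# Bound-titrant concentration from the single-site quadratic equilibrium.
bound_conc <- function(X, S, kd) {
  b <- X + S + kd
  (b - sqrt(b^2 - 4 * X * S)) / 2
}

#' Per-injection heats of the one-set-of-sites isotherm
#'
#' Forward model of a single-class independent-sites titration (the Wiseman
#' isotherm) under displaced-volume accounting: after each injection the cell
#' concentrations of macromolecule and titrant are updated for dilution (the
#' injected volume expels an equal volume of averaged pre/post cell
#' contents), the bound-titrant concentration follows from the quadratic
#' mass-action equilibrium, and the measured heat of injection `i` is
#'
#' `q_i = (Q_i - Q_{i-1} + (v_i / V0) * (Q_i + Q_{i-1}) / 2)`
#'
#' with `Q_i = V0 * dH * B_i` the cumulative heat content of the cell
#' (`B_i` bound concentration); the second term accounts for heat carried out
#' with the displaced volume.
#'
#' @param params An [itc_params()].
#' @param schedule An [itc_schedule()].
#' @return Tibble: `injection`, `volume` (ul), `molar_ratio` (titrant/cell),
#'   `heat` (ucal).
#' @export
isotherm_heats <- function(params, schedule) {
  stopifnot(inherits(params, "itc_params"), inherits(schedule, "itc_schedule"))
  conc <- itc_concentrations(schedule)
  B <- bound_conc(conc$X, params$n * conc$M, params$kd)
  v0 <- schedule$cell_volume
  # uM * ul * kcal/mol = 1e-3 ucal
  Q <- v0 * params$dh * B * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  dv <- schedule$injection_volumes / v0
  tibble::tibble(
    injection = seq_along(Q),
    volume = schedule$injection_volumes,
    molar_ratio = conc$X / conc$M,
    heat = Q - Qprev + dv * (Q + Qprev) / 2
  )
}

#' Simulate an ITC titration experiment
#'
#' @param params True [itc_params()].
#' @param schedule An [itc_schedule()].
#' @param noise_sd Gaussian noise on per-injection heats (ucal); `NULL` uses
#'   2\% of the largest absolute model heat.
#' @param seed Integer seed.
#' @return Tibble of class `itc_experiment` with the forward-model columns
#'   plus noisy `heat`; true parameters in `attr(, "true_params")`.
#' @export
simulate_itc <- function(params, schedule = itc_schedule(), noise_sd = NULL,
                         seed = 1) {
  model <- isotherm_heats(params, schedule)
  noise_sd <- noise_sd %||% (0.02 * max(abs(model$heat)))
  out <- model
  out$model_heat <- model$heat
  out$heat <- model$heat +
    if (noise_sd > 0) with_seed(seed, rnorm(nrow(model), 0, noise_sd)) else 0
  attr(out, "true_params") <- params
  attr(out, "schedule") <- schedule
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("itc_experiment", class(out))
  out
}

#' Fit the one-set-of-sites model to titration heats
#'
#' Least-squares fit of [isotherm_heats()] to observed per-injection heats
#' over `(n, log10 kd, dH)` with bound constraints (`kd` in
#' `[1e-4, 1e4]` uM, `n` in `[0.1, 10]`), multi-start initialization over a
#' log-spaced `kd` grid, Levenberg-Marquardt refinement, and asymptotic
#' standard errors. The small priming injection is excluded by default.
#'
#' @param experiment An `itc_experiment` (or tibble with `injection` and
#'   `heat`), plus its schedule either attached as an attribute or given
#'   explicitly.
#' @param schedule An [itc_schedule()]; defaults to the experiment's.
#' @param exclude_first Drop the first (priming) injection from the fit.
#' @param weights Optional per-injection weights.
#' @return An object of class `itc_fit`: `params` ([itc_params()] point
#'   estimates), `std_errors`, `residual_norm`, `n_excluded`, `fitted`,
#'   `data`, `convergence`.
#' @export
fit_itc <- function(experiment, schedule = NULL, exclude_first = TRUE,
                    weights = NULL) {
  schedule <- schedule %||% attr(experiment, "schedule")
  if (is.null(schedule)) abort("supply the injection `schedule`")
  keep <- rep(TRUE, nrow(experiment))
  if (exclude_first) keep[1] <- FALSE
  if (sum(keep) < 5) abort("need at least 5 usable injections")
  obs <- experiment$heat
  w <- weights %||% rep(1, length(obs))

  model_fun <- function(n, log10_kd, dh) {
    isotherm_heats(itc_params(n = n, kd = 10^log10_kd, dh = dh), schedule)$heat
  }
  resid_fun <- function(p) {
    sqrt(w[keep]) * (obs[keep] - model_fun(p[1], p[2], p[3])[keep])
  }

  dh0 <- sum(obs[keep]) / (schedule$cell_volume * schedule$cell_conc * 1e-3)
  starts <- expand.grid(n = c(0.5, 1, 2),
                        log10_kd = seq(-2, 2, by = 1),
                        dh = c(dh0, if (abs(dh0) < 1) c(-10, 10)))
  lower <- c(0.1, -4, -Inf)
  upper <- c(10, 4, Inf)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = as.numeric(starts[i, ]), fn = resid_fun,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    abort("one-set-of-sites fit failed from every start",
          class = "mrpr_fit_error")
  }

  p <- best$par
  dof <- sum(keep) - 3
  sigma2 <- best$deviance / max(dof, 1)
  cov <- tryCatch(sigma2 * solve(best$hessian), error = function(e) {
    matrix(NA_real_, 3, 3)
  })
  se_raw <- sqrt(pmax(diag(cov), 0))
  # delta method: se(kd) from se(log10 kd)
  se <- c(n = se_raw[1], kd = se_raw[2] * log(10) * 10^p[2], dh = se_raw[3])

  structure(list(
    params = itc_params(n = p[1], kd = 10^p[2], dh = p[3]),
    std_errors = se,
    residual_norm = sqrt(best$deviance),
    n_excluded = sum(!keep),
    fitted = model_fun(p[1], p[2], p[3]),
    data = tibble::as_tibble(experiment),
    convergence = best$info
  ), class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("<itc_fit> one set of sites\n",
      sprintf("  n  = %.4g +/- %.2g\n", x$params$n, x$std_errors["n"]),
      sprintf("  Kd = %.4g +/- %.2g uM\n", x$params$kd, x$std_errors["kd"]),
      sprintf("  dH = %.4g +/- %.2g kcal/mol\n", x$params$dh, x$std_errors["dh"]),
      sep = "")
  invisible(x)
}

#' @export
tidy.itc_fit <- function(x, ...) {
  tibble::tibble(
    term = c("n", "kd", "dh"),
    estimate = c(x$params$n, x$params$kd, x$params$dh),
    std.error = unname(x$std_errors)
  )
}

#' @export
glance.itc_fit <- function(x, ...) {
  tibble::tibble(
    residual.norm = x$residual_norm,
    n.injections = nrow(x$data),
    n.excluded = x$n_excluded,
    converged = x$convergence %in% 1:4
  )
}
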