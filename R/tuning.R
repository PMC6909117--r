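#' Estimate the equivalent inherent aluminum filtration
#'
#' CT vendors rarely publish the inherent filtration (tube window, collimator
#' and central-ray bowtie), so the spectrum entering the measurement region
#' is determined indirectly: the aluminum thickness is tuned until the
#' deterministic narrow-beam model reproduces a measured copper attenuation
#' curve. Matching is done in log-transmission space (equal relative weight
#' across thicknesses), with transmission normalised to the extrapolated
#' unattenuated exposure I0'.
#'
#' @param measured An \code{\link{attenuation_series}}.
#' @param tube_voltage_kv Tube voltage; must match the series metadata when
#'   that is present.
#' @param anode_angle_deg Anode angle for the spectrum model.
#' @param use_fit If TRUE (default) the transmission curves are taken from
#'   the fitted quadratics exp(c1 t + c2 t^2); if FALSE the raw
#'   per-thickness means divided by the fitted I0' are matched. Measured and
#'   modelled curves always pass through the same processing, so the small
#'   quadratic-model bias cancels instead of leaking into the filtration
#'   estimate.
#' @param interval Search interval for the aluminum thickness, mm (default
#'   c(0, 30)).
#' @param tol Search tolerance, mm (default 0.01).
#' @param ... Passed to \code{\link{generate_spectrum}}.
#' @return A list of class \code{filtration_estimate}: \code{al_mm} (the
#'   estimate), \code{objective} (sum of squared log-transmission residuals
#'   at the optimum), \code{matched} (data.frame of thickness, measured and
#'   modelled transmission), and \code{spectrum} (the filtered model
#'   spectrum).
#' @export
estimate_inherent_filtration <- function(measured, tube_voltage_kv,
                                         anode_angle_deg = 12,
                                         use_fit = TRUE,
                                         interval = c(0, 30), tol = 0.01,
                                         ...) {
  stopifnot(inherits(measured, "attenuation_series"))
  if (!is.na(measured$tube_voltage_kv) &&
      abs(measured$tube_voltage_kv - tube_voltage_kv) > 1e-9)
    stop("tube_voltage_kv does not match the series metadata (",
         measured$tube_voltage_kv, " kV)")
  t_mm <- measured$thickness_mm
  fit <- fit_attenuation(measured)
  ln_t_meas <- if (use_fit) fit$c1 * t_mm + fit$c2 * t_mm^2
               else log(series_means(measured)) - fit$c0

  base <- generate_spectrum(tube_voltage_kv, anode_angle_deg, ...)
  cu <- load_material("cu"); al <- load_material("al")
  mu_cu <- linear_attenuation(cu, base$energy_kev)
  mu_al <- linear_attenuation(al, base$energy_kev)
  air <- load_material("air")
  kw <- base$energy_kev * mass_energy_absorption(air, base$energy_kev)

  # identical processing for both curves: quadratic fit of ln(kerma) on the
  # measured thicknesses, normalised to the fitted intercept
  process <- function(ln_k) {
    X <- cbind(1, t_mm, t_mm^2)
    cf <- stats::lm.fit(X, ln_k)$coefficients
    if (use_fit) cf[2L] * t_mm + cf[3L] * t_mm^2 else ln_k - cf[1L]
  }
  ln_t_model <- function(al_mm) {
    f <- base$fluence * exp(-mu_al * al_mm / 10)
    process(vapply(t_mm, function(ti)
      log(sum(f * exp(-mu_cu * ti / 10) * kw)), numeric(1L)))
  }
  objective <- function(al_mm) sum((ln_t_model(al_mm) - ln_t_meas)^2)

  # coarse unimodality pre-scan
  grid <- seq(interval[1L], interval[2L], length.out = 31L)
  ov <- vapply(grid, objective, numeric(1L))
  sign_changes <- sum(diff(sign(diff(ov))) != 0)
  if (sign_changes > 1L)
    warning("objective may be non-unimodal on the search interval (",
            sign_changes, " local extrema on the pre-scan)")

  opt <- stats::optimize(objective, interval = interval, tol = tol)
  al_mm <- opt$minimum
  # boundary solutions: the data want less (or more) filtration than allowed
  if (objective(interval[1L]) <= opt$objective) al_mm <- interval[1L]
  spectrum <- apply_filter(base, "al", al_mm)
  structure(
    list(al_mm = al_mm,
         objective = objective(al_mm),
         matched = data.frame(thickness_mm = t_mm,
                              log_transmission_measured = ln_t_meas,
                              log_transmission_model = ln_t_model(al_mm)),
         spectrum = spectrum,
         tube_voltage_kv = tube_voltage_kv,
         anode_angle_deg = anode_angle_deg),
    class = "filtration_estimate")
}

#' @export
print.filtration_estimate <- function(x, ...) {
  cat(sprintf("<filtration_estimate> %.2f mm Al (tube %g kV, anode %g deg; objective %.3g)\n",
              x$al_mm, x$tube_voltage_kv, x$anode_angle_deg, x$objective))
  invisible(x)
}
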