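#' Construct an attenuation measurement series
#'
#' A set of replicate exposure readings at several absorber thicknesses for
#' one scanner / tube-voltage / acquisition-method combination -- the input
#' of the HVL analysis.
#'
#' @param thickness_mm Distinct absorber thicknesses in mm (>= 4 values).
#' @param exposures List (one element per thickness) of replicate exposure
#'   readings, all positive, arbitrary units.
#' @param method One of \code{"copper_pipe"}, \code{"nonrotating"},
#'   \code{"simulated"}.
#' @param scanner Scanner label.
#' @param tube_voltage_kv Tube voltage in kV.
#' @param strict If TRUE (default) reject series whose per-thickness mean
#'   exposures are not strictly decreasing; with FALSE the series is built
#'   and the check deferred (a warning) to \code{\link{fit_attenuation}}.
#' @return An object of class \code{attenuation_series}.
#' @export
attenuation_series <- function(thickness_mm, exposures,
                               method = c("copper_pipe", "nonrotating",
                                          "simulated"),
                               scanner = NA_character_,
                               tube_voltage_kv = NA_real_,
                               strict = TRUE) {
  method <- match.arg(method)
  thickness_mm <- as.numeric(thickness_mm)
  if (anyDuplicated(thickness_mm))
    stop("thicknesses must be distinct")
  if (is.matrix(exposures))
    exposures <- split(exposures, row(exposures))
  if (!is.list(exposures) || length(exposures) != length(thickness_mm))
    stop("exposures must be a list with one replicate vector per thickness")
  ord <- order(thickness_mm)
  thickness_mm <- thickness_mm[ord]
  exposures <- lapply(exposures[ord], as.numeric)
  if (length(thickness_mm) < 4L)
    stop("need at least 4 distinct thicknesses")
  if (any(vapply(exposures, function(e) any(!is.finite(e) | e <= 0),
                 logical(1L))))
    stop("all exposures must be positive and finite")
  means <- vapply(exposures, mean, numeric(1L))
  if (strict && any(diff(means) >= 0))
    stop("mean exposure must decrease strictly with thickness; ",
         "use strict = FALSE to defer this check to the fit")
  structure(
    list(thickness_mm = thickness_mm, exposures = exposures,
         method = method, scanner = scanner,
         tube_voltage_kv = tube_voltage_kv),
    class = "attenuation_series")
}

#' @export
print.attenuation_series <- function(x, ...) {
  nrep <- vapply(x$exposures, length, integer(1L))
  cat(sprintf("<attenuation_series> %s | %s %s kV | %d thicknesses (%g-%g mm), %s replicates\n",
              x$method, x$scanner, format(x$tube_voltage_kv),
              length(x$thickness_mm), min(x$thickness_mm),
              max(x$thickness_mm),
              if (length(unique(nrep)) == 1L) nrep[1L]
              else paste0(min(nrep), "-", max(nrep))))
  invisible(x)
}

#' Per-thickness means of a series
#' @param series An \code{\link{attenuation_series}}.
#' @return Numeric vector of mean exposures, one per thickness.
#' @export
series_means <- function(series) {
  vapply(series$exposures, mean, numeric(1L))
}

#' Fit the quadratic log-attenuation curve
#'
#' Ordinary unweighted least squares of ln(mean exposure) on thickness and
#' thickness squared. Replicates are averaged per thickness first; the beam
#' hardens as it penetrates, so the log-attenuation curve is curved and the
#' quadratic term captures that curvature over the 0.05--0.6 mm range.
#'
#' @param series An \code{\link{attenuation_series}}.
#' @return An object of class \code{quadratic_fit} with coefficients
#'   \code{c0}, \code{c1}, \code{c2} of
#'   ln(exposure) = c0 + c1 t + c2 t^2, \code{r_squared}, per-point
#'   \code{residuals}, per-thickness replicate standard deviations, and the
#'   turning point -c1/(2 c2) beyond which the fitted quadratic is no longer
#'   a physically valid attenuation curve.
#' @export
fit_attenuation <- function(series) {
  stopifnot(inherits(series, "attenuation_series"))
  t <- series$thickness_mm
  if (length(t) < 4L) stop("need at least 4 distinct thicknesses")
  m <- series_means(series)
  if (any(diff(m) >= 0))
    warning("mean exposure is not strictly decreasing with thickness; ",
            "fit proceeds but check the data")
  y <- log(m)
  fit <- stats::lm(y ~ t + I(t^2))
  cf <- unname(stats::coef(fit))
  # direct R^2 (summary.lm warns on exact, noise-free data)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(c0 = cf[1L], c1 = cf[2L], c2 = cf[3L],
         r_squared = r2,
         residuals = unname(stats::residuals(fit)),
         thickness_mm = t,
         log_mean_exposure = y,
         replicate_sd = vapply(series$exposures, stats::sd, numeric(1L)),
         turning_point_mm = if (abs(cf[3L]) > 1e-12) -cf[2L] / (2 * cf[3L])
                            else Inf),
    class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  cat(sprintf("<quadratic_fit> ln I = %.5g %+.5g t %+.5g t^2   (R^2 = %.5f)\n",
              x$c0, x$c1, x$c2, x$r_squared))
  invisible(x)
}

#' Extrapolated unattenuated exposure I0'
#'
#' The fitted curve evaluated at zero thickness, exp(c0). Extrapolating from
#' the curve, instead of reading the bare chamber, suppresses the scatter
#' component present in the open-beam measurement.
#'
#' @param fit A \code{\link{quadratic_fit}}.
#' @return I0' on the exposure scale of the input data.
#' @export
extrapolate_unattenuated <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  exp(fit$c0)
}

#' Solve the fitted curve for the half-value layer
#'
#' The HVL is the thickness at which the fitted exposure falls to I0'/2,
#' i.e. the smallest positive root of c2 t^2 + c1 t + ln 2 = 0 (closed-form
#' quadratic; the linear fallback -ln2/c1 is used when |c2| < 1e-12). The
#' root is verified to satisfy |c1 t + c2 t^2 + ln 2| < 1e-10.
#'
#' @param fit A \code{\link{quadratic_fit}} with c1 < 0.
#' @return HVL in mm (same thickness units as the fit).
#' @export
solve_hvl <- function(fit) {
  stopifnot(inherits(fit, "quadratic_fit"))
  c1 <- fit$c1; c2 <- fit$c2
  if (c1 >= 0)
    stop("invalid attenuation curve: linear coefficient must be negative")
  ln2 <- log(2)
  if (abs(c2) < 1e-12) {
    root <- -ln2 / c1
  } else {
    disc <- c1^2 - 4 * c2 * ln2
    if (disc < 0)
      stop("fitted curve never reaches half of I0' (negative discriminant)")
    roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
    roots <- roots[roots > 0]
    if (length(roots) == 0L)
      stop("fitted curve has no positive half-value root")
    root <- min(roots)
  }
  stopifnot(abs(c1 * root + c2 * root^2 + ln2) < 1e-10)
  root
}

#' Full HVL analysis of a measurement series
#'
#' Pipeline: quadratic log-attenuation fit, extrapolation of the
#' scatter-corrected unattenuated exposure I0', closed-form half-value solve,
#' and conversion to effective energy through the copper attenuation curve.
#' All intermediate objects are retained in the result.
#'
#' @param series An \code{\link{attenuation_series}}.
#' @param cu_table Copper \code{\link{material_table}} used for the effective
#'   energy conversion.
#' @return An object of class \code{hvl_result}: \code{i0_prime},
#'   \code{hvl_mm}, \code{effective_energy_kev}, the \code{fit}, and the
#'   series metadata.
#' @export
analyze_series <- function(series, cu_table = load_material("cu")) {
  stopifnot(inherits(series, "attenuation_series"))
  fit <- fit_attenuation(series)
  i0 <- extrapolate_unattenuated(fit)
  hvl <- solve_hvl(fit)
  rng <- range(series$thickness_mm)
  extrapolated <- hvl < rng[1L] || hvl > rng[2L]
  if (extrapolated)
    warning(sprintf(
      "HVL %.3f mm lies outside the measured thickness range [%g, %g] mm (extrapolation)",
      hvl, rng[1L], rng[2L]))
  structure(
    list(i0_prime = i0, hvl_mm = hvl,
         effective_energy_kev = hvl_to_effective_energy(hvl, cu_table),
         fit = fit, method = series$method, scanner = series$scanner,
         tube_voltage_kv = series$tube_voltage_kv,
         extrapolated = extrapolated),
    class = "hvl_result")
}

#' @export
print.hvl_result <- function(x, ...) {
  cat(sprintf("<hvl_result> %s | %s %s kV\n", x$method, x$scanner,
              format(x$tube_voltage_kv)),
      sprintf("  HVL = %.2f mmCu   effective energy = %.1f keV   (R^2 = %.4f)\n",
              round(x$hvl_mm, 2), round(x$effective_energy_kev, 1),
              x$fit$r_squared))
  invisible(x)
}

#' Display-rounded summary of an HVL result
#'
#' Reporting convention: HVL to 2 decimals (mmCu), effective energy to 1
#' decimal (keV). Full precision stays in the \code{hvl_result} object.
#'
#' @param x An \code{\link{analyze_series}} result.
#' @return One-row data.frame.
#' @export
format_hvl_result <- function(x) {
  stopifnot(inherits(x, "hvl_result"))
  data.frame(scanner = x$scanner, tube_voltage_kv = x$tube_voltage_kv,
             method = x$method,
             hvl_mmcu = round(x$hvl_mm, 2),
             effective_energy_kev = round(x$effective_energy_kev, 1),
             r_squared = round(x$fit$r_squared, 4))
}
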