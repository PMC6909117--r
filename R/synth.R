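#' Generate a synthetic replicate attenuation series
#'
#' Emulates a copper-pipe acquisition from a known spectrum: the mean signal
#' at wall thickness t is the narrow-beam air kerma of the filtered spectrum
#' times a scatter excess decaying with thickness,
#' \deqn{S(t) = K(t) [1 + s_0 e^{-\gamma t}],}
#' and replicate readings carry multiplicative Gaussian noise with
#' coefficient of variation \code{noise_cv}. Defaults reproduce the
#' conditions of a careful chamber measurement: ~0.5% reading noise (log-data
#' SD < 0.01) and a small scatter excess that the quadratic-extrapolation
#' analysis is designed to remove (quadratic fits stay at R^2 >= 0.99).
#'
#' @param s An \code{\link{xray_spectrum}}.
#' @param thicknesses_mm Absorber thicknesses, mm (>= 4 distinct values;
#'   default the seven pipe walls 0.05--0.6 mm).
#' @param scatter_fraction_at_zero Scatter excess s_0 at zero thickness
#'   (default 0.03).
#' @param scatter_decay Scatter decay rate gamma, per mm (default 5).
#' @param noise_cv Coefficient of variation of the multiplicative reading
#'   noise (default 0.005).
#' @param replicates Readings per thickness (>= 3, default 3).
#' @param seed Integer seed; identical seeds give identical series.
#' @param method Method tag for the series (default \code{"copper_pipe"}).
#' @param scanner Scanner label.
#' @return An \code{\link{attenuation_series}}.
#' @export
generate_series <- function(s,
                            thicknesses_mm = c(0.05, 0.1, 0.2, 0.3, 0.4,
                                               0.5, 0.6),
                            scatter_fraction_at_zero = 0.03,
                            scatter_decay = 5,
                            noise_cv = 0.005,
                            replicates = 3,
                            seed = 1,
                            method = "copper_pipe",
                            scanner = NA_character_) {
  stopifnot(inherits(s, "xray_spectrum"))
  if (replicates < 3) stop("replicates must be >= 3")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (scatter_fraction_at_zero < 0 || scatter_decay < 0)
    stop("scatter parameters must be >= 0")
  means <- synthetic_mean_signal(s, thicknesses_mm,
                                 scatter_fraction_at_zero, scatter_decay)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  exposures <- lapply(means, function(m)
    m * (1 + noise_cv * stats::rnorm(replicates)))
  attenuation_series(thicknesses_mm, exposures, method = method,
                     scanner = scanner, tube_voltage_kv = s$tube_voltage_kv,
                     strict = FALSE)
}

#' Analytic mean signal of the synthetic acquisition model
#'
#' Narrow-beam kerma times the scatter excess; the noiseless expectation of
#' \code{\link{generate_series}} replicates.
#'
#' @inheritParams generate_series
#' @return Numeric vector of mean signals, one per thickness.
#' @export
synthetic_mean_signal <- function(s, thicknesses_mm,
                                  scatter_fraction_at_zero = 0.03,
                                  scatter_decay = 5) {
  vapply(thicknesses_mm, function(t_mm)
    air_kerma(apply_filter(s, "cu", t_mm)) *
      (1 + scatter_fraction_at_zero * exp(-scatter_decay * t_mm)),
    numeric(1L))
}
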