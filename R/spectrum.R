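# Tungsten K fluorescence lines (keV) and approximate relative intensities.
.k_lines <- data.frame(
  line = c("Ka1", "Ka2", "Kb1", "Kb2"),
  energy_kev = c(59.32, 57.98, 67.2, 69.1),
  rel_intensity = c(1.00, 0.57, 0.32, 0.08))
.k_edge_kev <- 69.5

#' Construct an X-ray spectrum
#'
#' A binned photon-fluence spectrum on a uniform energy grid. Fluence is on
#' an arbitrary scale; every downstream quantity that matters (transmission,
#' HVL, effective energy) is scale-invariant.
#'
#' @param energy_kev Bin centres, keV, uniform spacing.
#' @param fluence Photons per bin, non-negative; zero above the tube voltage.
#' @param tube_voltage_kv Tube voltage in kV.
#' @param anode_angle_deg Anode (target) angle in degrees.
#' @param filtration data.frame with columns \code{material},
#'   \code{thickness_mm}: the filters already applied, in order.
#' @return An object of class \code{xray_spectrum}.
#' @export
xray_spectrum <- function(energy_kev, fluence, tube_voltage_kv,
                          anode_angle_deg = NA_real_,
                          filtration = data.frame(material = character(),
                                                  thickness_mm = numeric())) {
  stopifnot(length(energy_kev) == length(fluence), length(energy_kev) >= 1L)
  if (any(fluence < 0)) stop("fluence must be non-negative")
  if (length(energy_kev) > 1L) {
    w <- diff(energy_kev)
    if (any(abs(w - w[1L]) > 1e-9 * w[1L]))
      stop("bin width must be uniform")
  }
  if (any(fluence[energy_kev > tube_voltage_kv] > 0))
    stop("fluence must vanish above the tube voltage")
  structure(
    list(energy_kev = as.numeric(energy_kev), fluence = as.numeric(fluence),
         tube_voltage_kv = tube_voltage_kv, anode_angle_deg = anode_angle_deg,
         filtration = filtration),
    class = "xray_spectrum")
}

#' @export
print.xray_spectrum <- function(x, ...) {
  filt <- if (nrow(x$filtration) == 0L) "none" else
    paste(sprintf("%s %.3g mm", x$filtration$material,
                  x$filtration$thickness_mm), collapse = " + ")
  cat(sprintf("<xray_spectrum> %g kV, anode %s deg, %d bins (%g-%g keV)\n",
              x$tube_voltage_kv,
              format(x$anode_angle_deg), length(x$energy_kev),
              min(x$energy_kev), max(x$energy_kev)),
      sprintf("  filtration: %s | mean energy %.2f keV\n",
              filt, mean_energy(x)))
  invisible(x)
}

#' Generate an unfiltered tungsten-anode spectrum
#'
#' Semi-empirical bremsstrahlung model: per-bin intensity proportional to the
#' Kramers form (V - E)/E, attenuated by anode self-filtration
#' exp(-mu_W(E) d / sin(anode angle)) averaged over a small set of production
#' depths, plus tungsten K characteristic lines when the tube voltage exceeds
#' the K edge (69.5 keV). Normalised to unit total fluence. The model is a
#' pluggable stand-in for dedicated spectrum codes: downstream analyses never
#' depend on the absolute shape, only on shapes constrained by matching a
#' measured attenuation curve (see \code{\link{estimate_inherent_filtration}}).
#'
#' @param tube_voltage_kv Tube voltage, 40--150 kV.
#' @param anode_angle_deg Anode angle, degrees, in (0, 45).
#' @param bin_width_kev Energy bin width (default 0.5 keV).
#' @param min_energy_kev Lowest bin edge (default 10 keV, the floor of the
#'   bundled coefficient tables; lower-energy photons do not survive inherent
#'   filtration in practice).
#' @param anode_depth_mm Maximum electron production depth in the anode
#'   (default 0.002 mm); self-filtration is averaged over 8 uniform depths.
#' @param k_fraction_120 Fraction of total fluence in the K lines at 120 kV
#'   (default 0.05), scaled linearly in (V - 69.5) above the edge.
#' @return An \code{\link{xray_spectrum}} with empty filtration list.
#' @export
generate_spectrum <- function(tube_voltage_kv, anode_angle_deg = 12,
                              bin_width_kev = 0.5, min_energy_kev = 10,
                              anode_depth_mm = 0.002, k_fraction_120 = 0.05) {
  if (!is.numeric(tube_voltage_kv) || tube_voltage_kv < 40 ||
      tube_voltage_kv > 150)
    stop("tube_voltage_kv must lie in [40, 150]")
  if (anode_angle_deg <= 0 || anode_angle_deg >= 45)
    stop("anode_angle_deg must lie in (0, 45)")
  if (bin_width_kev <= 0) stop("bin_width_kev must be positive")

  edges <- seq(min_energy_kev, tube_voltage_kv, by = bin_width_kev)
  centers <- edges[-length(edges)] + bin_width_kev / 2
  centers <- centers[centers < tube_voltage_kv]

  w_tab <- load_material("w")
  mu_w <- linear_attenuation(w_tab, centers)            # cm^-1
  depths_cm <- (1:8) / 8 * anode_depth_mm / 10
  sin_t <- sin(anode_angle_deg * pi / 180)
  self_filter <- rowMeans(exp(-outer(mu_w, depths_cm) / sin_t))
  brems <- (tube_voltage_kv - centers) / centers * self_filter
  fluence <- brems / sum(brems)

  if (tube_voltage_kv > .k_edge_kev) {
    frac <- k_fraction_120 * (tube_voltage_kv - .k_edge_kev) /
      (120 - .k_edge_kev)
    lines <- .k_lines[.k_lines$energy_kev < tube_voltage_kv, ]
    wts <- lines$rel_intensity / sum(lines$rel_intensity)
    # place each line in its containing bin; total line fluence = frac of all
    add <- frac / (1 - frac) * wts  # relative to current brems total (=1)
    for (i in seq_len(nrow(lines))) {
      j <- which.min(abs(centers - lines$energy_kev[i]))
      fluence[j] <- fluence[j] + add[i]
    }
    fluence <- fluence / sum(fluence)
  }
  xray_spectrum(centers, fluence, tube_voltage_kv, anode_angle_deg)
}

#' Filter a spectrum through an absorber
#'
#' Per-bin Beer--Lambert attenuation:
#' fluence x exp(-mu(E) thickness / 10), thickness in mm, mu in cm^-1.
#'
#' @param s An \code{\link{xray_spectrum}}.
#' @param material Material label known to \code{\link{load_material}}, or a
#'   \code{\link{material_table}}.
#' @param thickness_mm Absorber thickness in mm, >= 0.
#' @return The filtered \code{\link{xray_spectrum}}; the filtration list is
#'   extended.
#' @export
apply_filter <- function(s, material, thickness_mm) {
  stopifnot(inherits(s, "xray_spectrum"))
  if (thickness_mm < 0) stop("thickness_mm must be >= 0")
  tab <- if (inherits(material, "material_table")) material
         else load_material(material)
  mu <- linear_attenuation(tab, s$energy_kev)
  s$fluence <- s$fluence * exp(-mu * thickness_mm / 10)
  s$filtration <- rbind(s$filtration,
                        data.frame(material = tab$material,
                                   thickness_mm = thickness_mm))
  s
}

#' Air kerma of a spectrum
#'
#' Fluence-weighted kerma integral
#' \eqn{\sum_i \Phi_i E_i (\mu_{en}/\rho)_{air}(E_i)}, arbitrary units;
#' linear in fluence. The physical surrogate of an ionisation-chamber
#' exposure reading.
#'
#' @param s An \code{\link{xray_spectrum}}.
#' @return Scalar kerma (arbitrary units).
#' @export
air_kerma <- function(s) {
  stopifnot(inherits(s, "xray_spectrum"))
  air <- load_material("air")
  sum(s$fluence * s$energy_kev * mass_energy_absorption(air, s$energy_kev))
}

#' Mean energy of a spectrum
#'
#' @param s An \code{\link{xray_spectrum}}.
#' @return Fluence-weighted mean energy, keV.
#' @export
mean_energy <- function(s) {
  stopifnot(inherits(s, "xray_spectrum"))
  sum(s$fluence * s$energy_kev) / sum(s$fluence)
}

#' Narrow-beam (theoretical) HVL of a spectrum
#'
#' The absorber thickness halving the air kerma under ideal narrow-beam
#' geometry: root of kerma(t)/kerma(0) = 1/2, found by a bracketing solve to
#' 1e-9 mm. This is the deterministic oracle the measurement pipeline and the
#' Monte Carlo simulator are checked against.
#'
#' @param s An \code{\link{xray_spectrum}} with positive total fluence.
#' @param material Absorber material label (default \code{"cu"}).
#' @return HVL in mm of the absorber.
#' @export
theoretical_hvl <- function(s, material = "cu") {
  stopifnot(inherits(s, "xray_spectrum"))
  if (sum(s$fluence) <= 0) stop("spectrum has no fluence")
  k0 <- air_kerma(s)
  f <- function(t) air_kerma(apply_filter(s, material, t)) / k0 - 0.5
  upper <- 1
  while (f(upper) > 0) {
    upper <- upper * 2
    if (upper > 1e4) stop("could not bracket the half-value root; degenerate spectrum")
  }
  stats::uniroot(f, c(0, upper), tol = 1e-9)$root
}

#' Write a spectrum to CSV
#'
#' Two columns (\code{energy_kev}, \code{fluence}) so externally computed
#' spectra can be exchanged.
#'
#' @param s An \code{\link{xray_spectrum}}.
#' @param path Output file.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "xray_spectrum"))
  utils::write.csv(data.frame(energy_kev = s$energy_kev, fluence = s$fluence),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' @param path CSV with columns \code{energy_kev}, \code{fluence}.
#' @param tube_voltage_kv Tube voltage to record; defaults to the highest
#'   energy with positive fluence.
#' @return An \code{\link{xray_spectrum}}.
#' @export
read_spectrum_csv <- function(path, tube_voltage_kv = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("energy_kev", "fluence") %in% names(df)))
    stop("spectrum file must have columns energy_kev, fluence")
  if (is.null(tube_voltage_kv))
    tube_voltage_kv <- max(df$energy_kev[df$fluence > 0])
  xray_spectrum(df$energy_kev, df$fluence, tube_voltage_kv)
}
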