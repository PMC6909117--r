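# Densities (g/cm3) of the bundled materials.
.densities <- c(cu = 8.96, al = 2.699, w = 19.30, air = 1.205e-3)

.physdata_cache <- new.env(parent = emptyenv())

#' Construct a material cross-section table
#'
#' An energy-indexed table of the photon mass attenuation coefficient
#' \eqn{\mu/\rho} and mass energy-absorption coefficient \eqn{\mu_{en}/\rho}
#' for one material, the physical backbone of every attenuation and kerma
#' computation in the package.
#'
#' @param material Character label, e.g. \code{"cu"}.
#' @param density Mass density in g/cm^3.
#' @param energy_kev Strictly increasing energy grid in keV; must span at
#'   least 10--150 keV.
#' @param mu_rho Mass attenuation coefficients, cm^2/g, one per grid point.
#' @param mu_en_rho Mass energy-absorption coefficients, cm^2/g.
#' @return An object of class \code{material_table}.
#' @export
material_table <- function(material, density, energy_kev, mu_rho, mu_en_rho) {
  stopifnot(is.character(material), length(material) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a positive scalar (g/cm^3)")
  n <- length(energy_kev)
  if (length(mu_rho) != n || length(mu_en_rho) != n)
    stop("energy_kev, mu_rho and mu_en_rho must have equal length")
  if (any(diff(energy_kev) <= 0))
    stop("energy grid must be strictly increasing")
  if (energy_kev[1L] > 10 || energy_kev[n] < 150)
    stop("energy grid must span at least [10, 150] keV")
  if (any(mu_rho <= 0) || any(mu_en_rho <= 0))
    stop("all coefficients must be strictly positive")
  structure(
    list(material = material, density = density,
         energy_kev = as.numeric(energy_kev),
         mu_rho = as.numeric(mu_rho),
         mu_en_rho = as.numeric(mu_en_rho)),
    class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat(sprintf("<material_table> %s  (density %.4g g/cm^3, %d grid points, %g-%g keV)\n",
              x$material, x$density, length(x$energy_kev),
              min(x$energy_kev), max(x$energy_kev)))
  invisible(x)
}

#' Load a bundled material table
#'
#' Reads one of the NIST-derived coefficient files shipped with the package
#' (\code{"cu"}, \code{"al"}, \code{"w"}, \code{"air"}). Tables are cached per
#' session.
#'
#' @param material One of \code{"cu"}, \code{"al"}, \code{"w"}, \code{"air"}.
#' @return A \code{\link{material_table}}.
#' @export
load_material <- function(material = c("cu", "al", "w", "air")) {
  material <- match.arg(material)
  if (!is.null(.physdata_cache[[material]]))
    return(.physdata_cache[[material]])
  path <- system.file("extdata", paste0("mu_", material, ".csv"),
                      package = "copperhvl", mustWork = TRUE)
  tab <- read_material_csv(path, material = material,
                           density = .densities[[material]])
  .physdata_cache[[material]] <- tab
  tab
}

#' Read a material coefficient CSV
#'
#' Expected columns: \code{energy_kev}, \code{mu_rho_cm2_g},
#' \code{mu_en_rho_cm2_g}; lines starting with \code{#} are comments.
#'
#' @param path File path.
#' @param material Material label to attach.
#' @param density Density in g/cm^3.
#' @return A \code{\link{material_table}}.
#' @export
read_material_csv <- function(path, material, density) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("energy_kev", "mu_rho_cm2_g", "mu_en_rho_cm2_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("coefficient file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  material_table(material, density, df$energy_kev,
                 df$mu_rho_cm2_g, df$mu_en_rho_cm2_g)
}

.check_energy_range <- function(table, energy_kev) {
  lo <- table$energy_kev[1L]
  hi <- table$energy_kev[length(table$energy_kev)]
  bad <- energy_kev < lo | energy_kev > hi
  if (any(bad))
    stop(sprintf("energy %g keV outside the %s table range [%g, %g] keV",
                 energy_kev[which(bad)[1L]], table$material, lo, hi))
  invisible(NULL)
}

# log-log interpolation of a tabulated coefficient; exact at the knots.
.loglog_interp <- function(energy_grid, values, energy_kev) {
  exp(stats::approx(log(energy_grid), log(values), xout = log(energy_kev),
                    rule = 1)$y)
}

#' Linear attenuation coefficient
#'
#' Interpolates \eqn{\mu/\rho} linearly in (log E, log coefficient) space --
#' the standard scheme for photon cross sections -- and multiplies by the
#' material density.
#'
#' @param table A \code{\link{material_table}}.
#' @param energy_kev Photon energy (keV); vectorised. Must lie within the
#'   table's grid range.
#' @return Linear attenuation coefficient(s) \eqn{\mu} in cm^-1.
#' @export
linear_attenuation <- function(table, energy_kev) {
  stopifnot(inherits(table, "material_table"))
  .check_energy_range(table, energy_kev)
  table$density * .loglog_interp(table$energy_kev, table$mu_rho, energy_kev)
}

#' Mass energy-absorption coefficient
#'
#' @inheritParams linear_attenuation
#' @return \eqn{\mu_{en}/\rho} in cm^2/g (mass coefficient, not multiplied by
#'   density).
#' @export
mass_energy_absorption <- function(table, energy_kev) {
  stopifnot(inherits(table, "material_table"))
  .check_energy_range(table, energy_kev)
  .loglog_interp(table$energy_kev, table$mu_en_rho, energy_kev)
}

#' Convert a copper HVL to effective energy
#'
#' The effective energy of a polyenergetic beam is the energy of the
#' monoenergetic beam with the same HVL: the unique E solving
#' \eqn{\mu_{Cu}(E) = \ln 2 / HVL}. Solved by a bracketing root search on the
#' monotone log-log interpolant to a relative tolerance below 1e-10.
#'
#' @param hvl_mm HVL in mm of copper; vectorised, must be positive and
#'   within the range producible by the table's energy grid.
#' @param table Copper \code{\link{material_table}} (defaults to the bundled
#'   one).
#' @return Effective energy in keV.
#' @export
hvl_to_effective_energy <- function(hvl_mm, table = load_material("cu")) {
  if (any(!is.finite(hvl_mm)) || any(hvl_mm <= 0))
    stop("hvl_mm must be positive and finite")
  mu_target <- log(2) / (hvl_mm / 10)  # cm^-1
  rng <- range(table$energy_kev)
  mu_at <- function(e) linear_attenuation(table, e)
  mu_lo <- mu_at(rng[1L]); mu_hi <- mu_at(rng[2L])
  vapply(mu_target, function(m) {
    if (m > mu_lo || m < mu_hi)
      stop(sprintf(
        "HVL %.4g mm implies mu = %.4g cm^-1 outside the table range [%.4g, %.4g] cm^-1 (energies %g-%g keV)",
        10 * log(2) / m, m, mu_hi, mu_lo, rng[1L], rng[2L]))
    exp(stats::uniroot(function(le) log(mu_at(exp(le))) - log(m),
                       interval = log(rng), tol = 1e-13)$root)
  }, numeric(1L))
}

#' Convert an effective energy to the corresponding copper HVL
#'
#' Closed form for a monoenergetic beam: \eqn{HVL = 10 \ln 2 / \mu_{Cu}(E)}
#' in mm.
#'
#' @param energy_kev Energy in keV; vectorised, within the table grid.
#' @param table Copper \code{\link{material_table}}.
#' @return HVL in mm of copper.
#' @export
effective_energy_to_hvl <- function(energy_kev, table = load_material("cu")) {
  10 * log(2) / linear_attenuation(table, energy_kev)
}

#' Reference MDCT half-value layers
#'
#' Bundled reference dataset: HVLs (mmCu) and effective energies (keV) for a
#' 16-channel and a 64-channel MDCT scanner at 80--140 kV, measured by the
#' conventional nonrotating method (\code{nr}), the rotating-tube copper-pipe
#' method (\code{cp_m}) and Monte Carlo simulation of the copper-pipe
#' geometry (\code{cp_s}). Used by the method-comparison examples and the
#' equivalence tests.
#'
#' @return A data.frame with one row per (scanner, tube voltage).
#' @export
mdct_hvl_reference <- function() {
  path <- system.file("extdata", "mdct_hvl_reference.csv",
                      package = "copperhvl", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", check.names = TRUE)
}
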