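# Tablet geometry, density bookkeeping and the four-stage compaction ROM
# kernels. All kernels are plain vectorized functions of a parameter set;
# coupling of parameters to upstream mixing lives in rational_library.R.
#
# Unit conventions (fixed across the package):
#   lengths mm, densities g/cm^3 (= mg/mm^3), pressures MPa, forces N from
#   the Kawakita kernel (pi D^2/4 [mm^2] x MPa = N); run tables report kN.

#' Tablet tooling geometry
#'
#' Describes round concave tooling: die diameter `D`, punch cup depth `h`
#' and, optionally, the number of die stations of the press.
#'
#' @param die_diameter_mm Die diameter D (mm). Must be positive.
#' @param cup_depth_mm Punch cup depth h (mm). Zero gives flat-faced tooling.
#' @param n_stations Optional integer count of die stations (for production
#'   rate); must be >= 1 when given.
#' @return An object of class `tablet_geometry`.
#' @examples
#' tablet_geometry()           # the D-tooling used throughout: D = 8, h = 0.3302
#' tablet_geometry(10, 0)      # 10 mm flat tooling
#' @export
tablet_geometry <- function(die_diameter_mm = 8, cup_depth_mm = 0.3302,
                            n_stations = NULL) {
  if (!is.numeric(die_diameter_mm) || length(die_diameter_mm) != 1L ||
      !is.finite(die_diameter_mm) || die_diameter_mm <= 0) {
    stop("`die_diameter_mm` must be a single positive number")
  }
  if (!is.numeric(cup_depth_mm) || length(cup_depth_mm) != 1L ||
      !is.finite(cup_depth_mm) || cup_depth_mm < 0) {
    stop("`cup_depth_mm` must be a single non-negative number")
  }
  if (!is.null(n_stations)) {
    n_stations <- as.integer(n_stations)
    if (is.na(n_stations) || n_stations < 1L) stop("`n_stations` must be >= 1")
  }
  structure(list(D = die_diameter_mm, h = cup_depth_mm, n_stations = n_stations),
            class = "tablet_geometry")
}

#' @export
print.tablet_geometry <- function(x, ...) {
  cat(sprintf("Tablet tooling: D = %g mm, cup depth h = %g mm%s\n", x$D, x$h,
              if (is.null(x$n_stations)) "" else
                sprintf(", %d die stations", x$n_stations)))
  invisible(x)
}

# cup (spherical cap) volume term shared by all tablet volumes, mm^3
cup_volume <- function(geom) (pi * geom$h / 6) * (3 * geom$D^2 / 4 + geom$h^2)

#' Tablet volume at a given cylindrical thickness
#'
#' Volume of the powder column or tablet: a cylinder of diameter D and
#' thickness t plus the punch-cup spherical-cap term,
#' V = pi D^2 t / 4 + (pi h / 6)(3 D^2 / 4 + h^2).
#'
#' @param geom A [tablet_geometry()].
#' @param t_mm Band (cylindrical) thickness in mm; vectorized, must be >= 0.
#' @return Volume in mm^3.
#' @examples
#' tablet_volume(tablet_geometry(8, 0), 2)  # 32*pi, cup term vanishes
#' @export
tablet_volume <- function(geom, t_mm) {
  stopifnot(inherits(geom, "tablet_geometry"))
  if (any(!is.finite(t_mm)) || any(t_mm < 0)) {
    stop("thickness `t_mm` must be finite and non-negative")
  }
  pi * geom$D^2 * t_mm / 4 + cup_volume(geom)
}

#' Die fill volume at a given dosing position
#'
#' The die cavity volume at fill: identical in form to [tablet_volume()]
#' evaluated at the dosing position (fill depth) t_fill.
#'
#' @inheritParams tablet_volume
#' @param t_fill_mm Dosing position / fill depth in mm.
#' @return Volume in mm^3.
#' @export
fill_volume <- function(geom, t_fill_mm) tablet_volume(geom, t_fill_mm)

#' Relative density of a powder column or tablet
#'
#' rho = W / (rho_t V): the solid fraction given tablet weight, blend true
#' density and occupied volume. Warns (does not fail) above 1, which can
#' occur transiently for noisy measurements.
#'
#' @param weight_mg Tablet weight in mg.
#' @param true_density_gcc Blend true density in g/cm^3 (= mg/mm^3).
#' @param volume_mm3 Occupied volume in mm^3.
#' @return Dimensionless relative density (solid fraction).
#' @export
relative_density <- function(weight_mg, true_density_gcc, volume_mm3) {
  if (any(!is.finite(weight_mg)) || any(weight_mg <= 0) ||
      any(!is.finite(true_density_gcc)) || any(true_density_gcc <= 0) ||
      any(!is.finite(volume_mm3)) || any(volume_mm3 <= 0)) {
    stop("weight, true density and volume must all be positive and finite")
  }
  rho <- weight_mg / (true_density_gcc * volume_mm3)
  if (any(rho > 1)) {
    warning("relative density above 1: check weights/volumes for consistency")
  }
  rho
}

#' Diametral tensile strength of a convex tablet (Pitt's relation)
#'
#' Converts a measured diametral breaking force (hardness) F to tensile
#' strength for round convex tablets:
#' sigma_t = (10 F / (pi D^2)) / (2.84 H/D - 0.126 H/t + 3.15 t/D + 0.01),
#' with overall thickness H = t_tablet + 2 h and band thickness t_tablet.
#'
#' @param hardness_N Breaking force F in N (vectorized, >= 0).
#' @param geom A [tablet_geometry()].
#' @param t_tablet_mm Tablet band thickness in mm (> 0).
#' @return Tensile strength in MPa; linear in `hardness_N`.
#' @export
pitt_tensile_strength <- function(hardness_N, geom, t_tablet_mm) {
  stopifnot(inherits(geom, "tablet_geometry"))
  if (any(!is.finite(hardness_N)) || any(hardness_N < 0)) {
    stop("`hardness_N` must be finite and non-negative")
  }
  if (any(!is.finite(t_tablet_mm)) || any(t_tablet_mm <= 0)) {
    stop("`t_tablet_mm` must be positive")
  }
  den <- pitt_denominator(geom, t_tablet_mm)
  if (any(den <= 0)) stop("degenerate tablet geometry: Pitt denominator <= 0")
  (10 * hardness_N / (pi * geom$D^2)) / den
}

pitt_denominator <- function(geom, t_tablet_mm) {
  H <- t_tablet_mm + 2 * geom$h
  2.84 * H / geom$D - 0.126 * H / t_tablet_mm + 3.15 * t_tablet_mm / geom$D + 0.01
}

#' Breaking force for a target tensile strength (inverse Pitt)
#'
#' Inverse of [pitt_tensile_strength()]; used by the campaign simulator to
#' turn a modeled tensile strength into a hardness reading.
#'
#' @param sigma_MPa Tensile strength in MPa.
#' @inheritParams pitt_tensile_strength
#' @return Breaking force in N.
#' @export
pitt_hardness <- function(sigma_MPa, geom, t_tablet_mm) {
  stopifnot(inherits(geom, "tablet_geometry"))
  sigma_MPa * pi * geom$D^2 * pitt_denominator(geom, t_tablet_mm) / 10
}

#' Die-filling efficacy coefficient
#'
#' The ratio eta = W / (rho_b V_fill) of realized tablet weight to the weight
#' of a perfectly filled die. Two model forms are supported:
#' * `"second_order"` (default):
#'   eta = xi1 + xi2 (nF/nT) + xi3 (tfill/D) + xi4 (tfill/D)^2 +
#'         xi5 (nF/nT)(tfill/D), with `xi = c(xi1..xi5)`;
#' * `"su_linear"` (legacy linear form):
#'   eta = 1 - xi1 (nT/nF) + xi2 (tfill/D), with `xi = c(xi1, xi2)`.
#'
#' @param xi Numeric coefficient vector: length 5 for `"second_order"`,
#'   length 2 for `"su_linear"`.
#' @param nF Feed-frame (paddle) speed, rpm.
#' @param nT Turret speed, rpm (> 0).
#' @param t_fill_mm Dosing position in mm (> 0).
#' @param D_mm Die diameter in mm.
#' @param form Model form, see above.
#' @return Filling efficacy eta (raw; clip to \[0, 1\] only at reporting time).
#' @export
filling_efficacy <- function(xi, nF, nT, t_fill_mm, D_mm = 8,
                             form = c("second_order", "su_linear")) {
  form <- match.arg(form)
  if (any(!is.finite(nT)) || any(nT <= 0)) stop("turret speed `nT` must be > 0")
  if (any(!is.finite(t_fill_mm)) || any(t_fill_mm <= 0)) {
    stop("`t_fill_mm` must be > 0")
  }
  tf <- t_fill_mm / D_mm
  if (form == "second_order") {
    stopifnot(length(xi) == 5L)
    xi[1] + xi[2] * (nF / nT) + xi[3] * tf + xi[4] * tf^2 + xi[5] * (nF / nT) * tf
  } else {
    stopifnot(length(xi) == 2L)
    if (any(!is.finite(nF)) || any(nF <= 0)) {
      stop("`nF` must be > 0 for the linear form")
    }
    1 - xi[1] * (nT / nF) + xi[2] * tf
  }
}

#' Tablet weight implied by a filling efficacy
#'
#' Inverts the efficacy definition: W = eta rho_b V_fill.
#'
#' @param eta Filling efficacy (dimensionless, >= 0).
#' @param bulk_density_gcc Blend bulk density in g/cm^3.
#' @param fill_volume_mm3 Die fill volume in mm^3.
#' @return Weight in mg.
#' @export
weight_from_efficacy <- function(eta, bulk_density_gcc, fill_volume_mm3) {
  if (any(!is.finite(eta)) || any(eta < 0) ||
      any(!is.finite(bulk_density_gcc)) || any(bulk_density_gcc < 0) ||
      any(!is.finite(fill_volume_mm3)) || any(fill_volume_mm3 < 0)) {
    stop("all arguments must be finite and non-negative")
  }
  eta * bulk_density_gcc * fill_volume_mm3
}

#' Kawakita punch force at a given in-die relative density
#'
#' Density-based Kawakita compaction model:
#' F = pi D^2 (rho - rho_c) / (4 b (rho (a - 1) + rho_c)),
#' where `a` is the total compressibility, `1/b` (MPa) the mean punch
#' pressure at half-maximal compression, and `rho_c` the critical (jamming)
#' relative density. Below jamming (rho <= rho_c) the force is zero; the
#' model has a singularity where the degree of compression
#' (rho - rho_c)/rho reaches `a`, which is an error.
#'
#' @param rho_in_die In-die relative density (vectorized).
#' @param a Total compressibility, in \[0, 1\].
#' @param inv_b Pressure at half-maximal compression 1/b, MPa (> 0).
#' @param rho_c Critical (jamming) relative density, in \[0, 1\].
#' @param D_mm Die diameter in mm.
#' @param units `"N"` (default) or `"kN"`.
#' @return Punch force, strictly increasing in `rho_in_die` on the valid
#'   domain.
#' @export
kawakita_force <- function(rho_in_die, a, inv_b, rho_c, D_mm = 8,
                           units = c("N", "kN")) {
  units <- match.arg(units)
  if (any(!is.finite(a)) || any(a <= 0) || any(a > 1)) stop("`a` must be in (0, 1]")
  if (any(!is.finite(inv_b)) || any(inv_b <= 0)) stop("`inv_b` must be > 0")
  if (any(!is.finite(rho_c)) || any(rho_c < 0) || any(rho_c > 1)) {
    stop("`rho_c` must be in [0, 1]")
  }
  den <- rho_in_die * (a - 1) + rho_c
  active <- rho_in_die > rho_c
  if (any(active & den <= 0)) {
    stop("Kawakita singularity: degree of compression (rho - rho_c)/rho >= a")
  }
  f <- (pi * D_mm^2 / 4) * inv_b * (rho_in_die - rho_c) / den
  f[!active] <- 0
  if (units == "kN") f <- f / 1000
  f
}

#' Elastic recovery at ejection
#'
#' eps_rho = eps0 ((rho - rho_c_eps) / (1 - rho_c_eps))^n for rho above the
#' recovery onset density rho_c_eps, and 0 below it. eps0 is the recovery at
#' zero porosity (rho = 1) and the exponent n generalizes the linear trend.
#'
#' @param rho_in_die In-die relative density (vectorized).
#' @param eps0 Elastic recovery at full compaction, in \[0, 1\].
#' @param rho_c_eps Recovery onset relative density, in \[0, 1).
#' @param n_exp Recovery exponent (> 0).
#' @return Recovery strain fraction.
#' @export
elastic_recovery <- function(rho_in_die, eps0, rho_c_eps, n_exp = 1) {
  if (any(!is.finite(rho_c_eps)) || any(rho_c_eps < 0) || any(rho_c_eps >= 1)) {
    stop("`rho_c_eps` must be in [0, 1)")
  }
  if (any(!is.finite(n_exp)) || any(n_exp <= 0)) stop("`n_exp` must be > 0")
  z <- pmax(0, (rho_in_die - rho_c_eps) / (1 - rho_c_eps))
  eps0 * z^n_exp
}

#' Out-of-die tablet relative density after elastic recovery
#'
#' rho_tablet = rho_in_die (1 - eps_rho).
#'
#' @param rho_in_die In-die relative density.
#' @param eps_rho Elastic recovery strain fraction, in \[0, 1).
#' @return Tablet relative density, <= `rho_in_die`.
#' @export
tablet_density <- function(rho_in_die, eps_rho) {
  if (any(!is.finite(eps_rho)) || any(eps_rho < 0) || any(eps_rho >= 1)) {
    stop("`eps_rho` must be in [0, 1)")
  }
  rho_in_die * (1 - eps_rho)
}

#' Leuenberger-type tensile strength of the ejected tablet
#'
#' sigma_t = sigma0 (1 - (1 - rho)/(1 - rho_c_sigma) exp(rho - rho_c_sigma)),
#' evaluated at the out-of-die density rho = rho_tablet; zero below the
#' strength onset density rho_c_sigma (no coherent tablet is formed there)
#' and sigma0 at zero porosity.
#'
#' @param rho_tablet Out-of-die tablet relative density (vectorized).
#' @param sigma0 Tensile strength at zero porosity, MPa (> 0).
#' @param rho_c_sigma Strength onset relative density, in \[0, 1).
#' @return Tensile strength in MPa (>= 0).
#' @export
leuenberger_tensile <- function(rho_tablet, sigma0, rho_c_sigma) {
  if (any(!is.finite(sigma0)) || any(sigma0 <= 0)) stop("`sigma0` must be > 0")
  if (any(!is.finite(rho_c_sigma)) || any(rho_c_sigma < 0) || any(rho_c_sigma >= 1)) {
    stop("`rho_c_sigma` must be in [0, 1)")
  }
  s <- sigma0 * (1 - (1 - rho_tablet) / (1 - rho_c_sigma) * exp(rho_tablet - rho_c_sigma))
  s[rho_tablet < rho_c_sigma] <- 0
  pmax(s, 0)
}

#' Press production rate
#'
#' mdot = Nd nT W: mass throughput of a rotary press with `Nd` die stations
#' turning at `nT` rpm and producing tablets of weight `W`.
#'
#' @param n_stations Number of die stations (>= 0).
#' @param nT Turret speed in rpm (>= 0).
#' @param weight_g Tablet weight in g.
#' @return Production rate in g/min.
#' @export
production_rate <- function(n_stations, nT, weight_g) {
  if (any(n_stations < 0) || any(nT < 0) || any(weight_g < 0)) {
    stop("all arguments must be non-negative")
  }
  n_stations * nT * weight_g
}
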