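# Latin-hypercube campaign design and forward simulation of run tables from
# the published fitted stage models. The simulator stands in for the
# undeposited experimental data: it reproduces the two campaign designs
# (lubricant: 20 runs, glidant: 30 runs) over their stated input ranges.

#' Campaign specification
#'
#' Input ranges, run count and noise levels of a simulated tableting
#' campaign. Defaults reproduce the two experimental campaigns: MgSt -
#' concentration 0-2% w/w, mixing 11-30 min, turret 11-22 rpm, dosing
#' 9-13 mm, 20 runs; CS - concentration 0-0.2% w/w, mixing 10-30 min,
#' turret 25-35 rpm, dosing 7-11 mm, 30 runs. The feed-frame speed has no
#' stated experimental range and is held at 30 rpm by default.
#'
#' @param campaign `"mgst"` or `"cs"`.
#' @param n_runs Number of runs (defaults 20 / 30).
#' @param ranges Named list of `c(lower, upper)` for `conc`, `tmix`,
#'   `turret`, `dosing`; defaults as above.
#' @param tablets_per_run Tablets measured per steady-state run (default 50).
#' @param noise Named coefficients of variation for the measured responses:
#'   `bulk_density`, `weight`, `force`, `hardness` (defaults 1%, 1%, 3%,
#'   5%). Set all to 0 for a noise-free campaign.
#' @param nF Feed-frame speed, rpm.
#' @param rho_in_max Physical cap on the in-die relative density: runs whose
#'   nominal fill would compact beyond this solid fraction at the nominal
#'   in-die thickness have their in-die thickness relaxed (force-limited
#'   press), recorded per run in the run table.
#' @param t_in_die_mm Nominal in-die thickness, mm (default 2.44).
#' @param densities Component true densities, g/cm^3, for
#'   [true_density_mixture()]: `apap`, `mcc`, `mgst`, `cs` (package
#'   defaults, not measured values).
#' @param api_fraction Mass fraction of API in the blend (default 0.10).
#' @return An object of class `campaign_spec`.
#' @export
campaign_spec <- function(campaign = c("mgst", "cs"), n_runs = NULL,
                          ranges = NULL, tablets_per_run = 50L,
                          noise = c(bulk_density = 0.01, weight = 0.01,
                                    force = 0.03, hardness = 0.05),
                          nF = 30, rho_in_max = 0.95, t_in_die_mm = 2.44,
                          densities = c(apap = 1.293, mcc = 1.56,
                                        mgst = 1.04, cs = 2.2),
                          api_fraction = 0.10) {
  campaign <- match.arg(campaign)
  defaults <- if (campaign == "mgst") {
    list(n_runs = 20L, ranges = list(conc = c(0, 2), tmix = c(11, 30),
                                     turret = c(11, 22), dosing = c(9, 13)))
  } else {
    list(n_runs = 30L, ranges = list(conc = c(0, 0.2), tmix = c(10, 30),
                                     turret = c(25, 35), dosing = c(7, 11)))
  }
  n_runs <- as.integer(n_runs %||% defaults$n_runs)
  if (n_runs < 2) stop("`n_runs` must be >= 2")
  ranges <- utils::modifyList(defaults$ranges, ranges %||% list())
  for (r in ranges) stopifnot(length(r) == 2L, r[1] < r[2])
  full <- c(bulk_density = 0.01, weight = 0.01, force = 0.03, hardness = 0.05)
  full[names(noise)] <- noise
  structure(list(campaign = campaign, n_runs = n_runs, ranges = ranges,
                 tablets_per_run = as.integer(tablets_per_run), noise = full,
                 nF = nF, rho_in_max = rho_in_max, t_in_die_mm = t_in_die_mm,
                 densities = densities, api_fraction = api_fraction),
            class = "campaign_spec")
}

#' Latin-hypercube campaign design
#'
#' Samples the four upstream inputs (concentration, mixing time, turret
#' speed, dosing position) with a Latin hypercube over the campaign ranges:
#' each column places exactly one run in each of `n_runs` equal-probability
#' strata.
#'
#' @param spec A [campaign_spec()].
#' @param seed Integer seed; the design is reproducible given the seed.
#' @return A data frame with `n_runs` rows and columns `conc`, `tmix`,
#'   `turret`, `dosing`, all strictly inside their ranges.
#' @export
lhs_design <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "campaign_spec"))
  set.seed(seed)
  u <- lhs::randomLHS(spec$n_runs, 4L)
  out <- mapply(function(uu, rg) rg[1] + uu * (rg[2] - rg[1]),
                as.data.frame(u), spec$ranges)
  out <- as.data.frame(out)
  names(out) <- names(spec$ranges)
  out
}

#' True density of a powder blend
#'
#' Inverse-mass-weighted harmonic mean of the component true densities:
#' 1/rho_t = sum(w_i / rho_i) for mass fractions w_i summing to 1.
#'
#' @param fractions Named mass fractions (must sum to 1 within 1e-8).
#' @param densities Named component true densities, g/cm^3, covering
#'   `names(fractions)`.
#' @return Blend true density in g/cm^3.
#' @examples
#' true_density_mixture(c(a = 0.5, b = 0.5), c(a = 1, b = 2))  # 4/3
#' @export
true_density_mixture <- function(fractions, densities) {
  stopifnot(all(names(fractions) %in% names(densities)))
  if (abs(sum(fractions) - 1) > 1e-8) stop("mass fractions must sum to 1")
  if (any(fractions < 0)) stop("mass fractions must be non-negative")
  1 / sum(fractions / densities[names(fractions)])
}

# blend true density as a function of excipient concentration (% w/w)
blend_true_density <- function(conc_pct, spec) {
  exc <- if (spec$campaign == "mgst") "mgst" else "cs"
  vapply(conc_pct, function(cc) {
    w <- c(apap = spec$api_fraction, mcc = 1 - spec$api_fraction - cc / 100)
    w[exc] <- cc / 100
    true_density_mixture(w, spec$densities)
  }, numeric(1))
}

#' Simulate a tableting campaign from the published fitted models
#'
#' Runs the full forward model for each design point: blend true and bulk
#' density, filling efficacy and tablet weight, in-die relative density,
#' Kawakita punch force, elastic recovery, out-of-die density/thickness,
#' Leuenberger tensile strength and the corresponding hardness reading.
#' Multiplicative Gaussian noise (per-response CV from the spec) is applied
#' to the measured responses; `noise = 0` reproduces the deterministic
#' forward model exactly. Runs whose nominal fill would exceed
#' `spec$rho_in_max` at the nominal in-die thickness are force-limited: the
#' in-die thickness is relaxed so the cap holds (see [campaign_spec()]).
#'
#' @param spec A [campaign_spec()].
#' @param seed Integer seed (design and noise).
#' @param truth Generating stage models, default [ground_truth()] for the
#'   campaign.
#' @param geom A [tablet_geometry()].
#' @param design Optional design data frame (from [lhs_design()]); by
#'   default one is drawn with `seed`.
#' @return A run-table data frame (see [read_run_table()] for the schema)
#'   with attributes `spec`, `seed` and `tablets` (per-tablet measurements:
#'   `tablets_per_run` rows per run for weight, thickness and hardness).
#' @export
simulate_campaign <- function(spec, seed = 1L, truth = NULL,
                              geom = tablet_geometry(), design = NULL) {
  stopifnot(inherits(spec, "campaign_spec"))
  truth <- truth %||% ground_truth(spec$campaign)
  norm <- campaign_norm(spec$campaign)
  design <- design %||% lhs_design(spec, seed = seed)
  n <- nrow(design)
  set.seed(seed + 1L)

  rho_t <- blend_true_density(design$conc, spec)
  phi <- param_function(truth$bulk_density, "phi", design$conc, design$tmix,
                        norm)
  rho_b <- phi * rho_t

  wcomb <- truth$weight$combination
  eta <- as.numeric(weight_design(wcomb, data.frame(
    speed_ratio = spec$nF / design$turret,
    fill_ratio = design$dosing / geom$D)) %*%
      weight_theta(wcomb, truth$weight$theta)) +
    if (wcomb$weight_form == "eq21") 1 else 0
  Vfill <- fill_volume(geom, design$dosing)
  W <- weight_from_efficacy(eta, rho_b, Vfill)          # mg

  # in-die thickness: nominal, relaxed where the press would exceed the cap
  A <- pi * geom$D^2 / 4
  t_in <- rep(spec$t_in_die_mm, n)
  rho_in <- W / (rho_t * tablet_volume(geom, t_in))
  over <- rho_in > spec$rho_in_max
  if (any(over)) {
    t_in[over] <- (W[over] / (rho_t[over] * spec$rho_in_max) -
                     cup_volume(geom)) / A
    rho_in[over] <- spec$rho_in_max
  }

  a_par <- param_function(truth$compaction, "a", design$conc, design$tmix, norm)
  invb <- param_function(truth$compaction, "inv_b", design$conc, design$tmix,
                         norm)
  rho_c <- param_function(truth$compaction, "rho_c", design$conc, design$tmix,
                          norm)
  F_kN <- kawakita_force(rho_in, a_par, invb, rho_c, geom$D, units = "kN")

  eps0 <- param_function(truth$elastic_recovery, "eps0", design$conc,
                         design$tmix, norm)
  rce <- param_function(truth$elastic_recovery, "rho_c_eps", design$conc,
                        design$tmix, norm)
  eps <- elastic_recovery(rho_in, eps0, rce,
                          truth$elastic_recovery$theta[["n"]])
  rho_tab <- tablet_density(rho_in, eps)
  t_tab <- (W / (rho_t * rho_tab) - cup_volume(geom)) / A

  sig0 <- param_function(truth$tensile_strength, "sigma0", design$conc,
                         design$tmix, norm)
  rcs <- param_function(truth$tensile_strength, "rho_c_sigma", design$conc,
                        design$tmix, norm)
  sigma_t <- leuenberger_tensile(rho_tab, sig0, rcs)
  hardness <- pitt_hardness(sigma_t, geom, t_tab)

  cv <- spec$noise
  jitter <- function(x, cvx) if (cvx > 0) x * (1 + stats::rnorm(n, 0, cvx)) else x
  runs <- data.frame(
    run_id = seq_len(n),
    campaign = spec$campaign,
    concentration_pct = design$conc,
    mixing_time_min = design$tmix,
    turret_rpm = design$turret,
    feedframe_rpm = spec$nF,
    dosing_mm = design$dosing,
    bulk_density_gcc = jitter(rho_b, cv[["bulk_density"]]),
    true_density_gcc = rho_t,
    mean_weight_mg = jitter(W, cv[["weight"]]),
    in_die_thickness_mm = t_in,
    tablet_thickness_mm = t_tab,
    tablet_diameter_mm = geom$D,
    compaction_force_kN = jitter(F_kN, cv[["force"]]),
    hardness_N = jitter(hardness, cv[["hardness"]])
  )
  if (any(runs[, 8:15] < 0)) stop("noise drew a negative response; lower CVs")

  m <- spec$tablets_per_run
  tjit <- function(x, cvx) {
    v <- rep(x, each = m)
    if (cvx > 0) v * (1 + stats::rnorm(n * m, 0, cvx)) else v
  }
  tablets <- data.frame(
    run_id = rep(runs$run_id, each = m),
    tablet = rep(seq_len(m), times = n),
    weight_mg = tjit(runs$mean_weight_mg, cv[["weight"]]),
    thickness_mm = rep(t_tab, each = m),
    diameter_mm = geom$D,
    hardness_N = tjit(runs$hardness_N, cv[["hardness"]])
  )
  attr(runs, "spec") <- spec
  attr(runs, "seed") <- seed
  attr(runs, "tablets") <- tablets
  runs
}

#' Write a simulated campaign to disk
#'
#' Emits `runs.csv` (run-level table), `tablets.csv` (per-tablet
#' measurements) and `metadata.json` (campaign spec, seed, package version)
#' into a directory.
#'
#' @param spec A [campaign_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param truth,geom Passed to [simulate_campaign()].
#' @return Invisibly, the run table.
#' @export
emit_campaign <- function(spec, dir, seed = 1L, truth = NULL,
                          geom = tablet_geometry()) {
  runs <- simulate_campaign(spec, seed = seed, truth = truth, geom = geom)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_run_table(runs, file.path(dir, "runs.csv"))
  utils::write.csv(attr(runs, "tablets"), file.path(dir, "tablets.csv"),
                   row.names = FALSE)
  meta <- list(campaign = spec$campaign, n_runs = spec$n_runs,
               ranges = spec$ranges, tablets_per_run = spec$tablets_per_run,
               noise = as.list(spec$noise), nF = spec$nF,
               rho_in_max = spec$rho_in_max, t_in_die_mm = spec$t_in_die_mm,
               seed = seed,
               package_version = as.character(utils::packageVersion("tabletrom")))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(runs)
}
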