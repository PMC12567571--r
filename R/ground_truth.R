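# Published best-fit stage models for the two experimental campaigns:
# magnesium stearate (lubricant, 20 runs) and colloidal silica (glidant,
# 30 runs). These parameter sets are the ground truth used by the campaign
# simulator; values are transcribed from the source fits and cross-checked.

#' Published fitted stage models for a campaign
#'
#' Returns the complete fitted model set (combination + parameter vector per
#' stage) for the magnesium stearate or colloidal silica campaign. These are
#' the generating models of [simulate_campaign()].
#'
#' Stage models (MgSt): bulk-density packing fraction variant 13,
#' second-order filling efficacy with xi1 = xi5 = 0, compaction triple
#' (9,3,3) with constant a, elastic recovery (6,9) with exponent n = 2.928,
#' tensile strength (3,3). (CS): bulk density variant 7, filling efficacy
#' with xi5 = 0, constant compaction (9,9,9), constant recovery (9,9) with
#' n = 1, tensile strength (8,8).
#'
#' @param campaign `"mgst"` or `"cs"`.
#' @return A named list of stage models; each element holds `combination`
#'   (a [model_combination()]) and `theta` (named parameter vector as used
#'   by [stage_predict()]).
#' @export
ground_truth <- function(campaign = c("mgst", "cs")) {
  campaign <- match.arg(campaign)
  if (campaign == "mgst") {
    list(
      bulk_density = list(
        combination = model_combination("bulk_density", c(phi = 13)),
        theta = c(phi.p1 = 14.21, phi.p4 = 0.17, phi.q1 = 51.58,
                  phi.q5 = 0.17)),
      weight = list(
        combination = model_combination("weight", weight_form = "eq23",
                                        zeroed = c("xi1", "xi5")),
        theta = c(xi2 = 0.076, xi3 = 1.281, xi4 = -0.533)),
      compaction = list(
        combination = model_combination("compaction",
                                        c(a = 9, inv_b = 3, rho_c = 3)),
        theta = c(a.p4 = 0.735,
                  inv_b.p1 = 0.00174, inv_b.p4 = 0.033, inv_b.q1 = 220.6,
                  inv_b.q2 = 0.0034,
                  rho_c.p1 = 264.2, rho_c.p4 = 0.365, rho_c.q1 = 915.4,
                  rho_c.q2 = 1.02,
                  rX = 0.85, rY = 8.76)),
      elastic_recovery = list(
        combination = model_combination("elastic_recovery",
                                        c(eps0 = 6, rho_c_eps = 9)),
        theta = c(eps0.p1 = 14.29, eps0.p4 = 9.32e-9, eps0.q1 = 117.11,
                  eps0.q3 = 4.99e-7,
                  rho_c_eps.p4 = 0.288, n = 2.928)),
      tensile_strength = list(
        combination = model_combination("tensile_strength",
                                        c(sigma0 = 3, rho_c_sigma = 3)),
        theta = c(sigma0.p1 = 335.0, sigma0.p4 = 9.44, sigma0.q1 = 125.1,
                  sigma0.q2 = 0.40,
                  rho_c_sigma.p1 = 5.40, rho_c_sigma.p4 = 0.649,
                  rho_c_sigma.q1 = 10.85, rho_c_sigma.q2 = 1.77e-7,
                  rX = 1.92, rY = 1.94))
    )
  } else {
    list(
      bulk_density = list(
        combination = model_combination("bulk_density", c(phi = 7)),
        theta = c(phi.p1 = 0.279, phi.p4 = 0.242, phi.q1 = 0.566,
                  rX = 0.325, rY = 0.222)),
      weight = list(
        combination = model_combination("weight", weight_form = "eq23",
                                        zeroed = "xi5"),
        theta = c(xi1 = 0.0862, xi2 = -0.0472, xi3 = 2.1036, xi4 = -1.1375)),
      compaction = list(
        combination = model_combination("compaction",
                                        c(a = 9, inv_b = 9, rho_c = 9)),
        theta = c(a.p4 = 0.824, inv_b.p4 = 0.0104, rho_c.p4 = 0.1977)),
      elastic_recovery = list(
        combination = model_combination("elastic_recovery",
                                        c(eps0 = 9, rho_c_eps = 9)),
        theta = c(eps0.p4 = 0.1098, rho_c_eps.p4 = 0.446, n = 1.0)),
      tensile_strength = list(
        combination = model_combination("tensile_strength",
                                        c(sigma0 = 8, rho_c_sigma = 8)),
        theta = c(sigma0.p1 = 161.0, sigma0.p4 = 10.7, sigma0.q1 = 17.18,
                  rho_c_sigma.p1 = 13.80, rho_c_sigma.p4 = 0.53,
                  rho_c_sigma.q1 = 23.80))
    )
  }
}

#' Evaluate a coupled parameter function of a stage model
#'
#' Convenience accessor: evaluates one rational parameter function (e.g.
#' `sigma0` or `rho_c`) of a stage model at given concentration and mixing
#' time.
#'
#' @param stage_model One element of [ground_truth()] or an equivalent
#'   list with `combination` and `theta`.
#' @param fun Coupled function role name, see [stage_funs()].
#' @param conc Concentration(s), % w/w.
#' @param tmix Mixing time(s), min.
#' @param norm A [norm_spec()].
#' @return The parameter function value(s).
#' @export
param_function <- function(stage_model, fun, conc, tmix, norm) {
  comb <- stage_model$combination
  theta <- stage_model$theta
  stopifnot(fun %in% names(comb$variants))
  rX <- theta_get(theta, "rX"); rY <- theta_get(theta, "rY")
  X <- normalize_cpp(conc, norm$c_max, rX)
  Y <- normalize_cpp(tmix, norm$t_max, rY)
  v <- rational_variant(comb$variants[[fun]])
  eval_rational_raw(v, theta_funs(comb, theta)[[fun]], X, Y)
}
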