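# Fitting, AIC ranking, overfit flagging, bootstrap and the sequential fit.

test_that("the information criterion matches both branches by hand", {
  # SSE = n makes the log term vanish: AIC = 2 Np
  expect_equal(rom_aic(40, 40, 3), 6)
  # small-sample correction: 6 + 2*3*4/(20-3-1)
  expect_equal(rom_aic(20, 20, 3), 7.5)
  # n = 30 uses the uncorrected branch (boundary inclusive)
  expect_equal(rom_aic(30, 30, 2), 4)
  expect_gt(rom_aic(29, 29, 2), rom_aic(29, 29, 2, mse_floor = 0) - 1e-12)
  expect_identical(rom_aic(0, 20, 3), -Inf)
  # the correction denominator must be positive
  expect_error(rom_aic(5, 5, 4), "Np \\+ 1")
})

test_that("R squared behaves at its anchor points", {
  y <- c(1, 2, 4)
  expect_equal(r_squared(0, y), 1)
  # constant prediction at the mean response gives exactly 0
  expect_equal(r_squared(sum((y - mean(y))^2), y), 0)
  # 3-point toy dataset against fixed predictions, SSE by hand
  pred <- c(1.5, 2.5, 3.5)
  expect_equal(r_squared(sum((y - pred)^2), y), 1 - 0.75 / (14 / 3))
})

test_that("zero-noise campaigns give zero residual under the true models", {
  for (camp in c("mgst", "cs")) {
    runs <- cached_campaign(camp)
    tr <- ground_truth(camp)
    norm <- campaign_norm(camp)
    for (st in c("bulk_density", "weight", "compaction",
                 "elastic_recovery", "tensile_strength")) {
      ds <- stage_data(runs, st, norm)
      sse <- stage_sse(ds, tr[[st]]$combination, tr[[st]]$theta)
      expect_lt(sse / ds$sst, 1e-16)
    }
  }
})

test_that("a simple generating model is recovered from scratch within 1%", {
  # glidant tensile-strength truth: paired simplest first-degree variants
  ds <- cached_stage_data("cs", "tensile_strength")
  truth <- ground_truth("cs")$tensile_strength
  fit <- fit_combination(ds, truth$combination, seed = 1, n_starts = 24)
  expect_lt(fit$sse / fit$sst, 1e-10)
  expect_equal(fit$theta[names(truth$theta)], truth$theta, tolerance = 0.01)
  expect_true(fit$feasible)
})

test_that("from-scratch recovery attains numerical zero where identifiable", {
  cases <- list(c("mgst", "bulk_density"), c("cs", "bulk_density"),
                c("mgst", "weight"), c("cs", "weight"),
                c("mgst", "elastic_recovery"), c("cs", "elastic_recovery"),
                c("cs", "compaction"), c("mgst", "tensile_strength"))
  for (cs in cases) {
    ds <- cached_stage_data(cs[1], cs[2])
    truth <- ground_truth(cs[1])[[cs[2]]]
    fit <- fit_combination(ds, truth$combination, seed = 2, n_starts = 32)
    expect_lt(fit$sse / fit$sst, 1e-8)
  }
})

test_that("constant-response data select the constant combination", {
  # glidant compaction truth is constant in (c, t): the all-constant triple
  # must be ranked first against more flexible rivals
  ds <- cached_stage_data("cs", "compaction")
  lib <- list(
    model_combination("compaction", c(a = 9, inv_b = 9, rho_c = 9)),
    model_combination("compaction", c(a = 9, inv_b = 8, rho_c = 8)),
    model_combination("compaction", c(a = 8, inv_b = 9, rho_c = 8))
  )
  sel <- select_model(ds, library = lib, seed = 1, n_starts = 10)
  expect_equal(sel$ranking$model[1], "compaction: (9,9,9)")
  expect_false(is.unsorted(sel$ranking$AIC))
})

test_that("fits are deterministic given the seed", {
  ds <- cached_stage_data("cs", "bulk_density")
  comb <- ground_truth("cs")$bulk_density$combination
  f1 <- fit_combination(ds, comb, seed = 7, n_starts = 8)
  f2 <- fit_combination(ds, comb, seed = 7, n_starts = 8)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$aic, f2$aic)
})

test_that("stored AIC is recomputable from SSE, n and Np", {
  ds <- cached_stage_data("mgst", "bulk_density")
  for (i in c(8, 9, 13)) {
    f <- fit_combination(ds, model_combination("bulk_density", c(phi = i)),
                         seed = 1, n_starts = 8)
    expect_identical(rom_aic(f$sse, f$n, f$np, mse_floor = f$mse_floor), f$aic)
  }
})

test_that("nested variants have non-increasing optimal SSE", {
  # variant 8 is nested in 7, 7 in 5, 5 in 1; fit a noisy bulk response
  runs <- cached_campaign("mgst", seed = 21,
                          noise = c(bulk_density = 0.01, weight = 0,
                                    force = 0, hardness = 0))
  ds <- stage_data(runs, "bulk_density", campaign_norm("mgst"))
  sse <- vapply(c(8, 7, 5, 1), function(i) {
    fit_combination(ds, model_combination("bulk_density", c(phi = i)),
                    seed = 3, n_starts = 24)$sse
  }, numeric(1))
  tol <- 1e-6 * ds$sst
  expect_true(all(diff(sse) <= tol))
})

test_that("overfit flagging compares magnitudes to the p4 scale", {
  ds <- cached_stage_data("cs", "tensile_strength")
  truth <- ground_truth("cs")$tensile_strength
  fit <- fit_combination(ds, truth$combination, seed = 1, n_starts = 6,
                         init = truth$theta)
  expect_false(fit$overfit)
  bloated <- fit
  bloated$theta[["rho_c_sigma.q1"]] <- 1e7
  expect_true(overfit_flag(bloated))
  expect_false(overfit_flag(fit, threshold = 1e3))
})

test_that("bootstrap intervals contain the estimate and are reproducible", {
  runs <- cached_campaign("cs", seed = 9,
                          noise = c(bulk_density = 0, weight = 0,
                                    force = 0.03, hardness = 0))
  ds <- stage_data(runs, "compaction", campaign_norm("cs"))
  comb <- ground_truth("cs")$compaction$combination
  fit <- fit_combination(ds, comb, seed = 1, n_starts = 6)
  ci <- bootstrap_ci(ds, fit, B = 60, seed = 5, n_starts = 2)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  ci2 <- bootstrap_ci(ds, fit, B = 60, seed = 5, n_starts = 2)
  expect_identical(ci, ci2)
  # true constants are covered at this noise level
  truth <- ground_truth("cs")$compaction$theta
  for (nm in names(truth)) {
    row <- ci[ci$parameter == nm, ]
    expect_true(row$lower <= truth[[nm]] && truth[[nm]] <= row$upper)
  }
  expect_warning(bootstrap_ci(ds, fit, B = 1, seed = 1, n_starts = 1),
                 "degenerate")
})

test_that("bootstrap intervals collapse in the zero-noise limit", {
  comb <- ground_truth("cs")$compaction$combination
  width <- vapply(c(0.06, 0), function(cv) {
    runs <- cached_campaign("cs", seed = 9,
                            noise = c(bulk_density = 0, weight = 0,
                                      force = cv, hardness = 0))
    ds <- stage_data(runs, "compaction", campaign_norm("cs"))
    fit <- fit_combination(ds, comb, seed = 1, n_starts = 4)
    ci <- bootstrap_ci(ds, fit, B = 30, seed = 5, n_starts = 2)
    mean((ci$upper - ci$lower) / pmax(ci$estimate, 1e-8))
  }, numeric(1))
  # every resample of exact data refits exactly: degenerate intervals
  expect_lt(width[2], 1e-6)
  expect_gt(width[1], width[2])
})

test_that("the sequential campaign fit threads the onset-density ordering", {
  runs <- cached_campaign("cs")
  tr <- ground_truth("cs")
  libs <- list(
    bulk_density = list(tr$bulk_density$combination,
                        model_combination("bulk_density", c(phi = 9))),
    weight = list(tr$weight$combination,
                  model_combination("weight", weight_form = "eq21")),
    compaction = list(tr$compaction$combination,
                      model_combination("compaction",
                                        c(a = 9, inv_b = 8, rho_c = 8))),
    elastic_recovery = list(tr$elastic_recovery$combination),
    tensile_strength = list(tr$tensile_strength$combination,
                            model_combination("tensile_strength",
                                              c(sigma0 = 9, rho_c_sigma = 9)))
  )
  cf <- sequential_campaign_fit(runs, "cs", seed = 1, n_starts = 10,
                                libraries = libs)
  expect_s3_class(cf, "rom_campaign_fit")
  # generating models win their stages on noise-free data
  expect_equal(format(cf$best$bulk_density$combination), "bulk_density: (7)")
  expect_equal(format(cf$best$compaction$combination), "compaction: (9,9,9)")
  # staged bounds increase along the chain: rho_c < rho_c_eps onset bounds
  expect_gt(cf$rho_lower[["rho_c_eps"]], 0.1)
  expect_gt(cf$rho_lower[["rho_c_sigma"]], cf$rho_lower[["rho_c_eps"]] - 0.05)
  # fitted onset densities respect the physical ordering
  rc <- cf$best$compaction$theta[["rho_c.p4"]]
  rce <- cf$best$elastic_recovery$theta[["rho_c_eps.p4"]]
  rcs <- cf$best$tensile_strength$theta[["rho_c_sigma.p4"]]
  expect_true(rc < rce && rce < rcs)
})

test_that("datasets too small for a combination are rejected", {
  runs <- cached_campaign("cs")[1:6, ]
  ds <- stage_data(runs, "tensile_strength", campaign_norm("cs"))
  expect_error(fit_combination(ds, ground_truth("cs")$tensile_strength$combination),
               "too small")
})
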