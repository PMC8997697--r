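test_that("compute_icer reproduces the worked base-case arithmetic", {
  # headline table values: usual care (4745, 3.405) vs reduction (4560, 3.343)
  cea <- compute_icer(4745, 3.405, 4560, 3.343)
  expect_equal(cea$delta_cost, 185)
  expect_equal(cea$delta_qaly, 0.062)
  expect_equal(cea$label, "tradeoff")
  expect_equal(cea$icer, 185 / 0.062, tolerance = 1e-12)  # ~2983.9
})

test_that("compute_icer labels dominance and equivalence, antisymmetrically", {
  expect_equal(compute_icer(100, 2.0, 100, 2.0)$label, "equivalent")
  expect_equal(compute_icer(90, 2.1, 100, 2.0)$label, "dominant")
  expect_equal(compute_icer(100, 2.0, 90, 2.1)$label, "dominated")
  # antisymmetry: swapping strategies flips labels and preserves |ICER|
  a <- compute_icer(4745, 3.405, 4560, 3.343)
  b <- compute_icer(4560, 3.343, 4745, 3.405)
  expect_equal(abs(a$icer), abs(b$icer), tolerance = 1e-12)
  expect_equal(b$delta_cost, -a$delta_cost)
  expect_equal(b$delta_qaly, -a$delta_qaly)
  flip <- c(dominant = "dominated", dominated = "dominant",
            tradeoff = "tradeoff", equivalent = "equivalent")
  for (pair in list(c(90, 2.1, 100, 2.0), c(100, 2.0, 90, 2.1),
                    c(10, 1, 20, 2))) {
    x <- compute_icer(pair[1], pair[2], pair[3], pair[4])$label
    y <- compute_icer(pair[3], pair[4], pair[1], pair[2])$label
    expect_equal(unname(flip[x]), y)
  }
})

test_that("PSA is seeded-reproducible and degenerates correctly when fixed", {
  p <- default_parameters()
  # all specs fixed: every iteration identical
  p_fixed <- p
  p_fixed$psa <- lapply(p_fixed$psa, function(e) {
    e$spec <- fit_distribution(e$spec$point, family = "fixed"); e
  })
  cfg <- simulation_config(n_patients = 400, seed = 42)
  psa_f <- run_psa(p_fixed, cfg, n_iterations = 4, fresh_cohort = FALSE)
  expect_equal(var(psa_f$delta_cost), 0)
  expect_equal(var(psa_f$delta_qaly), 0)
  # same master seed twice: identical clouds
  psa1 <- run_psa(p, cfg, n_iterations = 5)
  psa2 <- run_psa(p, cfg, n_iterations = 5)
  expect_equal(as.data.frame(psa1), as.data.frame(psa2))
  expect_equal(nrow(psa1), 5)
})

test_that("CEAC probabilities follow net monetary benefit and sum to one", {
  # single iteration at the headline increments
  psa <- data.frame(delta_cost = 185, delta_qaly = 0.062)
  ceac <- compute_ceac(psa, wtp_grid = c(0, 20000))
  # NMB difference 20,000 x 0.062 - 185 = 1,055 > 0: usual care certain
  expect_equal(ceac$p_usual_care[ceac$wtp == 20000], 1)
  # at lambda = 0 preference is by cost alone (usual care costlier)
  expect_equal(ceac$p_usual_care[ceac$wtp == 0], 0)
  expect_equal(ceac$p_usual_care + ceac$p_reduction, rep(1, 2))
  # symmetric cloud about the origin: probability one half everywhere
  sym <- data.frame(delta_cost = c(10, -10), delta_qaly = c(0.01, -0.01))
  ceac_s <- compute_ceac(sym, wtp_grid = c(0, 5000, 30000))
  expect_equal(ceac_s$p_usual_care, rep(0.5, 3))
  # monotone non-decreasing in WTP when the QALY gain has constant sign
  set.seed(13)
  cloud <- data.frame(delta_cost = rnorm(200, 185, 60),
                      delta_qaly = abs(rnorm(200, 0.06, 0.02)))
  curve <- compute_ceac(cloud, wtp_grid = seq(0, 50000, by = 2500))
  expect_true(all(diff(curve$p_usual_care) >= 0))
  expect_equal(curve$p_usual_care + curve$p_reduction,
               rep(1, nrow(curve)))
  expect_error(compute_ceac(cloud, numeric(0)), "non-empty")
})

test_that("threshold_search converges on a linear closed-form stub", {
  th <- threshold_search(NULL, "stub", wtp = 20000, bracket = c(0, 10),
                         icer_fn = function(x) 10000 * x, tol_icer = 1)
  expect_equal(th$threshold, 2, tolerance = 1e-3)
  expect_equal(th$icer_at_threshold, 20000, tolerance = 1)
  # stability under bracket refinement around the found point
  th2 <- threshold_search(NULL, "stub", wtp = 20000,
                          bracket = c(th$threshold * 0.9,
                                      th$threshold * 1.1),
                          icer_fn = function(x) 10000 * x, tol_icer = 1)
  expect_equal(th2$threshold, th$threshold, tolerance = 1e-3)
  expect_error(threshold_search(NULL, "stub", wtp = 20000,
                                bracket = c(3, 10),
                                icer_fn = function(x) 10000 * x),
               "sign")
})

test_that("threshold_search moves the model ICER to the willingness-to-pay", {
  # searched on the deprescribing utility gain: deterministic fixed-seed
  # evaluations, small cohort for speed, loose ICER tolerance to match
  p <- default_parameters()
  cfg <- simulation_config(n_patients = 4000, seed = 37)
  th <- threshold_search(p, "utility.deprescribe_utility_gain",
                         wtp = 20000, bracket = c(0, 0.2), config = cfg,
                         tol_icer = 500)
  expect_gt(th$threshold, 0)
  expect_lt(abs(th$icer_at_threshold - 20000), 500)
})

test_that("scenario runner applies overrides, subgroups and horizon changes", {
  p <- default_parameters()
  cfg <- simulation_config(n_patients = 4000, seed = 51)
  rr_one <- list(params = list("treatment_effect.rr.chd" = 1,
                               "treatment_effect.rr.stroke_tia" = 1,
                               "treatment_effect.rr.hf" = 1,
                               "treatment_effect.rr.sae" = 1,
                               "treatment_effect.rr.minor" = 1,
                               "costs.safety_visit_cost" = 0,
                               "costs.reinstatement_visit_cost" = 0,
                               "costs.cost_per_drug_per_cycle" = 0))
  res <- run_scenarios(p, list(
    null = rr_one,
    effect_1y = list(params = list(
      "treatment_effect.effect_duration_years" = 1)),
    lifetime = list(),
    horizon_5y = list(config = list(max_horizon_years = 5)),
    frail_only = list(subset = "frailty == 'frail'")
  ), cfg)
  expect_equal(nrow(res), 5)
  # the null scenario removes every arm difference exactly (CRN)
  null_row <- res[res$scenario == "null", ]
  expect_equal(null_row$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(null_row$delta_cost, 0, tolerance = 1e-12)
  # one-year effect loses fewer QALYs than a lifetime effect
  expect_lt(res$delta_qaly[res$scenario == "effect_1y"],
            res$delta_qaly[res$scenario == "lifetime"])
  # five-year horizon bounded by the 5-year discounted annuity
  bound <- sum(0.25 * 1.035^(-(0:19 + 0.5) / 4))
  expect_lte(res$qaly_usual[res$scenario == "horizon_5y"], bound)
  expect_lte(res$qaly_reduction[res$scenario == "horizon_5y"], bound)
  expect_lt(res$n[res$scenario == "frail_only"], 4000)
  expect_error(run_scenarios(p, list(bad = list(params = list(
    "no.such.path" = 1))), cfg), "unknown")
})
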