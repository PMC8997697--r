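test_that("defaults carry the published base-case values and validate", {
  p <- default_parameters()
  expect_s3_class(p, "deprescr_params")
  expect_equal(p$event_risks$sae_annual_risk, 0.0174)
  expect_equal(p$event_risks$hf_annual_risk[["85-89"]], 0.0358)
  expect_equal(p$treatment_effect$rr[["hf"]], 1.290)
  expect_equal(p$mortality$smr[["stroke"]], 2.72)
  expect_equal(p$utility$baseline, 0.769)
  # every event-type fraction table sums to one exactly after normalisation
  for (tab in c("chd_type_fractions", "cerebro_type_fractions"))
    for (band in names(p$event_risks[[tab]]))
      expect_equal(sum(p$event_risks[[tab]][[band]]), 1, tolerance = 1e-12)
  expect_true(validate_parameters(p))
})

test_that("config loading merges over defaults and rejects bad values", {
  p <- quiet_load(list(event_risks = list(sae_annual_risk = 0.03)))
  expect_equal(p$event_risks$sae_annual_risk, 0.03)
  # untouched entries keep their defaults
  expect_equal(p$event_risks$minor_ae_annual_risk, 0.137)
  # omitting costs fills the flagged placeholders, with a warning
  expect_warning(load_parameters(list()), "placeholder")
  expect_equal(quiet_load(list())$costs$provenance, "non-paper-default")
  # invariant violations are rejected with the offending key named
  expect_error(quiet_load(list(event_risks = list(hf_annual_risk =
    list(`80-84` = 1.2)))), "hf_annual_risk")
  expect_error(quiet_load(list(nonsense = list(a = 1))), "nonsense")
  expect_error(quiet_load(list(mortality = list(smr = list(mi = 0.5)))),
               "smr")
})

test_that("YAML round-trip reproduces the parameter set", {
  p <- default_parameters()
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path), add = TRUE)
  write_parameters(p, path)
  p2 <- quiet_load(path)
  expect_equal(unclass(p2)[names(unclass(p)) != "psa"],
               unclass(p)[names(unclass(p)) != "psa"], tolerance = 1e-12)
  # PSA specs are refitted from the (identical) values, so they agree too
  expect_equal(p2$psa[["treatment_effect.rr.hf"]]$spec$sdlog,
               p$psa[["treatment_effect.rr.hf"]]$spec$sdlog,
               tolerance = 1e-12)
})

test_that("set_parameter and get_parameter address nested values", {
  p <- default_parameters()
  p2 <- set_parameter(p, "treatment_effect.rr.hf", 1.472)
  expect_equal(get_parameter(p2, "treatment_effect.rr.hf"), 1.472)
  expect_error(set_parameter(p, "treatment_effect.rr.nope", 1), "unknown")
  expect_error(set_parameter(p, "event_risks.sae_annual_risk", 1.5), "\\[0,1\\]")
})

test_that("lognormal CI fit matches the closed-form sigma and its quantiles", {
  d <- fit_distribution(1.290, 1.134, 1.472, "lognormal")
  expect_equal(d$sdlog, (log(1.472) - log(1.134)) / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(exp(d$meanlog), 1.290)              # median at the point
  expect_equal(qlnorm(0.025, d$meanlog, d$sdlog), 1.134, tolerance = 0.05)
  expect_equal(qlnorm(0.975, d$meanlog, d$sdlog), 1.472, tolerance = 0.05)
})

test_that("fixed specs are degenerate and CI-absent beta matches its mean", {
  d <- fit_distribution(0.5, family = "fixed")
  expect_identical(draw_distribution(d, 5), rep(0.5, 5))
  # Monte-Carlo oracle: 1e6 beta draws under the SE = 20%-of-mean convention
  d <- fit_distribution(0.0174, family = "beta")
  set.seed(42)
  x <- draw_distribution(d, 1e6)
  se_mc <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.0174), 3 * se_mc)
  expect_equal(sd(x), 0.2 * 0.0174, tolerance = 0.01)
})

test_that("infeasible or ill-posed fits fail with a diagnostic", {
  expect_error(fit_distribution(0.5, se = 0.6, family = "beta"),
               "infeasible")
  expect_error(fit_distribution(-1, family = "lognormal"), "positive")
  expect_error(fit_distribution(0.5, 0.6, 0.9, "beta"), "bracket")
})

test_that("PSA draws are seeded, respect invariants, and centre on the base values", {
  p <- default_parameters()
  d1 <- draw_psa_parameters(p, seed = 11)
  d2 <- draw_psa_parameters(p, seed = 11)
  expect_equal(unclass(d1), unclass(d2))           # same seed, same draws
  expect_true(validate_parameters(d1))
  # fixed entries (the BP difference, splits, life table) are untouched
  expect_equal(d1$treatment_effect$delta_sbp_mmhg, 3.4)
  expect_equal(d1$event_risks$chd_cerebro_split, p$event_risks$chd_cerebro_split)
  # every draw in a batch satisfies every invariant (property check)
  draws <- lapply(1:25, function(i) draw_psa_parameters(p, seed = 100 + i))
  for (d in draws) expect_true(validate_parameters(d))
  # Monte-Carlo oracle: the SAE beta resamples centre on 0.0174
  sae <- vapply(draws, function(d) d$event_risks$sae_annual_risk, 0)
  more <- vapply(1:200, function(i)
    draw_psa_parameters(p, seed = 1000 + i)$event_risks$sae_annual_risk, 0)
  se <- 0.2 * 0.0174 / sqrt(length(more))
  expect_lt(abs(mean(more) - 0.0174), 4 * se)
})

test_that("the bundled life table is well-formed", {
  lt <- read_lifetable(system.file("extdata", "lifetable_synthetic_ew.csv",
                                   package = "deprescr"))
  expect_true(all(lt$qx_noncvd >= 0 & lt$qx_noncvd <= 1))
  for (s in c("M", "F")) {
    qx <- lt$qx_noncvd[lt$sex == s][order(lt$age[lt$sex == s])]
    ages <- sort(lt$age[lt$sex == s])
    expect_true(all(diff(qx[ages >= 90]) >= 0))    # non-decreasing beyond 90
  }
})
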