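test_that("prob_rescale inverts correctly and composes across durations", {
  # annual SAE risk to a 3-month cycle: compounding four cycles recovers it
  q <- prob_rescale(0.0174, 1, 0.25)
  expect_equal((1 - q)^4, 1 - 0.0174, tolerance = 1e-12)
  # 10-year CVD risk to a cycle: forty cycles recover it
  q10 <- prob_rescale(0.40, 10, 0.25)
  expect_equal((1 - q10)^40, 0.60, tolerance = 1e-12)
  expect_equal(prob_rescale(0, 7, 0.1), 0)
  expect_equal(prob_rescale(1, 1, 0.25), 1)  # certainty stays certain
  # composition property
  expect_equal(prob_rescale(prob_rescale(0.3, 1, 0.5), 0.5, 0.25),
               prob_rescale(0.3, 1, 0.25), tolerance = 1e-12)
  # monotone in p
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(prob_rescale(p, 1, 0.25)) >= 0))
})

test_that("interpolate_rr follows the log-linear law", {
  expect_equal(interpolate_rr(1.290, 3.4, 10), exp(0.34 * log(1.290)),
               tolerance = 1e-12)
  expect_equal(interpolate_rr(1.5, 0, 7), 1)
  expect_equal(interpolate_rr(1.108, 3.4, 3.4), 1.108)
  expect_error(interpolate_rr(-1, 3.4, 10), "positive")
  # log-additivity: splitting the BP difference multiplies the pieces
  r <- 1.29; d <- 2.1; ref <- 10
  expect_equal(interpolate_rr(r, d, ref) * interpolate_rr(r, ref - d, ref),
               r, tolerance = 1e-12)
  # continuity / monotonicity in delta for a harmful RR
  ds <- seq(0, 10, by = 0.5)
  expect_true(all(diff(interpolate_rr(1.29, ds, 10)) > 0))
})

test_that("cvd_event_prob applies hazard scaling and the prior-CVD multiplier", {
  p <- default_parameters()
  pat <- uniform_cohort(1, risk = 0.40)
  expect_equal(cvd_event_prob(pat, p, "usual_care"),
               1 - 0.60^(0.25 / 10), tolerance = 1e-12)
  pat_cvd <- uniform_cohort(1, risk = 0.40, prior = 1L)
  expect_equal(cvd_event_prob(pat_cvd, p, "usual_care"),
               1 - 0.60^(1.5 / 40), tolerance = 1e-12)
  pat0 <- uniform_cohort(1, risk = 0)
  expect_equal(cvd_event_prob(pat0, p, "usual_care"), 0)
  expect_equal(cvd_event_prob(pat0, p, "reduction"), 0)
  # intervention arm raises the probability while the effect lasts
  expect_gt(cvd_event_prob(pat, p, "reduction"),
            cvd_event_prob(pat, p, "usual_care"))
  # ... and reverts to the usual-care value once the effect has expired
  p5 <- set_parameter(p, "treatment_effect.effect_duration_years", 5)
  expect_equal(cvd_event_prob(pat, p5, "reduction", elapsed_years = 6),
               cvd_event_prob(pat, p5, "usual_care"))
})

test_that("classify_cvd_event reproduces the sex/age-band subtype tables", {
  p <- default_parameters()
  # deterministic checks through the uniform arguments
  expect_equal(classify_cvd_event(86, "M", p, u = c(0.9, 0.5)), "stroke")
  expect_equal(classify_cvd_event(86, "M", p, u = c(0.9, 0.99)), "tia")
  expect_equal(classify_cvd_event(80, "F", p, u = c(0.1, 0.1)), "mi")
  expect_error(classify_cvd_event(70, "M", p), "75")
  # frequency oracle: stroke fraction among events for M 86 is
  # P(cerebro) * P(stroke | cerebro) = 0.5 * 0.956
  set.seed(8)
  n <- 2e5
  draws <- vapply(seq_len(n), function(i)
    classify_cvd_event(86, "M", p, u = runif(2)), "")
  p_star <- 0.5 * 0.956
  se <- sqrt(p_star * (1 - p_star) / n)
  expect_lt(abs(mean(draws == "stroke") - p_star), 3 * se)
  # and the MI fraction for F 80: 0.5 * 0.358 (fractions renormalised)
  draws_f <- vapply(seq_len(n), function(i)
    classify_cvd_event(80, "F", p, u = runif(2)), "")
  p_mi <- 0.5 * 0.358
  expect_lt(abs(mean(draws_f == "mi") - p_mi),
            3 * sqrt(p_mi * (1 - p_mi) / n))
})

test_that("hf_prob uses age bands and the HF relative risk", {
  p <- default_parameters()
  expect_equal(hf_prob(86, p, "usual_care"),
               prob_rescale(0.0358, 1, 0.25), tolerance = 1e-12)
  expect_equal(hf_prob(92, p, "usual_care"),
               prob_rescale(0.0536, 1, 0.25), tolerance = 1e-12)
  expect_equal(hf_prob(82, p, "usual_care"),
               prob_rescale(0.0223, 1, 0.25), tolerance = 1e-12)
  # null-effect scenario equalises the arms
  p1 <- set_parameter(p, "treatment_effect.rr.hf", 1)
  expect_equal(hf_prob(86, p1, "reduction"), hf_prob(86, p1, "usual_care"))
  expect_gt(hf_prob(86, p, "reduction"), hf_prob(86, p, "usual_care"))
})

test_that("adverse_event_probs rescale and share one relative risk", {
  p <- default_parameters()
  ae <- adverse_event_probs(p, "usual_care")
  expect_equal(unname(ae["serious"]), prob_rescale(0.0174, 1, 0.25),
               tolerance = 1e-12)
  expect_equal(unname(ae["minor"]), prob_rescale(0.137, 1, 0.25),
               tolerance = 1e-12)
  aer <- adverse_event_probs(p, "reduction")
  rr <- unname(p$treatment_effect$rr["sae"])  # reference delta = observed
  expect_equal(unname(aer["serious"] / ae["serious"]), rr, tolerance = 1e-12)
  expect_equal(unname(aer["minor"] / ae["minor"]), rr, tolerance = 1e-12)
  p1 <- set_parameter(set_parameter(p, "treatment_effect.rr.sae", 1),
                      "treatment_effect.rr.minor", 1)
  expect_equal(adverse_event_probs(p1, "reduction"),
               adverse_event_probs(p1, "usual_care"))
})

test_that("death_prob applies SMRs on the hazard scale", {
  p <- default_parameters(lifetable = flat_lifetable(0.10))
  # event-free: plain rescaled life-table probability
  expect_equal(death_prob(85, "M", "event_free", p),
               1 - 0.9^0.25, tolerance = 1e-12)
  # post-stroke, SMR 2.72
  expect_equal(death_prob(85, "M", "post_stroke", p),
               1 - 0.9^(2.72 / 4), tolerance = 1e-12)
  # monotone in the SMR: AKI (1.18) < stroke (2.72)
  expect_lt(death_prob(85, "M", "post_aki", p),
            death_prob(85, "M", "post_stroke", p))
  # ages beyond the table use the terminal row
  expect_equal(death_prob(150, "F", "event_free", p),
               death_prob(120, "F", "event_free", p))
})

test_that("all per-cycle probabilities stay in [0,1] under random parameter draws", {
  p <- default_parameters()
  for (i in 1:10) {
    d <- draw_psa_parameters(p, seed = 400 + i)
    pats <- generate_cohort(cohort_spec(), 20, seed = i)
    for (j in seq_len(nrow(pats))) {
      pat <- pats[j, ]
      vals <- c(cvd_event_prob(pat, d, "reduction"),
                hf_prob(pat$age, d, "reduction"),
                adverse_event_probs(d, "reduction"),
                death_prob(pat$age, pat$sex, "post_stroke", d))
      expect_true(all(vals >= 0 & vals <= 1))
    }
  }
})
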