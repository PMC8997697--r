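# Shared test fixtures, built in code.

# A flat life table: the same annual non-CVD death probability at every age
# 80-120 for both sexes. Makes hazards time-constant for closed-form checks.
flat_lifetable <- function(qx = 0.1) {
  lt <- expand.grid(age = 80:120, sex = c("M", "F"), stringsAsFactors = FALSE)
  lt$qx_noncvd <- qx
  lt[order(lt$sex, lt$age), ]
}

# Parameter set with every stochastic ingredient switched off; individual
# risks are then turned back on by tests that need them.
zero_hazard_params <- function() {
  p <- default_parameters(lifetable = flat_lifetable(0))
  p$event_risks$sae_annual_risk <- 0
  p$event_risks$minor_ae_annual_risk <- 0
  p$event_risks$hf_annual_risk[] <- 0
  p
}

# One identical patient replicated n times (age 91 keeps every age band
# fixed for a 20-year run started in the 90+ band is wrong -- use 95 so
# band stays 90+ and life-table rows exist to 120).
uniform_cohort <- function(n, age = 95, sex = "M", risk = 0, utility = 0.769,
                           prior = 0L, drugs = 2L) {
  out <- data.frame(age = rep(age, n), sex = sex, n_prior_cvd = prior,
                    ten_year_cvd_risk = risk, baseline_utility = utility,
                    frailty = "fit", n_drugs = drugs,
                    stringsAsFactors = FALSE)
  class(out) <- c("deprescr_cohort", "data.frame")
  out
}

quiet_load <- function(...) suppressWarnings(load_parameters(...))
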