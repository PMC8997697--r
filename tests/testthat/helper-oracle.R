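# Independent deterministic oracle: exact expected discounted cost and QALYs
# for a reduced model (one representative patient, hazards constant over
# time) evaluated as a Markov *cohort* model -- state-occupancy vectors
# propagated through an explicitly constructed transition law. All
# arithmetic here is written from the model definition, independently of the
# package's engine code, so microsimulation means can be checked against it.
#
# Constancy requires: a flat life table, start age >= 90 (heart-failure and
# event-type age bands then never change) and an infinite or zero effect
# duration.
markov_cohort_oracle <- function(patient, arm, params, config) {
  cl <- config$cycle_length_years
  ncyc <- round(config$max_horizon_years / cl)
  r <- config$discount_rate_annual
  er <- params$event_risks
  te <- params$treatment_effect
  stopifnot(patient$age >= 90)

  types <- c("mi", "acs", "angina", "stroke", "tia", "hf", "fall", "aki")
  lt <- params$mortality$life_table
  qx <- lt$qx_noncvd[lt$sex == patient$sex & lt$age == floor(patient$age)]
  stopifnot(length(qx) == 1)

  rr <- function(class) {
    if (arm != "reduction") return(1)
    te$rr[[class]]^(te$delta_sbp_mmhg / te$reference_delta_mmhg)
  }
  # cause marginals from the event-free state
  mult_prior <- if (patient$n_prior_cvd >= 1) er$prior_cvd_multiplier else 1
  base_cvd <- 1 - (1 - patient$ten_year_cvd_risk)^(mult_prior * cl / 10)
  p_death0 <- 1 - (1 - qx)^cl
  p_chd <- er$chd_cerebro_split[["chd"]] * base_cvd * rr("chd")
  p_cer <- er$chd_cerebro_split[["cerebro"]] * base_cvd * rr("stroke_tia")
  p_hf <- (1 - (1 - er$hf_annual_risk[["90+"]])^cl) * rr("hf")
  p_sae <- (1 - (1 - er$sae_annual_risk)^cl) * rr("sae")
  p_min <- (1 - (1 - er$minor_ae_annual_risk)^cl) * rr("minor")

  band <- paste0(patient$sex, "_85p")
  sub_chd <- er$chd_type_fractions[[band]]
  sub_cer <- er$cerebro_type_fractions[[band]]
  # per-event-type entry probabilities from event-free, via the product
  # construction (event mass shared in proportion to the marginals)
  marg <- c(death = p_death0, chd = p_chd, cer = p_cer, hf = p_hf,
            sae = p_sae, minor = p_min)
  p_none <- prod(1 - marg)
  w <- marg / sum(marg) * (1 - p_none)
  entry <- c(mi = w[["chd"]] * sub_chd[["mi"]],
             acs = w[["chd"]] * sub_chd[["acs"]],
             angina = w[["chd"]] * sub_chd[["angina"]],
             stroke = w[["cer"]] * sub_cer[["stroke"]],
             tia = w[["cer"]] * sub_cer[["tia"]],
             hf = w[["hf"]],
             fall = w[["sae"]] * er$fall_aki_split[["fall"]],
             aki = w[["sae"]] * er$fall_aki_split[["aki"]])

  # from each post-event state: death (SMR-adjusted), minor AE, or nothing
  smr <- params$mortality$smr[types]
  p_death_x <- 1 - (1 - qx)^(smr * cl)
  stay_x <- setNames(numeric(8), types)
  minor_x <- setNames(numeric(8), types)
  for (x in types) {
    m2 <- c(p_death_x[[x]], p_min)
    pn <- prod(1 - m2)
    ww <- m2 / sum(m2) * (1 - pn)
    minor_x[x] <- ww[2]
    stay_x[x] <- pn + ww[2]           # survives the cycle (minor or nothing)
  }

  ut <- params$utility
  gain <- if (arm == "reduction") ut$deprescribe_utility_gain else 0
  multip <- setNames(rep(1, 8), types)
  multip[names(ut$state_multipliers)] <- ut$state_multipliers
  u_post <- pmax(patient$baseline_utility * multip -
                   ifelse(types == "aki", ut$decrements_annual[["aki"]], 0) +
                   gain, 0)
  names(u_post) <- types
  u_free <- max(patient$baseline_utility + gain, 0)
  mean_minor_dec <- mean(ut$decrements_annual[
    c("hypotension", "syncope", "bradycardia", "electrolyte",
      "nonserious_fall")])
  tia_pen <- ut$decrements_annual[["tia"]] / 12    # QALY loss, event cycle
  minor_pen <- mean_minor_dec / 12

  co <- params$costs
  fixed_cost <- function(k, maintained_frac) {
    base <- co$consultations_per_cycle * co$cost_per_consultation
    if (arm == "reduction") {
      drugs <- if (k == 0) patient$n_drugs - 1 else
        maintained_frac * (patient$n_drugs - 1) +
        (1 - maintained_frac) * patient$n_drugs
      extra <- if (k == 0) co$safety_visit_cost else
        if (k == 1) (1 - maintained_frac) * co$reinstatement_visit_cost else 0
      base + drugs * co$cost_per_drug_per_cycle + extra
    } else base + patient$n_drugs * co$cost_per_drug_per_cycle
  }
  m_frac <- if (arm == "reduction") te$maintain_reduction_prob else 1
  acute <- co$acute_event_costs[types]
  longterm <- co$longterm_event_costs_per_cycle[types]

  pi_free <- 1
  pi_post <- setNames(numeric(8), types)
  eq <- ec <- 0
  for (k in 0:(ncyc - 1)) {
    disc <- (1 + r)^(-(k + 0.5) * cl)
    fx <- fixed_cost(k, m_frac)
    # event-free occupants
    q_free <- p_none * u_free * cl +
      w[["minor"]] * (u_free * cl - minor_pen) +
      sum(entry * u_post * cl) - entry[["tia"]] * tia_pen
    c_free <- (p_none + w[["minor"]] + sum(entry)) * fx +
      sum(entry * acute) + w[["minor"]] * co$minor_ae_cost
    # post-event occupants (long-term cost, possible minor AE)
    q_post <- sum(pi_post * stay_x * u_post * cl) -
      sum(pi_post * minor_x) * minor_pen
    c_post <- sum(pi_post * stay_x * (fx + longterm)) +
      sum(pi_post * minor_x * co$minor_ae_cost)
    eq <- eq + disc * (pi_free * q_free + q_post)
    ec <- ec + disc * (pi_free * c_free + c_post)
    pi_post <- pi_post * stay_x + pi_free * entry
    pi_free <- pi_free * (p_none + w[["minor"]])
  }
  list(qaly = eq, cost = ec)
}
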