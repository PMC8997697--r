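#' Simulation run configuration
#'
#' @param n_patients Number of simulated patients (base case 100,000).
#' @param cycle_length_years Cycle length in years (base 0.25 = 3 months).
#' @param max_horizon_years Time horizon in years (base 20, i.e. lifetime
#'   for an 80+ cohort).
#' @param discount_rate_annual Annual discount rate applied to both costs
#'   and QALYs (base 0.035).
#' @param half_cycle_correction Discount at cycle midpoints (\code{TRUE},
#'   the default) rather than cycle starts.
#' @param seed Integer master seed; every random stream in a run is derived
#'   from it.
#' @param common_random_numbers Reuse identical random streams across the
#'   two arms (variance reduction for incremental results; default
#'   \code{TRUE}).
#' @param wtp_thresholds Willingness-to-pay thresholds (GBP/QALY) reported
#'   against (base 20,000 and 30,000).
#' @return A \code{deprescr_config} object.
#' @export
simulation_config <- function(n_patients = 100000,
                              cycle_length_years = 0.25,
                              max_horizon_years = 20,
                              discount_rate_annual = 0.035,
                              half_cycle_correction = TRUE,
                              seed = 1,
                              common_random_numbers = TRUE,
                              wtp_thresholds = c(20000, 30000)) {
  if (cycle_length_years <= 0 || cycle_length_years > max_horizon_years)
    stop("require 0 < cycle_length_years <= max_horizon_years")
  if (discount_rate_annual < 0) stop("discount rate must be >= 0")
  if (n_patients < 1) stop("n_patients must be >= 1")
  structure(list(n_patients = as.integer(n_patients),
                 cycle_length_years = cycle_length_years,
                 max_horizon_years = max_horizon_years,
                 discount_rate_annual = discount_rate_annual,
                 half_cycle_correction = half_cycle_correction,
                 seed = as.integer(seed),
                 common_random_numbers = common_random_numbers,
                 wtp_thresholds = wtp_thresholds),
            class = "deprescr_config")
}

# Integer state codes for the engine: index into .states (1 = event_free,
# 2..9 = post-event in .event_types order, 10 = dead).
.state_code <- function(name) match(name, .states)

# Vectorised engine: walks all patients through the cycles simultaneously.
# Within a cycle, independent cause probabilities are combined into one
# multinomial by the product construction: P(no event) is the product of
# the cause-wise complements and the event mass 1 - P(none) is shared in
# proportion to the marginal cause probabilities. One uniform picks the
# cause, a second the subtype. Draw shapes are fixed at n per cycle so that
# two arms run under common random numbers stay aligned draw-for-draw.
.sim_engine <- function(cohort, arm, params, config, trace = FALSE) {
  n <- nrow(cohort)
  cl <- config$cycle_length_years
  ncycles <- as.integer(round(config$max_horizon_years / cl))
  er <- params$event_risks
  te <- params$treatment_effect
  scale_opt <- params$options$risk_multiplier_scale

  # life-table lookup vectors per sex, clamped to the terminal row
  lt <- params$mortality$life_table
  lt_min <- min(lt$age); lt_max <- max(lt$age)
  qx_M <- lt$qx_noncvd[lt$sex == "M"][order(lt$age[lt$sex == "M"])]
  qx_F <- lt$qx_noncvd[lt$sex == "F"][order(lt$age[lt$sex == "F"])]
  if (any(cohort$age < lt_min)) stop("cohort ages below life-table range")

  # per-state vectors indexed by state code
  smr_code <- c(1, unname(params$mortality$smr[.event_types]), 1)
  mult_code <- unname(.state_multiplier_vector(params)[.states])
  ltc <- params$costs$longterm_event_costs_per_cycle
  ltc_code <- c(0, unname(ltc[.event_types]), 0)
  acute <- params$costs$acute_event_costs
  aki_dec <- params$utility$decrements_annual[["aki"]]
  tia_dec <- params$utility$decrements_annual[["tia"]]
  minor_dec <- unname(params$utility$decrements_annual[.minor_types])
  gain <- if (arm == "reduction") params$utility$deprescribe_utility_gain else 0
  co <- params$costs

  # event-type fraction cumulative tables, band rows M_75_84/M_85p/F_75_84/F_85p
  bands <- c("M_75_84", "M_85p", "F_75_84", "F_85p")
  chd_cum <- t(vapply(bands, function(b)
    cumsum(er$chd_type_fractions[[b]]), numeric(3)))
  cer_cum <- t(vapply(bands, function(b)
    cumsum(er$cerebro_type_fractions[[b]]), numeric(2)))

  # per-patient constants
  is_m <- cohort$sex == "M"
  prior_mult <- ifelse(cohort$n_prior_cvd >= 1, er$prior_cvd_multiplier, 1)
  base_cvd <- .apply_mult(prob_rescale(cohort$ten_year_cvd_risk, 10, cl),
                          prior_mult, scale_opt)
  sae_cycle <- prob_rescale(er$sae_annual_risk, 1, cl)
  minor_cycle <- prob_rescale(er$minor_ae_annual_risk, 1, cl)
  split_chd <- er$chd_cerebro_split[["chd"]]
  split_cer <- er$chd_cerebro_split[["cerebro"]]
  baseline_u <- cohort$baseline_utility
  n_drugs <- cohort$n_drugs

  maintained <- rep(TRUE, n)
  if (arm == "reduction") {
    set.seed(config$seed + 101L)
    maintained <- runif(n) < te$maintain_reduction_prob
  }
  cycle_seed <- config$seed + 202L
  if (!config$common_random_numbers && arm == "reduction")
    cycle_seed <- config$seed + 203L
  set.seed(cycle_seed)

  state <- rep(1L, n)              # event_free
  entered_post_before <- rep(FALSE, n)
  age <- cohort$age
  disc_cost <- disc_qaly <- qaly_und <- cost_und <- disc_ly <- numeric(n)
  ever <- matrix(FALSE, n, 5,
                 dimnames = list(NULL, c("hf", "chd", "stroke_tia",
                                         "serious_ae", "minor_ae")))
  tr <- if (trace) vector("list", ncycles) else NULL

  consult_cost <- co$consultations_per_cycle * co$cost_per_consultation
  hf_bands <- unname(er$hf_annual_risk)

  for (k in 0:(ncycles - 1L)) {
    elapsed <- k * cl
    alive <- state != 10L
    if (!any(alive) && !trace) break
    eff_on <- arm == "reduction" && elapsed < te$effect_duration_years
    rr_chd <- if (eff_on) interpolate_rr(te$rr[["chd"]], te$delta_sbp_mmhg,
                                         te$reference_delta_mmhg) else 1
    rr_cer <- if (eff_on) interpolate_rr(te$rr[["stroke_tia"]],
                                         te$delta_sbp_mmhg,
                                         te$reference_delta_mmhg) else 1
    rr_hf <- if (eff_on) interpolate_rr(te$rr[["hf"]], te$delta_sbp_mmhg,
                                        te$reference_delta_mmhg) else 1
    rr_sae <- if (eff_on) interpolate_rr(te$rr[["sae"]], te$delta_sbp_mmhg,
                                         te$reference_delta_mmhg) else 1
    rr_minor <- if (eff_on) interpolate_rr(te$rr[["minor"]],
                                           te$delta_sbp_mmhg,
                                           te$reference_delta_mmhg) else 1

    age_i <- pmin(pmax(floor(age), lt_min), lt_max) - lt_min + 1L
    qx <- ifelse(is_m, qx_M[age_i], qx_F[age_i])
    p_death <- 1 - (1 - qx)^(smr_code[state] * cl)
    free <- state == 1L
    p_chd <- ifelse(free, pmin(split_chd * base_cvd * rr_chd, 1), 0)
    p_cer <- ifelse(free, pmin(split_cer * base_cvd * rr_cer, 1), 0)
    hf_annual <- hf_bands[ifelse(age < 85, 1L, ifelse(age < 90, 2L, 3L))]
    p_hf <- ifelse(free, pmin(prob_rescale(hf_annual, 1, cl) * rr_hf, 1), 0)
    p_sae <- ifelse(free, pmin(sae_cycle * rr_sae, 1), 0)
    p_minor <- pmin(minor_cycle * rr_minor, 1)

    p_none <- (1 - p_death) * (1 - p_chd) * (1 - p_cer) * (1 - p_hf) *
      (1 - p_sae) * (1 - p_minor)
    tot <- p_death + p_chd + p_cer + p_hf + p_sae + p_minor
    sc <- ifelse(tot > 0, (1 - p_none) / tot, 0)

    u1 <- runif(n)     # cause draw (fixed shape for CRN alignment)
    u2 <- runif(n)     # subtype draw
    c1 <- p_death * sc
    c2 <- c1 + p_chd * sc
    c3 <- c2 + p_cer * sc
    c4 <- c3 + p_hf * sc
    c5 <- c4 + p_sae * sc
    c6 <- c5 + p_minor * sc
    cause <- rep(0L, n)  # 0 none, 1 death, 2 chd, 3 cereb, 4 hf, 5 sae, 6 minor
    cause[u1 < c6] <- 6L
    cause[u1 < c5] <- 5L
    cause[u1 < c4] <- 4L
    cause[u1 < c3] <- 3L
    cause[u1 < c2] <- 2L
    cause[u1 < c1] <- 1L
    cause[!alive] <- 0L

    band <- (!is_m) * 2L + (age >= 85) + 1L
    state_prev <- state
    new_event <- rep(0L, n)  # event code into .event_types, 0 none, -1 minor

    i <- which(cause == 2L)  # CHD: mi / acs / angina
    if (length(i)) {
      sub <- 1L + (u2[i] > chd_cum[band[i], 1L]) + (u2[i] > chd_cum[band[i], 2L])
      new_event[i] <- sub                      # 1 mi, 2 acs, 3 angina
    }
    i <- which(cause == 3L)  # cerebrovascular: stroke / tia
    if (length(i)) new_event[i] <- 4L + (u2[i] > cer_cum[band[i], 1L])
    i <- which(cause == 4L)
    if (length(i)) new_event[i] <- 6L          # hf
    i <- which(cause == 5L)  # serious AE: fall / aki
    if (length(i)) new_event[i] <- 7L + (u2[i] > er$fall_aki_split[["fall"]])
    minor_idx <- which(cause == 6L)
    minor_sub <- rep(0L, n)
    if (length(minor_idx)) {
      new_event[minor_idx] <- -1L
      minor_sub[minor_idx] <- pmin(floor(u2[minor_idx] * 5) + 1L, 5L)
    }

    serious <- new_event > 0L
    state[serious] <- new_event[serious] + 1L   # post-event state codes 2..9
    state[cause == 1L] <- 10L
    died_now <- cause == 1L

    ever[, "hf"] <- ever[, "hf"] | new_event == 6L
    ever[, "chd"] <- ever[, "chd"] | (new_event >= 1L & new_event <= 3L)
    ever[, "stroke_tia"] <- ever[, "stroke_tia"] |
      (new_event == 4L | new_event == 5L)
    ever[, "serious_ae"] <- ever[, "serious_ae"] |
      (new_event == 7L | new_event == 8L)
    ever[, "minor_ae"] <- ever[, "minor_ae"] | new_event == -1L

    accr <- alive & !died_now
    trans_dec <- numeric(n)
    trans_dec[new_event == 5L] <- tia_dec
    trans_dec[minor_idx] <- minor_dec[minor_sub[minor_idx]]
    score <- baseline_u * mult_code[state] -
      ifelse(state == 9L, aki_dec, 0) + gain - trans_dec / 12 / cl
    score <- pmax(score, 0)
    score[!accr] <- 0

    drugs_now <- if (arm == "reduction") {
      ifelse(k == 0L | maintained, n_drugs - 1L, n_drugs)
    } else n_drugs
    ccost <- consult_cost + drugs_now * co$cost_per_drug_per_cycle
    if (arm == "reduction") {
      if (k == 0L) ccost <- ccost + co$safety_visit_cost
      if (k == 1L) ccost <- ccost + ifelse(maintained, 0,
                                           co$reinstatement_visit_cost)
    }
    acute_cost <- numeric(n)
    acute_cost[serious] <- acute[.event_types[new_event[serious]]]
    acute_cost[minor_idx] <- co$minor_ae_cost
    lt_cost <- ifelse(entered_post_before, ltc_code[state_prev], 0)
    ccost <- ccost + acute_cost + lt_cost
    ccost[!accr] <- 0

    t_eval <- if (config$half_cycle_correction) (k + 0.5) * cl else k * cl
    dfac <- (1 + config$discount_rate_annual)^(-t_eval)
    qaly_und <- qaly_und + score * cl
    cost_und <- cost_und + ccost
    disc_qaly <- disc_qaly + score * cl * dfac
    disc_cost <- disc_cost + ccost * dfac
    disc_ly <- disc_ly + ifelse(accr, cl * dfac, 0)

    if (trace) {
      ev_name <- rep("none", n)
      ev_name[serious] <- .event_types[new_event[serious]]
      ev_name[minor_idx] <- paste0("minor_", .minor_types[minor_sub[minor_idx]])
      ev_name[died_now] <- "death"
      tr[[k + 1L]] <- data.frame(cycle = k, patient = seq_len(n),
                                 state = .states[state], event = ev_name,
                                 cost = ccost, qaly = score * cl,
                                 disc_cost = ccost * dfac,
                                 disc_qaly = score * cl * dfac,
                                 alive_at_start = alive,
                                 stringsAsFactors = FALSE)
    }

    entered_post_before <- entered_post_before | serious
    age <- age + ifelse(accr, cl, 0)
  }

  list(disc_cost = disc_cost, disc_qaly = disc_qaly, qaly = qaly_und,
       cost = cost_und, disc_ly = disc_ly, ever = ever,
       maintained = maintained,
       trace = if (trace) do.call(rbind, tr) else NULL)
}

#' Simulate one patient's trajectory
#'
#' Walks a single patient through the model in the given arm and returns the
#' per-cycle record: state occupied, event (if any), cost and QALY
#' increments, undiscounted and discounted. The trajectory ends with the
#' cycle of death (recorded with zero increments) or at the horizon.
#'
#' @param patient One-row cohort data frame (see
#'   \code{\link{generate_cohort}}).
#' @param arm \code{"usual_care"} or \code{"reduction"}.
#' @param params A \code{deprescr_params} object.
#' @param config A \code{\link{simulation_config}} (its \code{seed} drives
#'   the patient's random stream).
#' @return A data frame of class \code{deprescr_trajectory}, one row per
#'   cycle lived.
#' @export
simulate_patient <- function(patient, arm = c("usual_care", "reduction"),
                             params, config = simulation_config()) {
  arm <- match.arg(arm)
  patient <- as.data.frame(patient)
  if (nrow(patient) != 1) stop("simulate_patient takes exactly one patient")
  res <- .sim_engine(patient, arm, params, config, trace = TRUE)
  tr <- res$trace[res$trace$alive_at_start, ]
  tr$patient <- NULL
  tr$alive_at_start <- NULL
  rownames(tr) <- NULL
  class(tr) <- c("deprescr_trajectory", "data.frame")
  tr
}

#' Construct an arm-result record
#'
#' Container for one strategy arm's aggregate results; produced by
#' \code{\link{run_arm}} and consumable by \code{\link{build_event_table}}
#' and \code{\link{compute_icer}}.
#'
#' @param arm Arm label.
#' @param n Number of simulated patients.
#' @param mean_cost,mean_qaly Mean discounted cost (GBP) and QALYs per
#'   patient.
#' @param se_cost,se_qaly Monte-Carlo standard errors of those means.
#' @param events_per_100k Named vector of event counts per 100,000 patients
#'   (categories \code{hf, chd, stroke_tia, serious_ae, minor_ae}).
#' @param mean_ly_disc Mean discounted life-years per patient.
#' @param run_id Identifier tying together arms from the same run.
#' @return An object of class \code{deprescr_arm}.
#' @export
arm_result <- function(arm, n, mean_cost, mean_qaly, se_cost = NA_real_,
                       se_qaly = NA_real_,
                       events_per_100k = c(hf = NA_real_, chd = NA_real_,
                                           stroke_tia = NA_real_,
                                           serious_ae = NA_real_,
                                           minor_ae = NA_real_),
                       mean_ly_disc = NA_real_, run_id = "manual") {
  structure(list(arm = arm, n = n, mean_cost = mean_cost,
                 mean_qaly = mean_qaly, se_cost = se_cost,
                 se_qaly = se_qaly, events_per_100k = events_per_100k,
                 mean_ly_disc = mean_ly_disc, run_id = run_id),
            class = "deprescr_arm")
}

#' Run one strategy arm over a cohort
#'
#' Simulates every patient in the cohort through the model under one
#' strategy and aggregates mean discounted costs and QALYs (with
#' Monte-Carlo standard errors) and cumulative event incidence per 100,000
#' patients in the five reported categories (heart failure, coronary heart
#' disease, stroke/TIA, serious drug-related adverse events, minor adverse
#' events; a patient counts once per category).
#'
#' Random streams are derived from \code{config$seed}; with
#' \code{common_random_numbers = TRUE} (default) the cycle-level streams are
#' identical across arms, so arms differing only through parameters that do
#' not alter any draw produce identical trajectories.
#'
#' @param cohort A \code{deprescr_cohort} data frame.
#' @param arm \code{"usual_care"} or \code{"reduction"}.
#' @param params A \code{deprescr_params} object.
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{arm_result}} object.
#' @export
run_arm <- function(cohort, arm = c("usual_care", "reduction"), params,
                    config = simulation_config()) {
  arm <- match.arg(arm)
  if (NROW(cohort) == 0) stop("cohort is empty")
  res <- .sim_engine(cohort, arm, params, config, trace = FALSE)
  n <- nrow(cohort)
  ev <- colMeans(res$ever) * 1e5
  arm_result(arm = arm, n = n,
             mean_cost = mean(res$disc_cost),
             mean_qaly = mean(res$disc_qaly),
             se_cost = sd(res$disc_cost) / sqrt(n),
             se_qaly = sd(res$disc_qaly) / sqrt(n),
             events_per_100k = ev,
             mean_ly_disc = mean(res$disc_ly),
             run_id = sprintf("seed%d_n%d_h%g", config$seed, n,
                              config$max_horizon_years))
}

#' Run the base-case comparison
#'
#' Runs both strategies on the same cohort with common random numbers and
#' computes the incremental result (usual care minus medication reduction,
#' matching the trial-economics presentation).
#'
#' @param params A \code{deprescr_params} object.
#' @param config A \code{\link{simulation_config}}.
#' @param cohort Optional pre-built cohort; generated from \code{spec} with
#'   a seed derived from \code{config$seed} when \code{NULL}.
#' @param spec A \code{\link{cohort_spec}} used when generating.
#' @return An object of class \code{deprescr_basecase}: list with
#'   \code{usual_care} and \code{reduction} \code{\link{arm_result}}s, the
#'   \code{cea} comparison (see \code{\link{compute_icer}}), the event
#'   table, and the config used.
#' @export
run_base_case <- function(params = default_parameters(),
                          config = simulation_config(), cohort = NULL,
                          spec = cohort_spec()) {
  if (is.null(cohort))
    cohort <- generate_cohort(spec, config$n_patients,
                              seed = config$seed + 7L)
  usual <- run_arm(cohort, "usual_care", params, config)
  red <- run_arm(cohort, "reduction", params, config)
  cea <- compute_icer(usual$mean_cost, usual$mean_qaly,
                      red$mean_cost, red$mean_qaly,
                      labels = c("usual_care", "reduction"))
  structure(list(usual_care = usual, reduction = red, cea = cea,
                 event_table = build_event_table(red, usual),
                 config = config),
            class = "deprescr_basecase")
}

#' @export
print.deprescr_arm <- function(x, ...) {
  cat(sprintf("Arm '%s' (n = %d): mean discounted cost £%.0f (SE %.1f), QALYs %.3f (SE %.4f)\n",
              x$arm, x$n, x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  cat("  events per 100,000:",
      paste(names(x$events_per_100k), round(x$events_per_100k), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.deprescr_basecase <- function(x, ...) {
  cat("Deprescribing cost-utility analysis (usual care vs medication reduction)\n")
  cat(sprintf("  %-18s cost £%8.0f   QALYs %6.3f\n", "reduction:",
              x$reduction$mean_cost, x$reduction$mean_qaly))
  cat(sprintf("  %-18s cost £%8.0f   QALYs %6.3f\n", "usual care:",
              x$usual_care$mean_cost, x$usual_care$mean_qaly))
  print(x$cea)
  cat("  Event incidence per 100,000 (reduction - usual care):\n")
  et <- x$event_table$table
  for (i in seq_len(nrow(et)))
    cat(sprintf("    %-12s %8.0f %8.0f %+8.0f\n", et$event[i],
                et$reduction[i], et$usual_care[i], et$difference[i]))
  invisible(x)
}

#' @export
summary.deprescr_basecase <- function(object, ...) {
  out <- data.frame(
    strategy = c("reduction", "usual_care"),
    mean_cost = c(object$reduction$mean_cost, object$usual_care$mean_cost),
    mean_qaly = c(object$reduction$mean_qaly, object$usual_care$mean_qaly),
    se_cost = c(object$reduction$se_cost, object$usual_care$se_cost),
    se_qaly = c(object$reduction$se_qaly, object$usual_care$se_qaly))
  attr(out, "cea") <- object$cea
  out
}
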