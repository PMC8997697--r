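#' Rescale a probability to a different time interval
#'
#' Constant-hazard (exponential) conversion:
#' \code{1 - (1 - p)^(to_years / from_years)}. Used to turn annual and
#' 10-year risks into 3-month cycle probabilities.
#'
#' @param p Probability over \code{from_years}.
#' @param from_years,to_years Source and target durations (> 0).
#' @return Probability over \code{to_years}; monotone in \code{p}, and 1
#'   stays 1 for any durations.
#' @export
#' @examples
#' prob_rescale(0.0174, 1, 0.25)  # annual SAE risk per 3-month cycle
prob_rescale <- function(p, from_years, to_years) {
  if (any(from_years <= 0) || any(to_years <= 0))
    stop("durations must be positive")
  if (any(p < 0 | p > 1)) stop("p must lie in [0,1]")
  1 - (1 - p)^(to_years / from_years)
}

#' Log-linear interpolation of a relative risk
#'
#' Rescales a relative risk quoted at a reference blood-pressure difference
#' to a different difference: \code{rr_ref ^ (delta_sbp / reference_delta)}.
#' At \code{delta_sbp = reference_delta} the RR is returned unchanged; at
#' \code{delta_sbp = 0} the result is 1.
#'
#' @param rr_ref Relative risk at the reference BP difference (> 0).
#' @param delta_sbp Systolic BP difference to interpolate to (mm Hg).
#' @param reference_delta Reference BP difference (mm Hg, > 0).
#' @return Interpolated relative risk.
#' @export
#' @examples
#' interpolate_rr(1.290, 3.4, 10)  # heart-failure RR scaled to 3.4 mmHg
interpolate_rr <- function(rr_ref, delta_sbp, reference_delta) {
  if (any(rr_ref <= 0)) stop("rr_ref must be positive")
  if (any(reference_delta <= 0)) stop("reference_delta must be positive")
  rr_ref^(delta_sbp / reference_delta)
}

# Effective RR for an event class in a given arm at a given model time:
# 1 in the usual-care arm and once the effect duration has elapsed.
.effective_rr <- function(params, class, arm, elapsed_years) {
  te <- params$treatment_effect
  if (arm != "reduction" || elapsed_years >= te$effect_duration_years)
    return(1)
  interpolate_rr(te$rr[[class]], te$delta_sbp_mmhg, te$reference_delta_mmhg)
}

# Apply a hazard-scale or probability-scale multiplier to a probability.
.apply_mult <- function(p, mult, scale = "hazard") {
  if (scale == "hazard") 1 - (1 - p)^mult else pmin(p * mult, 1)
}

#' Per-cycle cardiovascular event probability
#'
#' Converts a patient's 10-year cardiovascular risk into a per-cycle
#' probability (constant hazard), applies the prior-CVD multiplier (1.5 on
#' the hazard scale by default) for patients with at least one previous
#' cardiovascular event, and, in the medication-reduction arm while the
#' treatment effect lasts, multiplies the CHD and cerebrovascular halves of
#' the risk by their interpolated relative risks.
#'
#' @param patient One-row cohort data frame (or list) with
#'   \code{ten_year_cvd_risk} and \code{n_prior_cvd}.
#' @param params A \code{deprescr_params} object.
#' @param arm \code{"usual_care"} or \code{"reduction"}.
#' @param elapsed_years Model time since baseline (years).
#' @param cycle_length_years Cycle length (default 0.25).
#' @return Total per-cycle CVD event probability (capped at 1).
#' @export
cvd_event_prob <- function(patient, params, arm = "usual_care",
                           elapsed_years = 0, cycle_length_years = 0.25) {
  arm <- match.arg(arm, c("usual_care", "reduction"))
  risk <- patient$ten_year_cvd_risk
  mult <- ifelse(patient$n_prior_cvd >= 1,
                 params$event_risks$prior_cvd_multiplier, 1)
  scale <- params$options$risk_multiplier_scale
  base <- prob_rescale(risk, 10, cycle_length_years)
  base <- .apply_mult(base, mult, scale)
  split <- params$event_risks$chd_cerebro_split
  p <- split[["chd"]] * base *
         .effective_rr(params, "chd", arm, elapsed_years) +
       split[["cerebro"]] * base *
         .effective_rr(params, "stroke_tia", arm, elapsed_years)
  pmin(p, 1)
}

# age band labels used by the event-type fraction tables
.type_band <- function(age, sex) {
  if (any(age < 75)) stop("event-type fractions only cover ages >= 75")
  paste0(sex, ifelse(age < 85, "_75_84", "_85p"))
}

#' Classify a cardiovascular event into its subtype
#'
#' Draws coronary heart disease vs cerebrovascular at the configured split
#' (50:50 in the base case), then the subtype — MI / ACS / stable angina, or
#' stroke / TIA — from the sex-and-age-band fraction table.
#'
#' @param age Age in years (>= 75).
#' @param sex \code{"M"} or \code{"F"}.
#' @param params A \code{deprescr_params} object.
#' @param u Optional vector of up to two uniforms (class draw, subtype draw)
#'   for external random streams; drawn internally when missing.
#' @return One of \code{"mi"}, \code{"acs"}, \code{"angina"},
#'   \code{"stroke"}, \code{"tia"}.
#' @export
classify_cvd_event <- function(age, sex, params, u = NULL) {
  if (is.null(u)) u <- runif(2)
  band <- .type_band(age, sex)
  er <- params$event_risks
  if (u[1] < er$chd_cerebro_split[["chd"]]) {
    fr <- er$chd_type_fractions[[band]]
  } else {
    fr <- er$cerebro_type_fractions[[band]]
  }
  names(fr)[findInterval(u[2], cumsum(fr), left.open = TRUE) + 1L]
}

#' Per-cycle heart-failure probability
#'
#' Age-banded annual heart-failure risk (80-84 / 85-89 / 90+) rescaled to
#' the cycle length, with the interpolated heart-failure relative risk
#' applied in the medication-reduction arm while the effect lasts.
#'
#' @inheritParams cvd_event_prob
#' @param age Age in years (>= 80).
#' @return Per-cycle heart-failure event probability.
#' @export
hf_prob <- function(age, params, arm = "usual_care", elapsed_years = 0,
                    cycle_length_years = 0.25) {
  arm <- match.arg(arm, c("usual_care", "reduction"))
  if (any(age < 80)) stop("heart-failure risk bands start at age 80")
  bands <- params$event_risks$hf_annual_risk
  annual <- bands[ifelse(age < 85, 1L, ifelse(age < 90, 2L, 3L))]
  p <- prob_rescale(unname(annual), 1, cycle_length_years)
  pmin(p * .effective_rr(params, "hf", arm, elapsed_years), 1)
}

#' Per-cycle adverse-event probabilities
#'
#' Annual risks of serious (hospitalised fall / acute kidney injury) and
#' minor antihypertensive-related adverse events rescaled to the cycle, with
#' the single adverse-event relative risk (0.685 in the base case) applied
#' to both classes in the medication-reduction arm while the effect lasts.
#'
#' @inheritParams cvd_event_prob
#' @return Named vector \code{c(serious =, minor =)} of per-cycle
#'   probabilities.
#' @export
adverse_event_probs <- function(params, arm = "usual_care",
                                elapsed_years = 0,
                                cycle_length_years = 0.25) {
  arm <- match.arg(arm, c("usual_care", "reduction"))
  er <- params$event_risks
  c(serious = min(1, prob_rescale(er$sae_annual_risk, 1, cycle_length_years) *
        .effective_rr(params, "sae", arm, elapsed_years)),
    minor = min(1, prob_rescale(er$minor_ae_annual_risk, 1,
                                cycle_length_years) *
        .effective_rr(params, "minor", arm, elapsed_years)))
}

#' Per-cycle death probability
#'
#' Background non-circulatory mortality from the life table, by current age
#' and sex, rescaled to the cycle length. In a post-event health state the
#' annual hazard is multiplied by the state's standardised mortality ratio
#' before rescaling, so the per-cycle probability is
#' \code{1 - (1 - qx)^(SMR * cycle_length)}. Ages beyond the table use its
#' terminal row.
#'
#' @param age Age in years.
#' @param sex \code{"M"} or \code{"F"}.
#' @param state Health-state name (\code{"event_free"}, \code{"post_mi"},
#'   ..., see package overview); \code{"event_free"} means SMR 1.
#' @param params A \code{deprescr_params} object.
#' @param cycle_length_years Cycle length (default 0.25).
#' @return Per-cycle death probability, capped at 1.
#' @export
death_prob <- function(age, sex, state = "event_free", params,
                       cycle_length_years = 0.25) {
  lt <- params$mortality$life_table
  qx <- mapply(function(a, s) {
    rows <- lt[lt$sex == s, ]
    if (nrow(rows) == 0) stop("sex '", s, "' not in life table")
    if (a < min(rows$age)) stop("age ", a, " below life table range")
    i <- findInterval(a, rows$age)
    rows$qx_noncvd[min(i, nrow(rows))]
  }, age, sex)
  smr <- ifelse(state == "event_free", 1,
                params$mortality$smr[sub("^post_", "", state)])
  pmin(1 - (1 - qx)^(unname(smr) * cycle_length_years), 1)
}
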