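#' Per-cycle utility score
#'
#' Health-state utility for one cycle: the patient's baseline EQ-5D index
#' multiplied by the long-term state multiplier (stroke 0.629, MI 0.778,
#' ACS 0.77, stable angina 0.88, HF 0.68, serious fall 0.797; post-TIA and
#' post-AKI carry no multiplier), minus the lifelong absolute AKI decrement
#' while post-AKI, minus the within-cycle average of any transient
#' (one-month) decrement for a TIA or minor adverse event occurring this
#' cycle, plus any deprescribing utility gain in the reduction arm. The
#' score is floored at 0.
#'
#' The transient decrement enters as \code{decrement / 12 / cycle_length},
#' so that one cycle at this score loses exactly \code{decrement / 12}
#' QALYs (one month at the full annual decrement).
#'
#' @param state Health-state name(s) (\code{"event_free"}, \code{"post_mi"},
#'   ...).
#' @param baseline_utility Patient baseline EQ-5D index.
#' @param params A \code{deprescr_params} object.
#' @param transient_decrement_annual Annual-scale decrement of a transient
#'   event occurring this cycle (0 when none), e.g.
#'   \code{params$utility$decrements_annual[["tia"]]}.
#' @param arm \code{"usual_care"} or \code{"reduction"}.
#' @param cycle_length_years Cycle length in years.
#' @return Utility score(s) for the cycle, in \code{[0, 1]}-index units.
#' @export
#' @examples
#' cycle_utility("post_hf", 0.769, default_parameters())  # 0.769 * 0.68
cycle_utility <- function(state, baseline_utility, params,
                          transient_decrement_annual = 0,
                          arm = "usual_care", cycle_length_years = 0.25) {
  mult <- .state_multiplier_vector(params)[state]
  if (any(is.na(mult))) stop("unknown health state")
  aki_dec <- params$utility$decrements_annual[["aki"]]
  gain <- if (arm == "reduction") params$utility$deprescribe_utility_gain else 0
  score <- baseline_utility * unname(mult) -
    ifelse(state == "post_aki", aki_dec, 0) + gain -
    transient_decrement_annual / 12 / cycle_length_years
  pmax(score, 0)
}

# utility multiplier by state name; 1 for event-free, post-TIA, post-AKI
.state_multiplier_vector <- function(params) {
  m <- setNames(rep(1, length(.states)), .states)
  sm <- params$utility$state_multipliers
  m[paste0("post_", names(sm))] <- sm
  m["dead"] <- 0
  m
}

#' Per-cycle cost
#'
#' Adds up, for one cycle: routine primary-care consultations (0.8 per
#' 3-month cycle by default), antihypertensive prescription costs for the
#' drugs on the current regimen, the one-off 4-week safety visit in the
#' first cycle of the medication-reduction arm, the reinstatement visit in
#' cycle 1 for reduction patients who did not maintain the reduction, the
#' acute event cost when a serious event occurs this cycle (or the minor-AE
#' cost for a minor event), and the long-term per-cycle cost of an
#' established post-event state.
#'
#' @param state Health-state name at the start of the cycle (before any
#'   event this cycle); long-term costs apply when it is a post-event state.
#' @param arm \code{"usual_care"} or \code{"reduction"}.
#' @param cycle 0-based cycle index.
#' @param n_drugs Drugs prescribed at baseline (usual-care regimen).
#' @param maintained For reduction-arm patients, whether the reduction was
#'   maintained beyond the safety visit.
#' @param event Event occurring this cycle: \code{"none"}, one of the
#'   serious event types (\code{"mi"}, ..., \code{"aki"}) or
#'   \code{"minor"}.
#' @param params A \code{deprescr_params} object.
#' @return Cost in GBP for the cycle.
#' @export
cycle_cost <- function(state, arm, cycle, n_drugs, maintained = TRUE,
                       event = "none", params) {
  co <- params$costs
  n <- max(length(state), length(event), length(n_drugs), length(maintained))
  state <- rep_len(state, n); event <- rep_len(event, n)
  n_drugs <- rep_len(n_drugs, n); maintained <- rep_len(maintained, n)
  drugs_now <- if (arm == "reduction") {
    ifelse(cycle == 0 | maintained, n_drugs - 1L, n_drugs)
  } else n_drugs
  cost <- co$consultations_per_cycle * co$cost_per_consultation +
    drugs_now * co$cost_per_drug_per_cycle
  if (arm == "reduction") {
    if (cycle == 0) cost <- cost + co$safety_visit_cost
    if (cycle == 1) cost <- cost + ifelse(maintained, 0,
                                          co$reinstatement_visit_cost)
  }
  acute <- ifelse(event == "none", 0,
                  ifelse(event == "minor", co$minor_ae_cost,
                         co$acute_event_costs[event]))
  lt <- ifelse(state %in% c("event_free", "dead"), 0,
               co$longterm_event_costs_per_cycle[sub("^post_", "", state)])
  unname(cost + acute + lt)
}

#' Discount factor
#'
#' \code{(1 + rate)^(-time_years)}: present-value weight of a cost or
#' outcome accruing \code{time_years} after baseline at an annual discount
#' rate (3.5\% in the base case).
#'
#' @param time_years Time since baseline (years).
#' @param rate Annual discount rate (>= 0).
#' @return Discount factor(s) in \code{(0, 1]}.
#' @export
discount_factor <- function(time_years, rate) {
  if (any(rate < 0)) stop("discount rate must be >= 0")
  (1 + rate)^(-time_years)
}

#' Accrue one cycle's economics
#'
#' Turns a cycle record (utility score and cost) into undiscounted and
#' discounted QALY and cost increments. The QALY increment is
#' \code{utility * cycle_length}. With the half-cycle correction on
#' (midpoint-discounting variant), the discount factor is evaluated at the
#' cycle midpoint \code{(cycle + 0.5) * cycle_length}; off, at the cycle
#' start.
#'
#' @param record List or data frame with \code{cycle} (0-based),
#'   \code{utility} and \code{cost}.
#' @param config A \code{\link{simulation_config}}.
#' @return Data frame with \code{qaly}, \code{cost}, \code{disc_qaly},
#'   \code{disc_cost}, \code{discount}.
#' @export
#' @examples
#' accrue(list(cycle = 0, utility = 1, cost = 0), simulation_config())
accrue <- function(record, config) {
  cl <- config$cycle_length_years
  t_eval <- if (config$half_cycle_correction) {
    (record$cycle + 0.5) * cl
  } else record$cycle * cl
  df <- discount_factor(t_eval, config$discount_rate_annual)
  data.frame(qaly = record$utility * cl, cost = record$cost,
             disc_qaly = record$utility * cl * df,
             disc_cost = record$cost * df, discount = df)
}
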