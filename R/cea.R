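#' Incremental cost-effectiveness comparison
#'
#' Compares two strategies: incremental cost \code{cost_a - cost_b},
#' incremental QALYs \code{qaly_a - qaly_b}, and their ratio (the ICER) when
#' the comparison is a genuine trade-off. Dominance cases are labelled
#' rather than producing a ratio: \code{"dominant"} (strategy A cheaper and
#' at least as effective, or equally cheap and more effective),
#' \code{"dominated"} (the reverse), \code{"equivalent"} (both increments
#' inside \code{tol}), otherwise \code{"tradeoff"}.
#'
#' By package convention strategy A is usual care and strategy B medication
#' reduction, so positive increments mean usual care costs more and yields
#' more QALYs.
#'
#' @param cost_a,qaly_a Mean cost and QALYs of strategy A (reference
#'   presentation: usual care).
#' @param cost_b,qaly_b Mean cost and QALYs of strategy B (medication
#'   reduction).
#' @param labels Character pair naming strategies A and B.
#' @param tol Equivalence tolerance on both increments.
#' @return An object of class \code{deprescr_cea}: list with
#'   \code{delta_cost}, \code{delta_qaly}, \code{icer} (NA unless
#'   trade-off), \code{label}, \code{strategies}.
#' @export
#' @examples
#' compute_icer(4745, 3.405, 4560, 3.343)  # ICER ~ 2984 GBP/QALY
compute_icer <- function(cost_a, qaly_a, cost_b, qaly_b,
                         labels = c("usual_care", "reduction"),
                         tol = 1e-9) {
  stopifnot(is.finite(cost_a), is.finite(qaly_a), is.finite(cost_b),
            is.finite(qaly_b))
  dc <- cost_a - cost_b
  dq <- qaly_a - qaly_b
  if (abs(dc) <= tol && abs(dq) <= tol) {
    label <- "equivalent"
  } else if (dq >= -tol && dc <= tol) {
    label <- "dominant"          # A no worse on both, better on one
  } else if (dq <= tol && dc >= -tol) {
    label <- "dominated"
  } else {
    label <- "tradeoff"
  }
  icer <- if (label == "tradeoff") dc / dq else NA_real_
  structure(list(delta_cost = dc, delta_qaly = dq, icer = icer,
                 label = label, strategies = labels),
            class = "deprescr_cea")
}

#' @export
print.deprescr_cea <- function(x, ...) {
  cat(sprintf("  Incremental (%s - %s): cost £%.0f, QALYs %.3f",
              x$strategies[1], x$strategies[2], x$delta_cost, x$delta_qaly))
  if (x$label == "tradeoff") {
    cat(sprintf(" -> ICER £%.0f/QALY\n", x$icer))
  } else cat(sprintf(" -> %s (%s)\n", x$label, x$strategies[1]))
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Repeatedly redraws the uncertain parameters from their fitted
#' distributions (see \code{\link{draw_psa_parameters}}), reruns both arms,
#' and records the incremental cost and QALY pair (usual care minus
#' medication reduction) of each iteration. By default every iteration also
#' redraws a fresh cohort, so the cloud reflects parameter and first-order
#' (patient-level) uncertainty together; set \code{fresh_cohort = FALSE} to
#' pin one cohort across iterations.
#'
#' @param params A \code{deprescr_params} object with PSA specs.
#' @param config A \code{\link{simulation_config}} (its \code{n_patients}
#'   is the per-iteration cohort size; its \code{seed} is the master seed).
#' @param n_iterations Number of PSA iterations.
#' @param spec Cohort specification for generated cohorts.
#' @param fresh_cohort Redraw the cohort each iteration (default
#'   \code{TRUE}).
#' @return An object of class \code{deprescr_psa}: data frame of
#'   \code{(iteration, delta_cost, delta_qaly)} plus per-arm means, with the
#'   run configuration attached.
#' @export
run_psa <- function(params, config = simulation_config(),
                    n_iterations = 1000, spec = cohort_spec(),
                    fresh_cohort = TRUE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  base_seed <- config$seed
  cohort <- if (!fresh_cohort)
    generate_cohort(spec, config$n_patients, seed = base_seed + 7L)
  rows <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    p_i <- draw_psa_parameters(params, seed = base_seed + 30000L + i)
    coh_i <- if (fresh_cohort) {
      generate_cohort(spec, config$n_patients, seed = base_seed + 10000L + i)
    } else cohort
    cfg_i <- config
    # fixed-cohort mode also pins the engine stream, so iterations differ
    # only through the parameter draws
    cfg_i$seed <- base_seed + 20000L + if (fresh_cohort) i else 0L
    usual <- run_arm(coh_i, "usual_care", p_i, cfg_i)
    red <- run_arm(coh_i, "reduction", p_i, cfg_i)
    rows[[i]] <- data.frame(iteration = i,
                            cost_usual = usual$mean_cost,
                            qaly_usual = usual$mean_qaly,
                            cost_reduction = red$mean_cost,
                            qaly_reduction = red$mean_qaly,
                            delta_cost = usual$mean_cost - red$mean_cost,
                            delta_qaly = usual$mean_qaly - red$mean_qaly)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "n_iterations") <- n_iterations
  class(out) <- c("deprescr_psa", "data.frame")
  out
}

#' @export
print.deprescr_psa <- function(x, ...) {
  cat(sprintf("PSA: %d iterations x %d patients\n",
              attr(x, "n_iterations"), attr(x, "config")$n_patients))
  cat(sprintf("  mean delta cost £%.0f, mean delta QALYs %.4f (usual care - reduction)\n",
              mean(x$delta_cost), mean(x$delta_qaly)))
  for (wtp in attr(x, "config")$wtp_thresholds)
    cat(sprintf("  P(usual care cost-effective at £%.0f/QALY) = %.3f\n",
                wtp, mean(wtp * x$delta_qaly - x$delta_cost > 0) +
                  0.5 * mean(wtp * x$delta_qaly - x$delta_cost == 0)))
  invisible(x)
}

#' @export
plot.deprescr_psa <- function(x, ...) {
  plot(x$delta_qaly, x$delta_cost,
       xlab = "Incremental QALYs (usual care - reduction)",
       ylab = "Incremental cost, GBP (usual care - reduction)",
       main = "Cost-effectiveness plane", pch = 20,
       col = "#00000055", ...)
  abline(h = 0, v = 0, col = "grey50")
  for (wtp in attr(x, "config")$wtp_thresholds)
    abline(a = 0, b = wtp, lty = 2, col = "grey30")
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value \eqn{\lambda}, the probability (over
#' PSA iterations) that each strategy has the larger net monetary benefit:
#' usual care is preferred in an iteration when
#' \eqn{\lambda \Delta Q - \Delta C > 0}. Exact ties are split 0.5/0.5 so
#' the two curves always sum to 1.
#'
#' @param psa A \code{deprescr_psa} object (or data frame with
#'   \code{delta_cost}, \code{delta_qaly}).
#' @param wtp_grid Non-empty numeric vector of willingness-to-pay values
#'   (GBP/QALY).
#' @return An object of class \code{deprescr_ceac}: data frame with
#'   \code{wtp}, \code{p_usual_care}, \code{p_reduction}.
#' @export
compute_ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be non-empty")
  if (NROW(psa) == 0) stop("PSA result is empty")
  p_usual <- vapply(wtp_grid, function(l) {
    nmb <- l * psa$delta_qaly - psa$delta_cost
    mean(nmb > 0) + 0.5 * mean(nmb == 0)
  }, numeric(1))
  out <- data.frame(wtp = wtp_grid, p_usual_care = p_usual,
                    p_reduction = 1 - p_usual)
  class(out) <- c("deprescr_ceac", "data.frame")
  out
}

#' @export
plot.deprescr_ceac <- function(x, ...) {
  plot(x$wtp, x$p_usual_care, type = "l", ylim = c(0, 1),
       xlab = "Willingness to pay (GBP/QALY)",
       ylab = "P(strategy is cost-effective)",
       main = "Cost-effectiveness acceptability curve", ...)
  lines(x$wtp, x$p_reduction, lty = 2)
  legend("right", c("usual care", "medication reduction"), lty = 1:2,
         bty = "n")
  invisible(x)
}

# Deterministic incremental result (usual care - reduction) for one
# parameter value: the evaluation inside threshold_search, always on the
# same cohort and seeds so the map value -> (dC, dQ) is noise-free.
.incremental_eval <- function(params, config, cohort) {
  usual <- run_arm(cohort, "usual_care", params, config)
  red <- run_arm(cohort, "reduction", params, config)
  list(dc = usual$mean_cost - red$mean_cost,
       dq = usual$mean_qaly - red$mean_qaly)
}

#' Threshold analysis by bisection
#'
#' Finds the value of one model parameter at which usual care stops being
#' cost-effective against medication reduction at a willingness-to-pay
#' threshold \eqn{\lambda}. The search bisects on the sign of the
#' incremental net monetary benefit of usual care,
#' \eqn{\lambda \Delta Q - \Delta C}, which is monotone along the searched
#' parameter and remains well-defined where one strategy dominates; at the
#' crossing the ICER equals \eqn{\lambda}. Simulation noise is pinned by
#' running every evaluation on the same cohort with the same seeds (common
#' random numbers), so the searched function is deterministic and bisection
#' converges.
#'
#' @param params A \code{deprescr_params} object.
#' @param parameter_path Dot-separated path of the searched parameter, e.g.
#'   \code{"event_risks.sae_annual_risk"} or
#'   \code{"utility.deprescribe_utility_gain"}.
#' @param wtp Willingness-to-pay threshold (GBP/QALY).
#' @param bracket Length-2 numeric interval to search; the ICER minus
#'   \code{wtp} must change sign over it.
#' @param config A \code{\link{simulation_config}}; its \code{n_patients}
#'   sets the precision of each deterministic evaluation.
#' @param spec Cohort spec for the shared evaluation cohort.
#' @param tol_icer Convergence tolerance on \code{|ICER - wtp|}
#'   (GBP/QALY).
#' @param max_iter Maximum bisection steps.
#' @param icer_fn Optional function \code{value -> ICER} replacing the
#'   model evaluation (used to verify convergence on closed-form stubs).
#' @return An object of class \code{deprescr_threshold}: list with
#'   \code{parameter}, \code{threshold}, \code{icer_at_threshold},
#'   \code{wtp}, \code{bracket}, \code{iterations}.
#' @export
threshold_search <- function(params, parameter_path, wtp,
                             bracket, config = simulation_config(),
                             spec = cohort_spec(), tol_icer = 250,
                             max_iter = 60, icer_fn = NULL) {
  stopifnot(length(bracket) == 2, bracket[1] < bracket[2])
  if (is.null(icer_fn)) {
    cohort <- generate_cohort(spec, config$n_patients,
                              seed = config$seed + 7L)
    # objective: incremental NMB of usual care; ICER reported alongside
    eval_at <- function(x) {
      inc <- .incremental_eval(set_parameter(params, parameter_path, x),
                               config, cohort)
      list(f = wtp * inc$dq - inc$dc,
           icer = if (inc$dq != 0) inc$dc / inc$dq else NA_real_)
    }
    done <- function(e) !is.na(e$icer) && abs(e$icer - wtp) <= tol_icer
  } else {
    eval_at <- function(x) {
      ic <- icer_fn(x)
      list(f = if (is.finite(ic)) wtp - ic else -Inf, icer = ic)
    }
    done <- function(e) is.finite(e$icer) && abs(e$icer - wtp) <= tol_icer
  }
  elo <- eval_at(bracket[1]); ehi <- eval_at(bracket[2])
  if (sign(elo$f) == sign(ehi$f))
    stop("objective does not change sign over the bracket [",
         bracket[1], ", ", bracket[2], "]: the ICER does not cross the ",
         "willingness-to-pay there")
  lo <- bracket[1]; hi <- bracket[2]
  it <- 0L; mid <- (lo + hi) / 2; emid <- elo
  while (it < max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    emid <- eval_at(mid)
    if (done(emid)) break
    if (sign(emid$f) == sign(ehi$f)) {
      hi <- mid; ehi <- emid
    } else {
      lo <- mid; elo <- emid
    }
    if ((hi - lo) < .Machine$double.eps * max(1, abs(hi))) break
  }
  structure(list(parameter = parameter_path, threshold = mid,
                 icer_at_threshold = emid$icer, wtp = wtp,
                 bracket = bracket, iterations = it),
            class = "deprescr_threshold")
}

#' @export
print.deprescr_threshold <- function(x, ...) {
  cat(sprintf("Threshold analysis on '%s' at WTP £%.0f/QALY:\n",
              x$parameter, x$wtp))
  cat(sprintf("  threshold value %.6g (ICER there £%.0f/QALY; %d bisection steps)\n",
              x$threshold, x$icer_at_threshold, x$iterations))
  invisible(x)
}

#' Deterministic sensitivity and subgroup scenarios
#'
#' Runs a list of named scenarios on a shared cohort and seed. Each scenario
#' is a list with any of: \code{params} (named list
#' \code{path = value} of parameter overrides, paths as in
#' \code{\link{set_parameter}}), \code{config} (overrides of
#' \code{\link{simulation_config}} fields), and \code{subset} (an
#' expression string over cohort columns selecting a subgroup, e.g.
#' \code{"frailty == 'frail'"}).
#'
#' @param params A \code{deprescr_params} object.
#' @param scenario_specs Named list of scenario specs; see
#'   \code{\link{default_scenarios}}.
#' @param config A \code{\link{simulation_config}}.
#' @param spec Cohort spec for the shared cohort.
#' @return An object of class \code{deprescr_scenarios}: data frame with
#'   one row per scenario (\code{cost_usual, qaly_usual, cost_reduction,
#'   qaly_reduction, delta_cost, delta_qaly, icer, label}).
#' @export
run_scenarios <- function(params, scenario_specs,
                          config = simulation_config(),
                          spec = cohort_spec()) {
  if (is.null(names(scenario_specs)) || any(names(scenario_specs) == ""))
    stop("scenario_specs must be a named list")
  cohort <- generate_cohort(spec, config$n_patients, seed = config$seed + 7L)
  rows <- lapply(names(scenario_specs), function(nm) {
    sc <- scenario_specs[[nm]]
    bad <- setdiff(names(sc), c("params", "config", "subset"))
    if (length(bad)) stop("scenario '", nm, "': unknown field(s) ",
                          paste(bad, collapse = ", "))
    p <- params
    for (path in names(sc$params))
      p <- set_parameter(p, path, sc$params[[path]])
    cfg <- config
    for (k in names(sc$config)) {
      if (!k %in% names(unclass(cfg)))
        stop("scenario '", nm, "': unknown config field '", k, "'")
      cfg[[k]] <- sc$config[[k]]
    }
    coh <- cohort
    if (!is.null(sc$subset)) {
      keep <- eval(parse(text = sc$subset), envir = as.data.frame(cohort))
      coh <- cohort[keep, , drop = FALSE]
      if (nrow(coh) == 0) stop("scenario '", nm, "': empty subgroup")
    }
    usual <- run_arm(coh, "usual_care", p, cfg)
    red <- run_arm(coh, "reduction", p, cfg)
    cea <- compute_icer(usual$mean_cost, usual$mean_qaly,
                        red$mean_cost, red$mean_qaly)
    data.frame(scenario = nm, n = nrow(coh),
               cost_usual = usual$mean_cost, qaly_usual = usual$mean_qaly,
               cost_reduction = red$mean_cost,
               qaly_reduction = red$mean_qaly,
               delta_cost = cea$delta_cost, delta_qaly = cea$delta_qaly,
               icer = cea$icer, label = cea$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("deprescr_scenarios", "data.frame")
  out
}

#' Built-in deterministic sensitivity scenario set
#'
#' The published deterministic sensitivity and subgroup analyses: relative
#' risks at their 95\% CI bounds and at 1, halved cardiovascular risk, the
#' lower-CI blood-pressure difference (1 mmHg), treatment-effect durations
#' of 1/5/10 years, a 5-year horizon, and frailty / prior-CVD subgroups.
#'
#' @param params The parameter set the scenarios perturb (used for CI
#'   values).
#' @return Named list of scenario specs for \code{\link{run_scenarios}}.
#' @export
default_scenarios <- function(params = default_parameters()) {
  ci <- params$treatment_effect$rr_ci
  rr_at <- function(which) {
    out <- list()
    for (nm in names(ci))
      out[[paste0("treatment_effect.rr.", nm)]] <- ci[[nm]][which]
    out
  }
  rr_one <- setNames(as.list(rep(1, length(ci))),
                     paste0("treatment_effect.rr.", names(ci)))
  list(
    base_case = list(),
    rr_lower_ci = list(params = rr_at(1)),
    rr_upper_ci = list(params = rr_at(2)),
    rr_equal_1 = list(params = rr_one),
    delta_sbp_1mmhg = list(params = list(
      "treatment_effect.delta_sbp_mmhg" = 1.0)),
    effect_1y = list(params = list(
      "treatment_effect.effect_duration_years" = 1)),
    effect_5y = list(params = list(
      "treatment_effect.effect_duration_years" = 5)),
    effect_10y = list(params = list(
      "treatment_effect.effect_duration_years" = 10)),
    horizon_5y = list(config = list(max_horizon_years = 5)),
    subgroup_fit = list(subset = "frailty == 'fit'"),
    subgroup_frail = list(subset = "frailty == 'frail'"),
    subgroup_no_prior_cvd = list(subset = "n_prior_cvd == 0"),
    subgroup_prior_cvd_1 = list(subset = "n_prior_cvd == 1"),
    subgroup_prior_cvd_2p = list(subset = "n_prior_cvd == 2")
  )
}

# halved CVD risk is a cohort-level transformation, exposed as a helper so
# scenarios and callers can build the modified cohort explicitly
#' Halve every patient's 10-year cardiovascular risk
#' @param cohort A \code{deprescr_cohort}.
#' @return The cohort with \code{ten_year_cvd_risk} halved.
#' @export
halve_cvd_risk <- function(cohort) {
  cohort$ten_year_cvd_risk <- cohort$ten_year_cvd_risk / 2
  cohort
}
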