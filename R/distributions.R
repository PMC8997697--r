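#' Fit a sampling distribution to a point estimate and interval
#'
#' Builds a probabilistic-sensitivity-analysis distribution spec from a point
#' estimate and, where available, a 95\% confidence interval. Conventions
#' follow standard health-economics practice: beta for probabilities and
#' utilities, gamma for costs, lognormal for relative risks and standardised
#' mortality ratios, \code{fixed} for parameters excluded from PSA.
#'
#' With a CI, the lognormal takes \code{meanlog = log(point)} (median at the
#' point estimate, the usual convention for a ratio reported with a log-scale
#' CI) and \code{sdlog = (log(hi) - log(lo)) / (2 * 1.95996)}. Beta and gamma
#' are fitted by moment matching with \code{se = (hi - lo) / (2 * 1.95996)}.
#' Without a CI, the standard error defaults to \code{se_fraction} of the
#' point estimate (20\% unless overridden), and the lognormal is then fitted
#' mean-matching.
#'
#' @param point Point estimate.
#' @param ci_low,ci_high 95\% interval bounds, or \code{NULL} when
#'   unpublished.
#' @param family One of \code{"beta"}, \code{"gamma"}, \code{"lognormal"},
#'   \code{"fixed"}.
#' @param se Standard error, overriding both the CI and the default
#'   convention.
#' @param se_fraction CI-absent convention: \code{se = se_fraction * point}.
#' @return A \code{deprescr_dist} object: list with \code{family},
#'   \code{point} and the family's parameters.
#' @export
#' @examples
#' fit_distribution(1.290, 1.134, 1.472, "lognormal")$sdlog  # ~0.0665
fit_distribution <- function(point, ci_low = NULL, ci_high = NULL,
                             family = c("beta", "gamma", "lognormal", "fixed"),
                             se = NULL, se_fraction = 0.2) {
  family <- match.arg(family)
  z <- qnorm(0.975)
  if (family == "fixed")
    return(structure(list(family = "fixed", point = point),
                     class = "deprescr_dist"))
  if (!is.finite(point)) stop("point estimate must be finite")
  has_ci <- !is.null(ci_low) && !is.null(ci_high)
  if (has_ci && !(ci_low <= point && point <= ci_high))
    stop("confidence interval [", ci_low, ",", ci_high,
         "] does not bracket the point estimate ", point)
  if (is.null(se)) {
    se <- if (has_ci) (ci_high - ci_low) / (2 * z) else se_fraction * point
  }
  if (family == "lognormal") {
    if (point <= 0) stop("lognormal requires a positive point estimate")
    if (has_ci) {
      sdlog <- (log(ci_high) - log(ci_low)) / (2 * z)
      meanlog <- log(point)
    } else {
      cv <- se / point
      sdlog <- sqrt(log(1 + cv^2))
      meanlog <- log(point) - sdlog^2 / 2  # mean-matching
    }
    out <- list(family = "lognormal", point = point,
                meanlog = meanlog, sdlog = sdlog)
  } else if (family == "beta") {
    if (point <= 0 || point >= 1)
      stop("beta requires a point estimate strictly inside (0,1)")
    if (se^2 >= point * (1 - point))
      stop("beta moment match infeasible: se^2 = ", format(se^2),
           " >= mean*(1-mean) = ", format(point * (1 - point)))
    nu <- point * (1 - point) / se^2 - 1
    out <- list(family = "beta", point = point,
                shape1 = point * nu, shape2 = (1 - point) * nu)
  } else { # gamma
    if (point <= 0) stop("gamma requires a positive point estimate")
    out <- list(family = "gamma", point = point,
                shape = (point / se)^2, rate = point / se^2)
  }
  structure(out, class = "deprescr_dist")
}

#' Draw from a fitted distribution spec
#'
#' @param spec A \code{deprescr_dist} from \code{\link{fit_distribution}}.
#' @param n Number of draws.
#' @return Numeric vector of length \code{n}.
#' @export
draw_distribution <- function(spec, n = 1) {
  switch(spec$family,
    fixed = rep(spec$point, n),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    beta = rbeta(n, spec$shape1, spec$shape2),
    gamma = rgamma(n, spec$shape, rate = spec$rate),
    stop("unknown distribution family: ", spec$family))
}

#' @export
print.deprescr_dist <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "point"))]
  cat(sprintf("%s(point %.4g%s)\n", x$family, x$point,
              if (length(pars)) paste0("; ", paste(names(pars),
                signif(unlist(pars), 4), sep = "=", collapse = ", ")) else ""))
  invisible(x)
}

# The default PSA spec set: which parameters are uncertain, with which
# family, and (where published) which CI. Each entry: path into the
# parameter list, distribution spec, and an optional [0,1]/positivity bound
# used by the resample-on-violation loop in draw_psa_parameters().
default_psa_specs <- function(p) {
  sf <- p$options$ci_absent_se_fraction
  specs <- list()
  add <- function(path, spec) {
    specs[[length(specs) + 1]] <<- list(path = path, spec = spec)
  }
  for (nm in names(p$treatment_effect$rr)) {
    ci <- p$treatment_effect$rr_ci[[nm]]
    add(paste0("treatment_effect.rr.", nm),
        fit_distribution(p$treatment_effect$rr[[nm]], ci[1], ci[2],
                         "lognormal"))
  }
  add("treatment_effect.maintain_reduction_prob",
      fit_distribution(p$treatment_effect$maintain_reduction_prob,
                       family = "beta", se_fraction = sf))
  for (band in names(p$event_risks$hf_annual_risk))
    add(paste0("event_risks.hf_annual_risk.", band),
        fit_distribution(p$event_risks$hf_annual_risk[[band]],
                         family = "beta", se_fraction = sf))
  add("event_risks.sae_annual_risk",
      fit_distribution(p$event_risks$sae_annual_risk, family = "beta",
                       se_fraction = sf))
  add("event_risks.minor_ae_annual_risk",
      fit_distribution(p$event_risks$minor_ae_annual_risk, family = "beta",
                       se_fraction = sf))
  for (nm in names(p$mortality$smr))
    add(paste0("mortality.smr.", nm),
        fit_distribution(p$mortality$smr[[nm]], family = "lognormal",
                         se_fraction = sf))
  add("utility.baseline",
      fit_distribution(p$utility$baseline, family = "beta", se_fraction = sf))
  for (nm in names(p$utility$state_multipliers))
    add(paste0("utility.state_multipliers.", nm),
        fit_distribution(p$utility$state_multipliers[[nm]], family = "beta",
                         se_fraction = sf))
  for (nm in names(p$utility$decrements_annual))
    add(paste0("utility.decrements_annual.", nm),
        fit_distribution(p$utility$decrements_annual[[nm]], family = "beta",
                         se_fraction = sf))
  for (nm in c("cost_per_consultation", "cost_per_drug_per_cycle",
               "safety_visit_cost", "reinstatement_visit_cost"))
    add(paste0("costs.", nm),
        fit_distribution(p$costs[[nm]], family = "gamma", se_fraction = sf))
  for (nm in names(p$costs$acute_event_costs))
    add(paste0("costs.acute_event_costs.", nm),
        fit_distribution(p$costs$acute_event_costs[[nm]], family = "gamma",
                         se_fraction = sf))
  for (nm in names(p$costs$longterm_event_costs_per_cycle))
    add(paste0("costs.longterm_event_costs_per_cycle.", nm),
        fit_distribution(p$costs$longterm_event_costs_per_cycle[[nm]],
                         family = "gamma", se_fraction = sf))
  names(specs) <- vapply(specs, `[[`, "", "path")
  specs
}

#' Draw a probabilistic-sensitivity-analysis parameter set
#'
#' Resamples every parameter that carries a distribution spec (relative
#' risks and SMRs lognormal, probabilities and utilities beta, costs gamma);
#' everything else — including the life table, event-type fraction tables and
#' the BP difference used for interpolation — is left at its base value.
#' Draws that violate a type invariant are resampled (up to 100 attempts
#' each) before failing; the returned set is fully re-validated.
#'
#' @param params A \code{deprescr_params} object with \code{psa} specs.
#' @param seed Optional integer seed for reproducible draws.
#' @return A new, validated \code{deprescr_params} object.
#' @export
draw_psa_parameters <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- unclass(params)
  for (entry in p$psa) {
    spec <- entry$spec
    if (spec$family == "fixed") {
      val <- spec$point
    } else {
      ok <- FALSE
      for (attempt in 1:100) {
        val <- draw_distribution(spec, 1)
        if (.psa_value_ok(entry$path, val)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not draw a valid value for ", entry$path,
                    " in 100 attempts")
    }
    keys <- strsplit(entry$path, ".", fixed = TRUE)[[1]]
    p <- .assign_path(p, keys, val, entry$path)
  }
  class(p) <- "deprescr_params"
  validate_parameters(p)
  p
}

.psa_value_ok <- function(path, val) {
  if (!is.finite(val)) return(FALSE)
  if (grepl("^costs\\.", path)) return(val >= 0)
  if (grepl("^mortality\\.smr", path)) return(val >= 1)
  if (grepl("\\.rr\\.", path)) return(val > 0)
  val >= 0 && val <= 1
}

.assign_path <- function(node, keys, value, full) {
  k <- keys[1]
  if (is.null(names(node)) || !(k %in% names(node)))
    stop("unknown PSA parameter path: ", full, call. = FALSE)
  if (length(keys) == 1) node[[k]] <- value
  else node[[k]] <- .assign_path(node[[k]], keys[-1], value, full)
  node
}
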