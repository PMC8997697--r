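#' Cohort specification
#'
#' Describes the joint baseline distribution from which synthetic patients
#' are drawn, calibrated to the baseline table of the OPTiMISE
#' antihypertensive deprescribing trial (adults aged 80+ on two or more
#' antihypertensives): mean age 84.8 years, 51.5\% male, prior-CVD category
#' probabilities 42.9/29.5/27.6\%, mean EQ-5D index 0.769. Dispersions and
#' the 10-year cardiovascular risk distribution are not published at that
#' level of detail; their defaults are documented modelling choices.
#'
#' @param mean_age Target mean age in years.
#' @param age_sd Standard deviation of age (gamma-shaped offset above 80).
#' @param prob_male Probability a patient is male.
#' @param prior_cvd_probs Probabilities of 0, 1 and 2+ previous
#'   cardiovascular events; must sum to 1.
#' @param utility_mean Target mean baseline EQ-5D index (mean of the
#'   upper-truncated-at-1 normal actually sampled, calibrated internally).
#' @param utility_sd Pre-truncation standard deviation of baseline utility.
#' @param risk_mean,risk_sd Mean and SD of the beta-distributed 10-year
#'   cardiovascular risk.
#' @param frail_prob Prevalence of frailty (used by subgroup scenarios).
#' @param drug_count_probs Named probabilities over antihypertensive drug
#'   counts (names are the counts, all >= 2).
#' @return A \code{deprescr_cohort_spec} object.
#' @export
cohort_spec <- function(mean_age = 84.8, age_sd = 3.5, prob_male = 0.515,
                        prior_cvd_probs = c(`0` = 0.429, `1` = 0.295,
                                            `2+` = 0.276),
                        utility_mean = 0.769, utility_sd = 0.2,
                        risk_mean = 0.35, risk_sd = 0.15,
                        frail_prob = 0.5,
                        drug_count_probs = c(`2` = 0.5, `3` = 0.5)) {
  if (mean_age <= 80) stop("mean_age must exceed 80")
  if (abs(sum(prior_cvd_probs) - 1) > 1e-9)
    stop("prior_cvd_probs must sum to 1")
  for (p in c(prob_male, prior_cvd_probs, frail_prob, drug_count_probs))
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0,1]")
  if (abs(sum(drug_count_probs) - 1) > 1e-9)
    stop("drug_count_probs must sum to 1")
  if (any(as.integer(names(drug_count_probs)) < 2))
    stop("drug counts must be >= 2")
  if (risk_mean <= 0 || risk_mean >= 1) stop("risk_mean must be in (0,1)")
  if (risk_sd^2 >= risk_mean * (1 - risk_mean))
    stop("risk_sd too large for a beta distribution with this mean")
  if (utility_mean > 1) stop("utility_mean must be <= 1")
  structure(list(mean_age = mean_age, age_sd = age_sd, prob_male = prob_male,
                 prior_cvd_probs = prior_cvd_probs,
                 utility_mean = utility_mean, utility_sd = utility_sd,
                 risk_mean = risk_mean, risk_sd = risk_sd,
                 frail_prob = frail_prob,
                 drug_count_probs = drug_count_probs),
            class = "deprescr_cohort_spec")
}

# mu of a normal truncated above at `upper` whose *truncated* mean hits
# `target`; solved by root-finding so sample means calibrate to the target.
.truncnorm_mu <- function(target, sd, upper = 1) {
  if (sd == 0) return(target)
  tr_mean <- function(mu) {
    a <- (upper - mu) / sd
    mu - sd * dnorm(a) / pnorm(a)
  }
  uniroot(function(mu) tr_mean(mu) - target,
          lower = target, upper = upper + 8 * sd, tol = 1e-10)$root
}

.rtruncnorm_upper <- function(n, mu, sd, upper = 1) {
  out <- rnorm(n, mu, sd)
  bad <- which(out > upper)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mu, sd)
    bad <- bad[out[bad] > upper]
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Draws \code{n} independent patients from a \code{\link{cohort_spec}}:
#' age = 80 + gamma offset, sex Bernoulli, prior-CVD category multinomial,
#' 10-year cardiovascular risk beta, baseline utility upper-truncated normal
#' (calibrated so the truncated mean equals the spec target), frailty
#' Bernoulli and drug count categorical. Characteristics are mutually
#' independent.
#'
#' @param spec A \code{deprescr_cohort_spec}.
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; identical \code{(spec, n, seed)} reproduce the
#'   cohort exactly.
#' @return A data frame of class \code{deprescr_cohort} with columns
#'   \code{age, sex, n_prior_cvd, ten_year_cvd_risk, baseline_utility,
#'   frailty, n_drugs}.
#' @export
#' @examples
#' head(generate_cohort(cohort_spec(), 5, seed = 1))
generate_cohort <- function(spec = cohort_spec(), n, seed = NULL) {
  stopifnot(inherits(spec, "deprescr_cohort_spec"))
  if (length(n) != 1 || n < 1) stop("n must be a positive count")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  age_mean_off <- spec$mean_age - 80
  if (spec$age_sd > 0) {
    shape <- (age_mean_off / spec$age_sd)^2
    age <- 80 + rgamma(n, shape = shape, rate = age_mean_off / spec$age_sd^2)
  } else age <- rep(spec$mean_age, n)
  sex <- ifelse(runif(n) < spec$prob_male, "M", "F")
  n_prior_cvd <- sample(c(0L, 1L, 2L), n, replace = TRUE,
                        prob = spec$prior_cvd_probs)
  if (spec$risk_sd > 0) {
    nu <- spec$risk_mean * (1 - spec$risk_mean) / spec$risk_sd^2 - 1
    risk <- rbeta(n, spec$risk_mean * nu, (1 - spec$risk_mean) * nu)
  } else risk <- rep(spec$risk_mean, n)
  mu <- .truncnorm_mu(spec$utility_mean, spec$utility_sd, upper = 1)
  util <- .rtruncnorm_upper(n, mu, spec$utility_sd, upper = 1)
  frailty <- ifelse(runif(n) < spec$frail_prob, "frail", "fit")
  counts <- as.integer(names(spec$drug_count_probs))
  n_drugs <- sample(counts, n, replace = TRUE, prob = spec$drug_count_probs)
  out <- data.frame(age = age, sex = sex, n_prior_cvd = n_prior_cvd,
                    ten_year_cvd_risk = risk, baseline_utility = util,
                    frailty = frailty, n_drugs = n_drugs,
                    stringsAsFactors = FALSE)
  class(out) <- c("deprescr_cohort", "data.frame")
  out
}

#' Read a patient cohort from CSV
#'
#' Expects the header
#' \code{age,sex,n_prior_cvd,ten_year_cvd_risk,baseline_utility,frailty,n_drugs}
#' and validates every row against the patient invariants (age >= 80, risk
#' in \code{[0,1]}, utility <= 1, drug count >= 2, sex in \code{M/F}).
#'
#' @param path CSV file path.
#' @return A \code{deprescr_cohort} data frame.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "n_prior_cvd", "ten_year_cvd_risk",
            "baseline_utility", "frailty", "n_drugs")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have columns: ", paste(need, collapse = ","))
  df <- df[, need]
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stop("cohort row ", i[1], ": ", what, call. = FALSE)
  }
  bad(df$age < 80, "age must be >= 80")
  bad(!(df$sex %in% c("M", "F")), "sex must be M or F")
  bad(df$ten_year_cvd_risk < 0 | df$ten_year_cvd_risk > 1,
      "ten_year_cvd_risk must lie in [0,1]")
  bad(df$baseline_utility > 1, "baseline_utility must be <= 1")
  bad(df$n_drugs < 2, "n_drugs must be >= 2")
  bad(!(df$frailty %in% c("fit", "frail")), "frailty must be fit or frail")
  bad(!(df$n_prior_cvd %in% 0:2), "n_prior_cvd must be 0, 1 or 2 (2 = 2+)")
  class(df) <- c("deprescr_cohort", "data.frame")
  df
}

#' Summarise a cohort against its calibration targets
#'
#' @param cohort A \code{deprescr_cohort} (or compatible data frame).
#' @return A data frame with one row per calibration dimension (mean age,
#'   male fraction, prior-CVD category fractions, mean risk, mean utility,
#'   frail fraction, mean drug count), each with its Monte-Carlo standard
#'   error.
#' @export
summarize_cohort <- function(cohort) {
  if (NROW(cohort) == 0) stop("cohort is empty")
  n <- nrow(cohort)
  prop <- function(x) c(mean(x), sqrt(mean(x) * (1 - mean(x)) / n))
  mn <- function(x) c(mean(x), sd(x) / sqrt(n))
  rows <- rbind(
    mean_age = mn(cohort$age),
    frac_male = prop(cohort$sex == "M"),
    frac_prior_cvd_0 = prop(cohort$n_prior_cvd == 0),
    frac_prior_cvd_1 = prop(cohort$n_prior_cvd == 1),
    frac_prior_cvd_2p = prop(cohort$n_prior_cvd == 2),
    mean_risk = mn(cohort$ten_year_cvd_risk),
    mean_utility = mn(cohort$baseline_utility),
    frac_frail = prop(cohort$frailty == "frail"),
    mean_drugs = mn(cohort$n_drugs))
  out <- data.frame(statistic = rownames(rows), value = rows[, 1],
                    se = rows[, 2], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  out
}

#' @export
print.deprescr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic deprescribing cohort: %d patients\n", nrow(x)))
  s <- summarize_cohort(x)
  cat(sprintf("  mean age %.1f y, %.1f%% male, %.1f%% no prior CVD, mean EQ-5D %.3f\n",
              s$value[s$statistic == "mean_age"],
              100 * s$value[s$statistic == "frac_male"],
              100 * s$value[s$statistic == "frac_prior_cvd_0"],
              s$value[s$statistic == "mean_utility"]))
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' @importFrom stats dnorm pnorm
NULL
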