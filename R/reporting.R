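#' Event-incidence comparison table
#'
#' Builds the per-100,000 event-count table comparing the two arms, with a
#' signed difference column defined as medication-reduction count minus
#' usual-care count (positive = more events under medication reduction).
#'
#' @param arm_reduction,arm_usual \code{\link{arm_result}} objects from the
#'   same run (matching \code{run_id}s).
#' @return An object of class \code{deprescr_event_table}: list with the
#'   \code{table} data frame (\code{event, reduction, usual_care,
#'   difference}) and the shared \code{run_id}.
#' @export
#' @examples
#' r <- arm_result("reduction", 1e5, 4560, 3.343,
#'                 events_per_100k = c(hf = 22160, chd = 18177,
#'                                     stroke_tia = 19376,
#'                                     serious_ae = 4938, minor_ae = 39859))
#' u <- arm_result("usual_care", 1e5, 4745, 3.405,
#'                 events_per_100k = c(hf = 19421, chd = 18606,
#'                                     stroke_tia = 18692,
#'                                     serious_ae = 6376, minor_ae = 51568))
#' build_event_table(r, u)$table
build_event_table <- function(arm_reduction, arm_usual) {
  stopifnot(inherits(arm_reduction, "deprescr_arm"),
            inherits(arm_usual, "deprescr_arm"))
  if (!identical(arm_reduction$run_id, arm_usual$run_id))
    stop("arm results come from different runs: '", arm_reduction$run_id,
         "' vs '", arm_usual$run_id, "'")
  cats <- c("hf", "chd", "stroke_tia", "serious_ae", "minor_ae")
  red <- arm_reduction$events_per_100k[cats]
  usu <- arm_usual$events_per_100k[cats]
  tab <- data.frame(event = cats, reduction = unname(red),
                    usual_care = unname(usu),
                    difference = unname(red - usu),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, run_id = arm_reduction$run_id),
            class = "deprescr_event_table")
}

#' @export
print.deprescr_event_table <- function(x, ...) {
  cat("Event incidence per 100,000 patients (difference = reduction - usual care)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

# ---- command-line interface -------------------------------------------------

#' Command-line dispatcher
#'
#' Thin shell interface over the package functions, invoked by the
#' \code{inst/cli/deprescr.R} script:
#' \preformatted{
#'   Rscript deprescr.R <command> [--flag value ...]
#' }
#' Commands: \code{cohort}, \code{simulate}, \code{psa}, \code{ceac},
#' \code{threshold}, \code{scenarios}, \code{report}. Flags:
#' \code{--params PATH} (YAML config), \code{--lifetable PATH},
#' \code{--cohort PATH}, \code{--n INT}, \code{--iterations INT},
#' \code{--seed INT}, \code{--horizon-years FLOAT}, \code{--wtp FLOAT},
#' \code{--parameter PATH}, \code{--bracket LO,HI}, \code{--out DIR}.
#' Each run writes its result CSVs and appends a JSON-lines record (seed,
#' command, outputs) to \code{run_log.jsonl} in the output directory.
#'
#' @param args Character vector of arguments (as from
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return Integer exit status, invisibly (0 = success).
#' @export
cli_dispatch <- function(args) {
  usage <- paste(
    "usage: deprescr <cohort|simulate|psa|ceac|threshold|scenarios|report> [flags]",
    "flags: --params P --lifetable P --cohort P --n I --iterations I --seed I",
    "       --horizon-years X --wtp X --parameter PATH --bracket LO,HI --out DIR",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  flags <- .parse_flags(args[-1])
  if (is.character(flags)) { message(flags, "\n", usage); return(invisible(1L)) }
  cmds <- c("cohort", "simulate", "psa", "ceac", "threshold", "scenarios",
            "report")
  if (!cmd %in% cmds) {
    message("unknown command: ", cmd, "\n", usage)
    return(invisible(1L))
  }
  status <- tryCatch({
    .cli_run(cmd, flags)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) return(paste("unexpected argument:", a))
    key <- sub("^--", "", a)
    if (i + 1 > length(args)) return(paste("flag", a, "needs a value"))
    flags[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  flags
}

.cli_run <- function(cmd, flags) {
  out_dir <- flags$out %||% "."
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(flags$seed %||% 1)
  n <- as.integer(flags$n %||% 10000)
  params <- load_parameters(flags$params, lifetable = flags$lifetable,
                            quiet = TRUE)
  config <- simulation_config(
    n_patients = n, seed = seed,
    max_horizon_years = as.numeric(flags$horizon_years %||% 20))
  cohort <- if (!is.null(flags$cohort)) read_cohort(flags$cohort) else NULL
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE)
    outputs <<- c(outputs, path)
  }
  if (cmd == "cohort") {
    coh <- cohort %||% generate_cohort(cohort_spec(), n, seed = seed)
    emit(as.data.frame(coh), "cohort.csv")
    emit(summarize_cohort(coh), "cohort_summary.csv")
  } else if (cmd %in% c("simulate", "report")) {
    bc <- run_base_case(params, config, cohort = cohort)
    emit(summary(bc), "results.csv")
    emit(bc$event_table$table, "events.csv")
    emit(data.frame(delta_cost = bc$cea$delta_cost,
                    delta_qaly = bc$cea$delta_qaly, icer = bc$cea$icer,
                    label = bc$cea$label), "icer.csv")
    if (cmd == "report") print(bc)
  } else if (cmd %in% c("psa", "ceac")) {
    iters <- as.integer(flags$iterations %||% 100)
    psa <- run_psa(params, config, n_iterations = iters)
    emit(data.frame(iteration = psa$iteration,
                    delta_cost = psa$delta_cost,
                    delta_qaly = psa$delta_qaly), "ce_plane.csv")
    ceac <- compute_ceac(psa)
    emit(as.data.frame(ceac), "ceac.csv")
  } else if (cmd == "threshold") {
    if (is.null(flags$parameter)) stop("--parameter is required")
    wtp <- as.numeric(flags$wtp %||% 20000)
    bracket <- if (!is.null(flags$bracket)) {
      as.numeric(strsplit(flags$bracket, ",")[[1]])
    } else c(0.001, 0.5)
    th <- threshold_search(params, flags$parameter, wtp, bracket, config)
    emit(data.frame(parameter = th$parameter, threshold = th$threshold,
                    icer = th$icer_at_threshold, wtp = th$wtp),
         "threshold.csv")
  } else if (cmd == "scenarios") {
    res <- run_scenarios(params, default_scenarios(params), config)
    emit(as.data.frame(res), "scenarios.csv")
  }
  log_rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  command = cmd, seed = seed, n = n,
                  params_file = flags$params %||% "<defaults>",
                  outputs = outputs,
                  version = as.character(utils::packageVersion("deprescr")))
  cat(jsonlite::toJSON(log_rec, auto_unbox = TRUE), "\n",
      file = file.path(out_dir, "run_log.jsonl"), append = TRUE, sep = "")
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
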