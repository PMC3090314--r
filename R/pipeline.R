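#' Pipeline configuration
#'
#' Collects every tunable of a full simulate/load -> detect -> classify ->
#' validate -> prevalence run. Either a simulation preset (or full
#' [simulation_config()]) or paths to existing claims/persons CSVs must be
#' given.
#'
#' @param preset Name of a [scenario_presets()] entry, or `NULL`.
#' @param simulation A [simulation_config()] overriding `preset`.
#' @param claims_path,persons_path Paths to input CSVs when not simulating.
#' @param horizon Claims horizon.
#' @param window A [detection_window()].
#' @param threshold `"estimate"` (default) to run
#'   [estimate_switch_threshold()], or a fixed integer age.
#' @param t2p_range Two proportions bounding the true type-2 share for the
#'   validity report.
#' @param t2p_grid Grid of proportions for [metric_intervals()]; default
#'   five evenly spaced points over `t2p_range`.
#' @param period Reporting period for prevalence.
#' @param seed Seed forwarded to the simulation config.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "tiny", simulation = NULL,
                            claims_path = NULL, persons_path = NULL,
                            horizon = c(1995L, 2006L),
                            window = detection_window(),
                            threshold = "estimate",
                            t2p_range = c(0.9, 0.97),
                            t2p_grid = NULL,
                            period = c(2000L, 2006L),
                            seed = NULL) {
  if (is.null(simulation) && !is.null(preset)) {
    simulation <- scenario_presets(preset)
  }
  if (!is.null(simulation) && !is.null(seed)) simulation$seed <- as.integer(seed)
  if (is.null(simulation) && (is.null(claims_path) || is.null(persons_path))) {
    stop("either a simulation config/preset or claims and persons paths are required",
         call. = FALSE)
  }
  structure(
    list(simulation = simulation, claims_path = claims_path,
         persons_path = persons_path, horizon = assert_year_range(horizon),
         window = window, threshold = threshold,
         t2p_range = t2p_range,
         t2p_grid = t2p_grid %||% seq(t2p_range[1], t2p_range[2], length.out = 5),
         period = assert_year_range(period)),
    class = "pipeline_config"
  )
}

#' Run the full phenotyping pipeline
#'
#' Executes every stage on one dataset and, when `out_dir` is given, writes
#' the intermediate tables (claims, persons, truth when simulated, cases,
#' type-2 set, validity report, prevalence series), a funnel summary JSON
#' and the resolved configuration YAML. Outputs are deterministic given the
#' configuration.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A list with `cases`, `type2`, `threshold`, `validity` (a
#'   [metric_intervals()] table), `prevalence`, `projection`, `summary`
#'   (funnel counts) and, when simulated, `truth`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", simulate_population(config$simulation))
    claims <- sim$claims
    persons <- sim$persons
    truth <- sim$truth
  } else {
    claims <- stage("load", read_claims(config$claims_path, config$horizon))
    persons <- stage("load", read_persons(config$persons_path))
  }

  pre <- preselect_a10(claims, config$horizon)
  matrix <- stage("count", count_deliveries(claims, "A10", config$horizon))
  cases <- stage("detect", detect_cases(matrix, persons, config$window))

  split <- stage("classify", split_by_oha(cases, claims, config$horizon))
  if (identical(config$threshold, "estimate")) {
    est <- stage("classify",
                 estimate_switch_threshold(cases, claims, persons, config$horizon))
    threshold <- est$threshold
    cohort <- est$cohort
  } else {
    threshold <- as.integer(config$threshold)
    cohort <- NULL
  }
  type2 <- stage("classify",
                 classify_type2(split, threshold, claims, persons, config$horizon))

  n_pos <- nrow(type2)
  n_cases <- nrow(cases)
  validity <- NULL
  if (n_pos > 0 && n_pos < n_cases) {
    vi <- validity_inputs(n_cases, n_pos,
                          t2p_min = config$t2p_range[1],
                          t2p_max = config$t2p_range[2])
    validity <- stage("validate", metric_intervals(vi, config$t2p_grid))
  }

  cy <- stage("prevalence", case_years(type2, claims, persons, config$period))
  den <- stage("prevalence",
               denominators_from_persons(persons, seq(config$period[1], config$period[2])))
  prev <- stage("prevalence", annual_prevalence(cy, den))
  projection <- NULL
  if (nrow(prev) >= 3 && all(prev$rate > 0)) {
    fit <- stage("project", fit_des(prev))
    projection <- list(alpha = fit$alpha, rmse = fit$rmse,
                       forecast = predict(fit, h = 1:2),
                       r2 = if (stats::var(prev$rate) > 0) linear_trend_r2(prev) else NA_real_,
                       mean_annual_increase = mean_annual_increase(prev))
  }

  summary <- list(
    n_preselected = length(pre),
    n_cases = n_cases,
    n_phase1 = sum(cases$phase == 1L),
    n_phase2 = sum(cases$phase == 2L),
    n_step2 = sum(type2$step == 2L),
    n_step3 = sum(type2$step == 3L),
    n_type2 = n_pos,
    threshold = threshold,
    criteria_mix = as.list(table(cases$primary_criterion))
  )

  result <- list(cases = cases, type2 = type2, threshold = threshold,
                 switch_cohort = cohort, validity = validity,
                 prevalence = prev, projection = projection,
                 summary = summary, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_claims(claims, file.path(out_dir, "claims.csv"))
    write_persons(persons, file.path(out_dir, "persons.csv"))
    if (!is.null(truth)) readr::write_csv(truth, file.path(out_dir, "truth.csv"), na = "")
    readr::write_csv(cases, file.path(out_dir, "cases.csv"))
    readr::write_csv(type2, file.path(out_dir, "type2.csv"))
    if (!is.null(validity)) readr::write_csv(validity, file.path(out_dir, "validity.csv"))
    readr::write_csv(prev, file.path(out_dir, "prevalence.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    cfg_out <- config
    cfg_out$window <- unclass(cfg_out$window)
    if (!is.null(cfg_out$simulation)) {
      cfg_out$simulation$death_hazard <- NULL  # closures do not serialize
      cfg_out$simulation <- unclass(cfg_out$simulation)
    }
    cfg_out <- c(unclass(cfg_out), list(package_version = as.character(utils::packageVersion("diabrx"))))
    yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  }
  result
}
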