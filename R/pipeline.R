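#' Run the full analysis pipeline
#'
#' Orchestrates data acquisition (simulation, files, or an imported survival
#' schedule), model fitting, herd-level survival summaries and the
#' sustainability breakpoint solver, and writes report artifacts: per-cell
#' recapture and survival tables, annual and accumulated survival summaries,
#' the breakpoint table and a machine-readable `summary.json`. Re-running
#' with an identical configuration reproduces byte-identical outputs.
#'
#' @param config Configuration: a named list or the path of a YAML file.
#'   Sections:
#'   \describe{
#'     \item{data}{one of `simulate: {design: study, seed: <int>}`,
#'       `histories: <path>` + `calendar: <path or "study">`, or
#'       `schedule: <path>` (skips fitting and summarizes the schedule
#'       directly).}
#'     \item{fit}{`structure: reference` (default) and optional `n_starts`,
#'       `seed`; `compare: true` additionally ranks the default candidate
#'       set by AICc.}
#'     \item{summaries}{`accumulate_from`, `accumulate_to` (autumn years;
#'       defaults 2007 and 2011).}
#'     \item{breakpoint}{`calving_rate`, `relative_calf_survival` (vector),
#'       `grid: true` to emit the whole construction grid.}
#'   }
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the report bundle: a list with `recapture`,
#'   `survival`, `annual`, `accumulated`, `breakpoints`, `fit` (or `NULL`),
#'   `comparison` (or `NULL`) and `summary` (what `summary.json` holds).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$data))
    stop("config must at least name a data source under `data`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[herdfate] ", sprintf(...))

  fit <- NULL; comparison <- NULL
  schedule <- NULL; recapture <- NULL; marked <- NULL

  if (!is.null(config$data$schedule)) {
    log_stage("stage data: schedule %s", config$data$schedule)
    schedule <- read_schedule(config$data$schedule)
  } else {
    if (!is.null(config$data$simulate)) {
      sim_conf <- config$data$simulate
      if (!identical(sim_conf$design %||% "study", "study"))
        stop("only the built-in `study` design is available by name")
      seed <- sim_conf$seed %||% 1
      log_stage("stage data: simulating study design, seed %d", seed)
      sim <- simulate_histories(study_design(), seed = seed)
      histories <- sim$histories
    } else if (!is.null(config$data$histories)) {
      cal_conf <- config$data$calendar %||% "study"
      calendar <- if (identical(cal_conf, "study")) study_calendar()
                  else read_calendar(cal_conf)
      log_stage("stage data: reading %s", config$data$histories)
      histories <- read_histories(config$data$histories, calendar)
    } else stop("config$data must give `simulate`, `histories` or `schedule`")
    marked <- length(histories)

    fit_conf <- config$fit %||% list()
    opts <- cjs_options(n_starts = fit_conf$n_starts %||% 5,
                        seed = fit_conf$seed %||% 1)
    structure_name <- fit_conf$structure %||% "reference"
    if (!identical(structure_name, "reference"))
      stop("only the `reference` structure is available by name")
    log_stage("stage fit: %d histories, reference structure", marked)
    fit <- fit_cjs(histories, reference_structure(histories$calendar), opts)
    schedule <- fitted_schedule(fit)
    recapture <- fit$p
    if (isTRUE(fit_conf$compare)) {
      log_stage("stage fit: AICc comparison of candidate set")
      comparison <- compare_models(histories,
                                   candidate_structures(histories$calendar),
                                   opts)
    }
  }

  log_stage("stage summaries")
  sum_conf <- config$summaries %||% list()
  from <- sum_conf$accumulate_from %||% 2007
  to <- sum_conf$accumulate_to %||% 2011
  herd_names <- unique(schedule$herd)
  annual <- lapply(herd_names, function(h) annual_survival(schedule, h))
  names(annual) <- herd_names
  accumulated <- vapply(herd_names, function(h)
    accumulated_survival(schedule, h, from, to), 0)

  bp_conf <- config$breakpoint %||% list()
  scenarios <- unlist(bp_conf$relative_calf_survival %||% c(0.8, 0.5))
  calving <- bp_conf$calving_rate %||% 0.6
  log_stage("stage breakpoint: calving %.2f, scenarios %s", calving,
            paste(scenarios, collapse = "/"))
  breakpoints <- do.call(rbind, lapply(scenarios, function(rcs) {
    bp <- max_sustainable_mortality(
      leslie_spec(calving_rate = calving, relative_calf_survival = rcs))
    data.frame(relative_calf_survival = rcs,
               breakpoint = bp$max_sustainable_mortality,
               eigenvalue = bp$eigenvalue_at_solution)
  }))
  grid <- if (isTRUE(bp_conf$grid))
    breakpoint_grid(calving_rate = calving,
                    relative_calf_survival = scenarios) else NULL

  summary <- list(
    config = config,
    n_marked = marked,
    fit = if (!is.null(fit)) list(
      model = fit$structure$label, loglik = round(fit$loglik, 4),
      K = fit$K, n_eff = fit$n_eff, AICc = round(fit$AICc, 2),
      boundary_flags = fit$boundary_flags) else NULL,
    annual_survival = lapply(annual, function(a)
      list(mean = round(a$mean, 3), yearly = round(a$yearly$survival, 3))),
    accumulated_survival = round(accumulated, 3),
    accumulated_window = c(from = from, to = to),
    breakpoints = breakpoints,
    package_version = as.character(utils::packageVersion("herdfate"))
  )

  log_stage("stage report: writing to %s", out_dir)
  if (!is.null(recapture))
    write_report_table(format_cells(recapture), file.path(out_dir,
                                                          "recapture.csv"))
  write_report_table(format_cells(schedule), file.path(out_dir,
                                                       "survival.csv"))
  annual_tab <- do.call(rbind, lapply(herd_names, function(h)
    cbind(herd = h, annual[[h]]$yearly)))
  write_report_table(annual_tab, file.path(out_dir, "annual_survival.csv"))
  write_report_table(breakpoints, file.path(out_dir, "breakpoint.csv"))
  if (!is.null(grid))
    write_report_table(grid, file.path(out_dir, "breakpoint_grid.csv"))
  if (!is.null(comparison))
    write_report_table(comparison, file.path(out_dir,
                                             "model_comparison.csv"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(recapture = recapture, survival = schedule,
                 annual = annual, accumulated = accumulated,
                 breakpoints = breakpoints, grid = grid, fit = fit,
                 comparison = comparison, summary = summary))
}

# probabilities to 3 decimals; fixed cells labelled "(fixed)" in reports
format_cells <- function(tab) {
  out <- tab
  for (col in intersect(c("estimate", "lcl", "ucl"), names(out)))
    out[[col]] <- round(out[[col]], 3)
  if ("fixed" %in% names(out)) {
    out$ci <- ifelse(out$fixed, "(fixed)",
                     ifelse(is.na(out$lcl), "",
                            sprintf("%.3f-%.3f", out$lcl, out$ucl)))
  }
  out
}

write_report_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Accumulated-survival plot
#'
#' Step-style plot of the running product of interval survival estimates
#' per herd, from a survival schedule. Requires ggplot2 (headless-safe:
#' nothing is drawn until the object is printed).
#'
#' @param schedule A survival schedule (see [annual_survival()]).
#' @param year_from,year_to Autumn years bounding the window.
#' @return A ggplot object.
#' @export
plot_accumulated_survival <- function(schedule, year_from = 2007,
                                      year_to = 2011) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is needed for plotting")
  herd_names <- unique(schedule$herd)
  dat <- do.call(rbind, lapply(herd_names, function(h) {
    w <- schedule_window(schedule, h, year_from, year_to)
    w <- w[order(w$year, season_rank(w$season)), ]
    data.frame(herd = h,
               time = w$year + season_rank(w$season) / 10,
               label = paste(w$season, w$year),
               accumulated = cumprod(w$estimate))
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time,
                                    y = .data$accumulated,
                                    colour = .data$herd)) +
    ggplot2::geom_step() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "occasion", y = "accumulated survival",
                  colour = "herd") +
    ggplot2::theme_minimal()
}
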