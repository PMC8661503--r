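#' Read and validate a pipeline run configuration
#'
#' The run configuration is a YAML (or already-parsed list) with three
#' stage blocks, each optional except \code{labeling}:
#' \preformatted{
#' seed: 1
#' labeling:
#'   times: [2, 4, 8, 16, 24]
#'   n_cells_per_field: 200
#'   n_fields: 6
#'   n_replicates: 2
#'   fit_policy: plateau_exclude      # or "all"
#'   subpops:
#'     marker_pos: {gf: 0.90, proportion: 0.8}
#'     marker_neg: {gf: 0.75, proportion: 0.2}
#'   conditions:
#'     DMSO: {marker_pos: {tc: 39.98, ts: 16.51}, marker_neg: {tc: 38.80, ts: 16.60}}
#'     LY:   {marker_pos: {tc: 45.65, ts: 21.76}, marker_neg: {tc: 40.26, ts: 16.11}}
#' pulse_chase:
#'   pulse: 2
#'   chase: 48
#'   quit_prob: {DMSO: 0.30, LY: 0.15}
#' flow:
#'   days: [25, 35, 45]
#'   n_events: 20000
#'   n_replicates: 3
#'   percentile: 99.9
#'   conditions:
#'     control: {condition_scale: 1.0}
#'     LY: {condition_scale: 0.3}
#' }
#' @param config Path to a YAML file, or a list with the same structure.
#' @return The validated configuration list, class \code{"run_config"}.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config error: file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: not a list", call. = FALSE)
  if (is.null(config$seed))
    stop("config error: a 'seed' is mandatory for simulated stages",
         call. = FALSE)
  lab <- config$labeling
  if (is.null(lab)) stop("config error: 'labeling' block missing", call. = FALSE)
  lab$times <- if (is.null(lab$times)) c(2, 4, 8, 16, 24) else as.numeric(lab$times)
  lab$n_cells_per_field <- lab$n_cells_per_field %||% 200
  lab$n_fields <- lab$n_fields %||% 6
  lab$n_replicates <- lab$n_replicates %||% 2
  lab$fit_policy <- lab$fit_policy %||% "plateau_exclude"
  if (!lab$fit_policy %in% c("all", "plateau_exclude"))
    stop("config error: unknown fit_policy '", lab$fit_policy, "'",
         call. = FALSE)
  if (is.null(lab$subpops) || is.null(lab$conditions))
    stop("config error: labeling needs 'subpops' and 'conditions'",
         call. = FALSE)
  props <- vapply(lab$subpops, function(s) s$proportion %||% NA_real_,
                  numeric(1))
  if (anyNA(props) || abs(sum(props) - 1) > 1e-8)
    stop("config error: subpop proportions must be given and sum to 1",
         call. = FALSE)
  for (cn in names(lab$conditions)) {
    miss <- setdiff(names(lab$subpops), names(lab$conditions[[cn]]))
    if (length(miss))
      stop("config error: condition '", cn, "' lacks kinetics for subpop(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  config$labeling <- lab
  if (!is.null(config$pulse_chase)) {
    pc <- config$pulse_chase
    pc$pulse <- pc$pulse %||% 2
    pc$chase <- pc$chase %||% 48
    if (is.null(pc$quit_prob))
      stop("config error: pulse_chase needs per-condition 'quit_prob'",
           call. = FALSE)
    miss <- setdiff(names(lab$conditions), names(pc$quit_prob))
    if (length(miss))
      stop("config error: quit_prob missing for condition(s) ",
           paste(miss, collapse = ", "), call. = FALSE)
    config$pulse_chase <- pc
  }
  if (!is.null(config$flow)) {
    fl <- config$flow
    fl$days <- as.numeric(fl$days %||% c(25, 35, 45))
    fl$n_events <- fl$n_events %||% 20000
    fl$n_replicates <- fl$n_replicates %||% 3
    fl$percentile <- fl$percentile %||% 99.9
    if (is.null(fl$conditions))
      stop("config error: flow needs 'conditions'", call. = FALSE)
    config$flow <- fl
  }
  class(config) <- c("run_config", "list")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mixture_from_config <- function(lab, cond_name, quit_prob = 0, seed = NULL) {
  kin <- lab$conditions[[cond_name]]
  comps <- lapply(names(lab$subpops), function(sp)
    cycle_population_params(tc = kin[[sp]]$tc, ts = kin[[sp]]$ts,
                            gf = lab$subpops[[sp]]$gf,
                            quit_prob = quit_prob, label = sp))
  mixture_spec(comps,
               proportions = vapply(lab$subpops, `[[`, numeric(1), "proportion"),
               n_cells_per_field = lab$n_cells_per_field,
               n_fields = lab$n_fields, n_replicates = lab$n_replicates,
               seed = seed)
}

#' Materialize a full synthetic study from one configuration
#'
#' Generates every input table the pipeline consumes — cumulative-labeling
#' curves and pulse-chase count tables per condition, flow event tables per
#' condition, day and replicate (each with its matched negative control) —
#' and writes them as tidy CSVs.
#'
#' @param config A \code{\link{read_run_config}} configuration (path or
#'   list).
#' @param out_dir Directory for the CSVs (created if absent).
#' @return Invisibly, a named list of the generated tables.
#' @export
write_study_fixtures <- function(config, out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- .generate_study(config)
  for (cn in names(gen$curves))
    write_labeling_curve(gen$curves[[cn]],
                         file.path(out_dir, paste0("labeling_", cn, ".csv")))
  for (cn in names(gen$exit_tables))
    write_exit_counts(gen$exit_tables[[cn]],
                      file.path(out_dir, paste0("exit_counts_", cn, ".csv")))
  for (cn in names(gen$flow_events))
    write_flow_events(gen$flow_events[[cn]],
                      file.path(out_dir, paste0("flow_events_", cn, ".csv")))
  invisible(gen)
}

# Simulate all stage inputs for a validated config; deterministic in
# config$seed (sub-seeds drawn once up front).
.generate_study <- function(config) {
  lab <- config$labeling
  conds <- names(lab$conditions)
  fl_conds <- if (!is.null(config$flow)) names(config$flow$conditions) else character()
  n_seeds <- 2L * length(conds) + length(fl_conds) *
    (if (is.null(config$flow)) 0L else length(config$flow$days) * config$flow$n_replicates)
  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max, max(n_seeds, 1L)))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }

  curves <- stats::setNames(lapply(conds, function(cn)
    simulate_cumulative_labeling(.mixture_from_config(lab, cn, seed = nxt()),
                                 times = lab$times)), conds)

  exit_tables <- NULL
  if (!is.null(config$pulse_chase)) {
    pc <- config$pulse_chase
    exit_tables <- stats::setNames(lapply(conds, function(cn)
      simulate_pulse_chase(
        .mixture_from_config(lab, cn, quit_prob = pc$quit_prob[[cn]],
                             seed = nxt()),
        pulse = pc$pulse, chase = pc$chase)), conds)
  } else {
    for (dummy in conds) nxt()
  }

  flow_events <- NULL
  if (!is.null(config$flow)) {
    fl <- config$flow
    flow_events <- stats::setNames(lapply(fl_conds, function(cn) {
      tp_args <- fl$conditions[[cn]]
      tp <- do.call(trajectory_params, tp_args[names(tp_args) %in%
                                                 names(formals(trajectory_params))])
      do.call(rbind, lapply(fl$days, function(d)
        do.call(rbind, lapply(seq_len(fl$n_replicates), function(r)
          simulate_flow_sample(tp, day = d, n_events = fl$n_events,
                               seed = nxt(), condition = cn, replicate = r)))))
    }), fl_conds)
  }
  list(curves = curves, exit_tables = exit_tables, flow_events = flow_events)
}

#' Run the full analysis pipeline from one configuration
#'
#' Executes every stage on simulated inputs: fixture generation, cumulative-
#' labeling fits and cycle-length inversion per condition and
#' subpopulation, condition comparisons through the gatekept statistics,
#' pulse-chase exit indices (with their deterministic expectation), and the
#' gated flow timecourse with percent-reduction/fold-change summaries.
#' Writes a JSON report, timecourse and estimate CSVs, and a plain-text log
#' of seeds, policies and package version. Re-running the same
#' configuration reproduces the report byte for byte.
#'
#' @param config Configuration path or list (see
#'   \code{\link{read_run_config}}).
#' @param out_dir Output directory; defaults to \code{config$output_dir}.
#' @param seed Optional integer overriding \code{config$seed}.
#' @return The report, a nested list (also written to
#'   \code{out_dir/report.json}), invisibly.
#' @examples
#' cfg <- system.file("extdata", "demo_config.yaml", package = "cyclekin")
#' \donttest{
#' rep <- run_pipeline(cfg, out_dir = tempfile("run"))
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  config <- tryCatch(read_run_config(config),
                     error = function(e) stop(conditionMessage(e), call. = FALSE))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out_dir <- out_dir %||% config$output_dir %||% "cyclekin_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(name, " stage: ", conditionMessage(e), call. = FALSE))
  }

  gen <- stage("fixtures", .generate_study(config))
  lab <- config$labeling
  conds <- names(lab$conditions)
  subpops <- names(lab$subpops)

  estimates <- stage("cycle_estimation", {
    res <- list()
    for (cn in conds) for (sp in subpops) {
      gf <- lab$subpops[[sp]]$gf
      fit <- fit_labeling_curve(gen$curves[[cn]], policy = lab$fit_policy,
                                gf = gf, subpop = sp)
      res[[cn]][[sp]] <- estimate_cycle_params(fit, gf = gf)
    }
    res
  })

  comparisons <- stage("cycle_estimation", {
    if (length(conds) < 2L) NULL else {
      cmp <- list()
      for (sp in subpops) {
        pairs <- utils::combn(conds, 2, simplify = FALSE)
        for (p in pairs) {
          cc <- compare_conditions(estimates[[p[1]]][[sp]],
                                   estimates[[p[2]]][[sp]], labels = p)
          cmp[[sp]][[paste(p, collapse = "_vs_")]] <- list(
            tc_diff = cc$tc_diff, tc_p = cc$tc$p_value, tc_test = cc$tc$test_name,
            ts_diff = cc$ts_diff, ts_p = cc$ts$p_value, ts_test = cc$ts$test_name)
        }
      }
      cmp
    }
  })

  exit <- NULL
  if (!is.null(gen$exit_tables)) exit <- stage("exit_index", {
    pc <- config$pulse_chase
    res <- list()
    for (cn in conds) {
      ei <- compute_exit_index(gen$exit_tables[[cn]], marker = subpops[1])
      kin <- lab$conditions[[cn]][[subpops[1]]]
      oracle <- expected_exit_index(
        cycle_population_params(tc = kin$tc, ts = kin$ts,
                                gf = lab$subpops[[subpops[1]]]$gf,
                                quit_prob = pc$quit_prob[[cn]],
                                label = subpops[1]),
        pulse = pc$pulse, chase = pc$chase)
      res[[cn]] <- list(index = ei$index, numerator = ei$numerator,
                        denominator = ei$denominator,
                        quartiles = as.list(ei$dispersion),
                        expected_marker_pos_exit = oracle)
    }
    res
  })

  flow <- NULL
  if (!is.null(gen$flow_events)) flow <- stage("flow_timecourse", {
    fl <- config$flow
    gates <- list()
    for (cn in names(gen$flow_events)) {
      ev <- gate_viable(gen$flow_events[[cn]])
      for (d in fl$days) for (r in seq_len(fl$n_replicates)) {
        smp <- ev[ev$day == d & ev$replicate == r & ev$role == "reporter", ]
        ctl <- ev[ev$day == d & ev$replicate == r &
                    ev$role == "negative_control", ]
        if (!nrow(ctl))
          stop("no matched negative control for day ", d, ", replicate ", r)
        gates[[length(gates) + 1L]] <-
          gate_positive(smp, ctl, percentile = fl$percentile)
      }
    }
    tcr <- build_timecourse(gates)
    summaries <- NULL
    fl_conds <- names(fl$conditions)
    if (length(fl_conds) >= 2L) {
      ref <- fl_conds[1]
      summaries <- do.call(rbind, lapply(fl_conds[-1], function(cn) {
        days <- intersect(tcr$day[tcr$condition == ref],
                          tcr$day[tcr$condition == cn])
        do.call(rbind, lapply(days, function(d) {
          a <- tcr$positive_fraction[tcr$condition == ref & tcr$day == d]
          b <- tcr$positive_fraction[tcr$condition == cn & tcr$day == d]
          data.frame(day = d, reference = ref, condition = cn,
                     percent_reduction = percent_reduction(a, b),
                     fold_change = if (b > 0) fold_change(a, b) else NA_real_)
        }))
      }))
    }
    list(timecourse = tcr, summaries = summaries)
  })

  est_rows <- do.call(rbind, lapply(conds, function(cn)
    do.call(rbind, lapply(subpops, function(sp) {
      e <- estimates[[cn]][[sp]]
      data.frame(condition = cn, subpop = sp, gf = e$gf_used,
                 m = e$fit$m, b = e$fit$b, r2 = e$fit$r2,
                 tc_hat = e$tc_hat, ts_hat = e$ts_hat,
                 tc_sem = e$tc_sem, ts_sem = e$ts_sem,
                 n_times = e$fit$n_points,
                 flags = paste(e$flags, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))))

  report <- list(
    pipeline = list(package = "cyclekin",
                    version = as.character(utils::packageVersion("cyclekin")),
                    seed = config$seed,
                    fit_policy = lab$fit_policy,
                    gating_percentile = if (!is.null(config$flow))
                      config$flow$percentile else NULL),
    cycle_estimates = est_rows,
    replicate_values = lapply(estimates, function(by_sp)
      lapply(by_sp, function(e)
        list(tc = as.list(e$tc_reps), ts = as.list(e$ts_reps)))),
    comparisons = comparisons,
    exit_index = exit,
    flow = flow)

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  utils::write.csv(est_rows, file.path(out_dir, "cycle_estimates.csv"),
                   row.names = FALSE)
  if (!is.null(flow))
    utils::write.csv(flow$timecourse, file.path(out_dir, "timecourse.csv"),
                     row.names = FALSE)
  writeLines(c(
    paste0("cyclekin ", utils::packageVersion("cyclekin")),
    paste0("seed: ", config$seed),
    paste0("fit policy: ", lab$fit_policy),
    paste0("labeling design: ", lab$n_fields, " fields x ",
           lab$n_replicates, " replicates, ~", lab$n_cells_per_field,
           " cells/field, times ", paste(lab$times, collapse = ", "), " h"),
    if (!is.null(config$flow))
      paste0("flow gating percentile: ", config$flow$percentile)),
    file.path(out_dir, "run_log.txt"))
  invisible(report)
}
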