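#' Ground-truth kinetics of a cycling subpopulation
#'
#' Bundles the parameters that define the cell-cycle behaviour of one
#' subpopulation in the simulator: total cycle length \code{tc}, S-phase
#' length \code{ts}, growth fraction \code{gf} (the proportion of cells
#' actively cycling) and the per-mitosis probability \code{quit_prob} that a
#' daughter exits the cycle and loses Ki67.
#'
#' The phase layout within one cycle is G1 of length \code{tc - ts - tg2m},
#' then S of length \code{ts}, then G2/M of length \code{tg2m} ending in
#' mitosis. \code{tg2m} only affects the timing of mitoses (pulse-chase
#' experiments); cumulative-labeling curves depend on \code{tc}, \code{ts}
#' and \code{gf} alone.
#'
#' @param tc Cell-cycle length, hours. Must be > 0.
#' @param ts S-phase length, hours. Must satisfy 0 < ts <= tc.
#' @param gf Growth fraction in `[0, 1]`.
#' @param quit_prob Probability that a daughter exits the cycle (loses Ki67)
#'   at each mitosis, in `[0, 1]`. Default 0 (pure proliferation).
#' @param label Subpopulation tag, e.g. \code{"marker_pos"}.
#' @param tg2m Combined G2 + M length, hours. Defaults to 2 h, shrunk to
#'   \code{tc - ts} when the cycle is too short to accommodate it.
#' @return An object of class \code{"cycle_population_params"}.
#' @examples
#' cycle_population_params(tc = 39.98, ts = 16.51, gf = 0.9)
#' @export
cycle_population_params <- function(tc, ts, gf = 1, quit_prob = 0,
                                    label = "marker_pos", tg2m = NULL) {
  stopifnot(is.numeric(tc), length(tc) == 1L, is.finite(tc),
            is.numeric(ts), length(ts) == 1L, is.finite(ts),
            is.numeric(gf), length(gf) == 1L, is.finite(gf),
            is.numeric(quit_prob), length(quit_prob) == 1L)
  if (tc <= 0) stop("'tc' must be > 0", call. = FALSE)
  if (ts <= 0 || ts > tc) stop("'ts' must satisfy 0 < ts <= tc", call. = FALSE)
  if (gf < 0 || gf > 1) stop("'gf' must lie in [0, 1]", call. = FALSE)
  if (quit_prob < 0 || quit_prob > 1)
    stop("'quit_prob' must lie in [0, 1]", call. = FALSE)
  if (is.null(tg2m)) tg2m <- min(2, tc - ts)
  if (tg2m < 0 || ts + tg2m > tc + 1e-12)
    stop("'tg2m' must satisfy 0 <= tg2m <= tc - ts", call. = FALSE)
  structure(list(tc = tc, ts = ts, gf = gf, quit_prob = quit_prob,
                 label = as.character(label), tg2m = tg2m),
            class = "cycle_population_params")
}

#' @export
print.cycle_population_params <- function(x, ...) {
  cat(sprintf(
    "Cycling population '%s': tc = %.2f h, ts = %.2f h, G2/M = %.2f h, GF = %.2f, quit prob = %.2f\n",
    x$label, x$tc, x$ts, x$tg2m, x$gf, x$quit_prob))
  invisible(x)
}

#' Sampling design for a simulated labeling experiment
#'
#' Describes a mixture of cycling subpopulations together with the counting
#' design: how many cells per microscope field, how many fields per
#' biological replicate, and how many replicates. Defaults mirror a common
#' immunostaining design of six fields from two biological replicates with a
#' few hundred cells per field.
#'
#' @param components A list of \code{\link{cycle_population_params}}, or a
#'   single such object.
#' @param proportions Mixing proportions, one per component; must sum to 1.
#' @param n_cells_per_field Expected cells per field (field totals are drawn
#'   Poisson around this value).
#' @param n_fields Fields counted per replicate.
#' @param n_replicates Biological replicates.
#' @param seed Integer seed making the simulated experiment reproducible.
#' @param age_distribution Stationary distribution of cycle positions:
#'   \code{"uniform"} (default; exactly stationary under the non-expanding
#'   renewal scheme, making the linear cumulative-labeling law exact) or
#'   \code{"exp_growth"} (age density of an exponentially expanding
#'   population with symmetric division, provided as a robustness option —
#'   under it the linear law holds only approximately).
#' @return An object of class \code{"mixture_spec"}.
#' @examples
#' pop <- cycle_population_params(tc = 40, ts = 16, gf = 0.9)
#' mixture_spec(pop, seed = 1)
#' @export
mixture_spec <- function(components, proportions = NULL,
                         n_cells_per_field = 200, n_fields = 6,
                         n_replicates = 2, seed = NULL,
                         age_distribution = c("uniform", "exp_growth")) {
  age_distribution <- match.arg(age_distribution)
  if (inherits(components, "cycle_population_params"))
    components <- list(components)
  if (!length(components) ||
      !all(vapply(components, inherits, logical(1), "cycle_population_params")))
    stop("'components' must be cycle_population_params objects", call. = FALSE)
  if (is.null(proportions)) proportions <- rep(1 / length(components), length(components))
  if (length(proportions) != length(components))
    stop("one mixing proportion per component is required", call. = FALSE)
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-8)
    stop("mixing proportions must be non-negative and sum to 1", call. = FALSE)
  stopifnot(n_cells_per_field >= 1, n_fields >= 1, n_replicates >= 1)
  labels <- vapply(components, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("component labels must be unique", call. = FALSE)
  structure(list(components = components, proportions = proportions,
                 n_cells_per_field = as.integer(n_cells_per_field),
                 n_fields = as.integer(n_fields),
                 n_replicates = as.integer(n_replicates),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 age_distribution = age_distribution),
            class = "mixture_spec")
}

#' Differentiation trajectory of a reporter-expressing population
#'
#' Parameterizes the progenitor-to-postmitotic conversion that drives the
#' prevalence of reporter-positive cells in a flow-cytometry timecourse. The
#' expected positive prevalence at differentiation day \eqn{d} is
#' \deqn{p(d) = A (1 - e^{-H(d)})}
#' where \eqn{H(d)} is the cumulative conversion hazard accrued after the
#' reporter-onset day, and \eqn{A} is the asymptotic fraction of the culture
#' on the reporter lineage. The per-day hazard equals
#' \code{hazard * condition_scale} before \code{forced_exit_day} and
#' \code{forced_exit_hazard} from that day on (modeling enforced cell-cycle
#' exit with cell-cycle inhibitors).
#'
#' @param hazard Baseline progenitor-to-postmitotic conversion hazard, per day.
#' @param onset_day Day of differentiation at which reporter-positive cells
#'   first appear (conversion before this day is invisible to the reporter).
#' @param asymptote Asymptotic reporter-positive fraction \eqn{A} in `(0, 1]`.
#' @param condition_scale Multiplier on \code{hazard}; values < 1 model
#'   pharmacological slowing of neurogenic conversion.
#' @param forced_exit_day Optional day from which the conversion hazard is
#'   replaced by \code{forced_exit_hazard} (forced cell-cycle exit mode).
#' @param forced_exit_hazard Hazard, per day, applied from
#'   \code{forced_exit_day} onward.
#' @param dead_fraction Fraction of events that are dead cells (high
#'   viability-dye intensity) in simulated samples.
#' @return An object of class \code{"trajectory_params"}.
#' @examples
#' trajectory_params()                       # control-like trajectory
#' trajectory_params(condition_scale = 0.3)  # slowed conversion
#' @export
trajectory_params <- function(hazard = 0.094, onset_day = 21,
                              asymptote = 0.5, condition_scale = 1,
                              forced_exit_day = NULL,
                              forced_exit_hazard = 0.3,
                              dead_fraction = 0.1) {
  stopifnot(hazard >= 0, onset_day >= 0, condition_scale >= 0,
            forced_exit_hazard >= 0,
            asymptote > 0, asymptote <= 1,
            dead_fraction >= 0, dead_fraction < 1)
  if (!is.null(forced_exit_day)) stopifnot(forced_exit_day >= 0)
  structure(list(hazard = hazard, onset_day = onset_day,
                 asymptote = asymptote, condition_scale = condition_scale,
                 forced_exit_day = forced_exit_day,
                 forced_exit_hazard = forced_exit_hazard,
                 dead_fraction = dead_fraction),
            class = "trajectory_params")
}

#' Expected reporter-positive prevalence at a given day
#'
#' Closed form of the conversion model in \code{\link{trajectory_params}};
#' serves as the generative truth for gating-recovery tests.
#'
#' @param trajectory A \code{\link{trajectory_params}} object.
#' @param day Day(s) of differentiation.
#' @return Expected positive prevalence in `[0, 1]`, vectorized over
#'   \code{day}.
#' @export
trajectory_prevalence <- function(trajectory, day) {
  stopifnot(inherits(trajectory, "trajectory_params"), is.numeric(day))
  h <- trajectory$hazard * trajectory$condition_scale
  fd <- trajectory$forced_exit_day
  H <- if (is.null(fd)) {
    h * pmax(0, day - trajectory$onset_day)
  } else {
    brk <- max(fd, trajectory$onset_day)
    h * pmax(0, pmin(day, brk) - trajectory$onset_day) +
      trajectory$forced_exit_hazard * pmax(0, day - brk)
  }
  trajectory$asymptote * (1 - exp(-H))
}

#' Published cumulative-EdU cell-cycle kinetics of human MGE-like progenitors
#'
#' Reference table of cell-cycle length (\code{tc}) and S-phase length
#' (\code{ts}) estimates, in hours, for NKX2.1-positive and NKX2.1-negative
#' populations of human MGE-like cultures at day 22 of differentiation,
#' under vehicle (DMSO) or TGF-beta-receptor inhibition (LY2109761). These
#' values are the ground truth used by the packaged parameter-recovery
#' studies.
#'
#' @return A data.frame with columns \code{condition}, \code{subpop},
#'   \code{tc}, \code{ts}, \code{tc_sem}, \code{ts_sem}.
#' @examples
#' mge_kinetics_table()
#' @export
mge_kinetics_table <- function() {
  data.frame(
    condition = c("DMSO", "LY", "DMSO", "LY"),
    subpop    = c("NKX2.1+", "NKX2.1+", "NKX2.1-", "NKX2.1-"),
    tc        = c(39.98, 45.65, 38.80, 40.26),
    ts        = c(16.51, 21.76, 16.60, 16.11),
    tc_sem    = c(1.48, 1.55, 4.02, 4.98),
    ts_sem    = c(1.45, 1.78, 3.78, 3.52),
    stringsAsFactors = FALSE
  )
}
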