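#' Expected labeled fraction under cumulative S-phase labeling
#'
#' Closed form of the linear cumulative-labeling law for an asynchronous
#' steady-state population: the fraction of cells labeled after continuous
#' exposure of length \eqn{t} is
#' \deqn{GF(t) = gf \min\{(ts + t)/tc,\ 1\},}
#' i.e. a line with slope \eqn{gf/tc} and intercept \eqn{gf \cdot ts/tc}
#' that saturates at the growth fraction once \eqn{t \ge tc - ts}. This is
#' the exact expectation of the simulator under its uniform
#' cycle-position distribution and serves as its oracle.
#'
#' @param params A \code{\link{cycle_population_params}} object.
#' @param t Exposure time(s), hours; must be >= 0.
#' @return Expected labeled fraction(s), vectorized over \code{t}.
#' @examples
#' p <- cycle_population_params(tc = 40, ts = 16, gf = 1)
#' analytic_labeled_fraction(p, 0)   # intercept gf*ts/tc = 0.4
#' @export
analytic_labeled_fraction <- function(params, t) {
  stopifnot(inherits(params, "cycle_population_params"), is.numeric(t))
  if (any(t < 0)) stop("exposure time 't' must be >= 0", call. = FALSE)
  params$gf * pmin((params$ts + t) / params$tc, 1)
}

# Draw the state of one field's cohort: per cell a subpopulation index,
# a cycling indicator, and (for cycling cells) a cycle position uniform on
# [0, tc). Returns a list of vectors of common length n.
.draw_field_cells <- function(spec, n) {
  k <- length(spec$components)
  comp <- sample.int(k, n, replace = TRUE, prob = spec$proportions)
  gf <- vapply(spec$components, `[[`, numeric(1), "gf")[comp]
  tc <- vapply(spec$components, `[[`, numeric(1), "tc")[comp]
  cycling <- stats::runif(n) < gf
  u <- stats::runif(n)
  pos <- if (identical(spec$age_distribution, "exp_growth")) {
    # age density of an exponentially growing population with symmetric
    # division: f(a) = 2 log(2)/tc * 2^(-a/tc), inverted via its CDF
    -tc * log2(1 - u / 2)
  } else {
    u * tc
  }
  list(comp = comp, cycling = cycling, pos = pos, tc = tc)
}

# Is a cycling cell at position `pos` labeled by a continuous exposure of
# length `t`? The cell is labeled iff its trajectory overlaps S-phase
# [s0, s0 + ts) during [0, t]: either it sits in S at time 0 or it reaches
# the start of S within t.
.labeled_by <- function(pos, t, tc, ts, tg2m) {
  s0 <- tc - ts - tg2m
  in_s <- pos >= s0 & pos < s0 + ts
  dist_to_s <- (s0 - pos) %% tc
  in_s | dist_to_s <= t
}

#' Simulate a cumulative S-phase-labeling experiment
#'
#' Generates labeled/total counts per exposure time, field and biological
#' replicate for a mixture of cycling subpopulations. Cycle positions are
#' drawn from the uniform stationary distribution on \eqn{[0, tc)} (a
#' non-expanding renewal scheme in which each mitosis replaces the mother
#' with one tracked daughter), under which the expected labeled fraction
#' equals \code{\link{analytic_labeled_fraction}} exactly. Labeling is
#' binary and permanent with no dilution across divisions.
#'
#' Each field draws a Poisson-sized cohort of cells once, and the same
#' cohort is scored at every exposure time (common random numbers), so the
#' observed labeled fraction is non-decreasing in exposure time within a
#' run. Labeled counts are therefore binomial given the field totals.
#'
#' @param spec A \code{\link{mixture_spec}}.
#' @param times Exposure times in hours; all must be > 0.
#' @param seed Optional integer seed overriding \code{spec$seed}.
#' @return A \code{labeling_curve} data.frame with columns \code{time},
#'   \code{replicate}, \code{field}, \code{subpop}, \code{n_total},
#'   \code{n_labeled}.
#' @examples
#' pop <- cycle_population_params(tc = 40, ts = 16, gf = 0.9)
#' curve <- simulate_cumulative_labeling(mixture_spec(pop, seed = 7),
#'                                       times = c(2, 4, 8, 16, 24))
#' head(curve)
#' @export
simulate_cumulative_labeling <- function(spec, times = c(2, 4, 8, 16, 24),
                                         seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (!length(times) || any(times <= 0))
    stop("'times' must be a non-empty vector of positive hours", call. = FALSE)
  seed <- if (!is.null(seed)) seed else spec$seed
  if (is.null(seed)) stop("a seed is required (in 'spec' or 'seed')", call. = FALSE)

  labels <- vapply(spec$components, `[[`, character(1), "label")
  ts_v <- vapply(spec$components, `[[`, numeric(1), "ts")
  tg_v <- vapply(spec$components, `[[`, numeric(1), "tg2m")

  rows <- withr::with_seed(seed, {
    out <- vector("list", spec$n_replicates * spec$n_fields)
    i <- 0L
    for (rep_id in seq_len(spec$n_replicates)) {
      for (field_id in seq_len(spec$n_fields)) {
        n <- stats::rpois(1L, spec$n_cells_per_field)
        if (n == 0L) n <- 1L
        cells <- .draw_field_cells(spec, n)
        per_time <- lapply(times, function(t) {
          lab <- cells$cycling &
            .labeled_by(cells$pos, t, cells$tc,
                        ts_v[cells$comp], tg_v[cells$comp])
          data.frame(
            time = t, replicate = rep_id, field = field_id,
            subpop = labels,
            n_total = as.integer(tabulate(cells$comp, nbins = length(labels))),
            n_labeled = as.integer(tabulate(cells$comp[lab], nbins = length(labels))),
            stringsAsFactors = FALSE)
        })
        i <- i + 1L
        out[[i]] <- do.call(rbind, per_time)
      }
    }
    out
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$time, curve$replicate, curve$field, curve$subpop), ]
  rownames(curve) <- NULL
  class(curve) <- c("labeling_curve", "data.frame")
  curve
}

#' Simulate an EdU pulse-chase cell-cycle-exit experiment
#'
#' Labels cells that traverse S-phase during a short pulse, then advances
#' the population through a chase period. At every mitosis a daughter exits
#' the cycle with probability \code{quit_prob} and loses Ki67 (with an
#' optional detection lag); cells that exit stop dividing. Non-cycling
#' cells are Ki67-negative and unlabeled. Returns the full
#' marker x EdU x Ki67 cross-tabulation per field and replicate.
#'
#' @param spec A \code{\link{mixture_spec}}; component labels play the role
#'   of the marker (e.g. \code{marker_pos} / \code{marker_neg}).
#' @param pulse Pulse length, hours (> 0).
#' @param chase Chase length, hours (>= 0), measured from the end of the
#'   pulse.
#' @param ki67_lag Hours after cycle exit before Ki67 immunoreactivity is
#'   lost. Default 0 (loss immediate at the exit mitosis).
#' @param seed Optional integer seed overriding \code{spec$seed}.
#' @return An \code{exit_count_table} data.frame with columns
#'   \code{replicate}, \code{field}, \code{marker}, \code{edu}, \code{ki67},
#'   \code{count} and attributes \code{pulse}, \code{chase}.
#' @examples
#' pop <- cycle_population_params(tc = 40, ts = 16, gf = 0.9, quit_prob = 0.3)
#' tab <- simulate_pulse_chase(mixture_spec(pop, seed = 2), pulse = 2, chase = 48)
#' compute_exit_index(tab)
#' @export
simulate_pulse_chase <- function(spec, pulse, chase, ki67_lag = 0, seed = NULL) {
  stopifnot(inherits(spec, "mixture_spec"))
  if (pulse <= 0) stop("'pulse' must be > 0", call. = FALSE)
  if (chase < 0) stop("'chase' must be >= 0", call. = FALSE)
  if (ki67_lag < 0) stop("'ki67_lag' must be >= 0", call. = FALSE)
  seed <- if (!is.null(seed)) seed else spec$seed
  if (is.null(seed)) stop("a seed is required (in 'spec' or 'seed')", call. = FALSE)

  labels <- vapply(spec$components, `[[`, character(1), "label")
  ts_v <- vapply(spec$components, `[[`, numeric(1), "ts")
  tg_v <- vapply(spec$components, `[[`, numeric(1), "tg2m")
  q_v  <- vapply(spec$components, `[[`, numeric(1), "quit_prob")
  total_t <- pulse + chase

  rows <- withr::with_seed(seed, {
    out <- vector("list", spec$n_replicates * spec$n_fields)
    i <- 0L
    for (rep_id in seq_len(spec$n_replicates)) {
      for (field_id in seq_len(spec$n_fields)) {
        n <- stats::rpois(1L, spec$n_cells_per_field)
        if (n == 0L) n <- 1L
        cells <- .draw_field_cells(spec, n)
        edu <- cells$cycling &
          .labeled_by(cells$pos, pulse, cells$tc,
                      ts_v[cells$comp], tg_v[cells$comp])
        # mitoses passed by the end of the chase; mitosis k occurs at
        # time k*tc - pos
        n_mit <- floor((cells$pos + total_t) / cells$tc)
        n_mit[!cells$cycling] <- 0
        # index of the mitosis at which the lineage exits (geometric trial
        # per mitosis with per-population quit probability)
        q <- q_v[cells$comp]
        k_exit <- rep(Inf, n)
        idx <- which(q > 0)
        if (length(idx))
          k_exit[idx] <- stats::rgeom(length(idx), q[idx]) + 1
        exit_time <- k_exit * cells$tc - cells$pos
        exited <- cells$cycling & k_exit <= n_mit &
          exit_time + ki67_lag <= total_t
        ki67 <- cells$cycling & !exited
        i <- i + 1L
        tab <- table(marker = labels[cells$comp],
                     edu = factor(edu, c(FALSE, TRUE), c("neg", "pos")),
                     ki67 = factor(ki67, c(FALSE, TRUE), c("neg", "pos")))
        df <- as.data.frame(tab, responseName = "count",
                            stringsAsFactors = FALSE)
        df$replicate <- rep_id
        df$field <- field_id
        out[[i]] <- df[, c("replicate", "field", "marker", "edu", "ki67", "count")]
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "pulse") <- pulse
  attr(res, "chase") <- chase
  class(res) <- c("exit_count_table", "data.frame")
  res
}

#' Simulate a flow-cytometry sample with a matched negative control
#'
#' Emits per-event reporter and viability-dye intensities for a reporter
#' line sample at a given day of differentiation, together with a matched
#' negative-control (parental line) sample with zero positive prevalence.
#' Viable events are reporter-positive with the prevalence given by
#' \code{\link{trajectory_prevalence}}; intensities are drawn from
#' log-normal background and right-shifted positive components, and a
#' configurable fraction of events are dead cells carrying high
#' viability-dye intensity.
#'
#' @param trajectory A \code{\link{trajectory_params}} object.
#' @param day Day of differentiation.
#' @param n_events Events per sample (>= 1); the control sample has the
#'   same size.
#' @param seed Integer seed.
#' @param condition Condition label stored in the metadata columns.
#' @param replicate Replicate id stored in the metadata columns.
#' @param intensity Optional list overriding the intensity model, with
#'   elements \code{bg_meanlog}, \code{bg_sdlog}, \code{pos_meanlog},
#'   \code{pos_sdlog}, \code{via_live_meanlog}, \code{via_dead_meanlog},
#'   \code{via_sdlog}.
#' @return A \code{flow_event_table} data.frame with columns
#'   \code{reporter_intensity}, \code{viability_intensity}, \code{day},
#'   \code{condition}, \code{replicate}, \code{role} (\code{"reporter"} or
#'   \code{"negative_control"}).
#' @examples
#' ev <- simulate_flow_sample(trajectory_params(), day = 45,
#'                            n_events = 2000, seed = 3)
#' table(ev$role)
#' @export
simulate_flow_sample <- function(trajectory, day, n_events, seed,
                                 condition = "control", replicate = 1L,
                                 intensity = list()) {
  stopifnot(inherits(trajectory, "trajectory_params"))
  if (n_events < 1) stop("'n_events' must be >= 1", call. = FALSE)
  im <- utils::modifyList(list(
    bg_meanlog = log(100), bg_sdlog = 0.5,
    pos_meanlog = log(3000), pos_sdlog = 0.5,
    via_live_meanlog = log(100), via_dead_meanlog = log(5000),
    via_sdlog = 0.4), intensity)
  prev <- trajectory_prevalence(trajectory, day)

  one_sample <- function(role, p_pos) {
    dead <- stats::runif(n_events) < trajectory$dead_fraction
    pos <- !dead & stats::runif(n_events) < p_pos
    rep_int <- stats::rlnorm(n_events, im$bg_meanlog, im$bg_sdlog)
    rep_int[pos] <- stats::rlnorm(sum(pos), im$pos_meanlog, im$pos_sdlog)
    via <- stats::rlnorm(n_events,
                         ifelse(dead, im$via_dead_meanlog, im$via_live_meanlog),
                         im$via_sdlog)
    data.frame(reporter_intensity = rep_int, viability_intensity = via,
               day = day, condition = condition, replicate = replicate,
               role = role, stringsAsFactors = FALSE)
  }
  res <- withr::with_seed(seed, rbind(one_sample("reporter", prev),
                                      one_sample("negative_control", 0)))
  rownames(res) <- NULL
  class(res) <- c("flow_event_table", "data.frame")
  res
}
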