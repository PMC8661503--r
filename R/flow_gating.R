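#' Viability gate: discard dead cells on the viability-dye channel
#'
#' Removes events whose viability-dye intensity exceeds a fixed multiple of
#' the within-sample median, the conventional stand-in for a manual
#' DAPI-exclusion gate. The threshold is computed separately for each
#' sample present in the table (grouping on day, condition, replicate and
#' role), so samples with different staining intensity scales are gated on
#' their own baseline.
#'
#' @param events A \code{flow_event_table} data.frame (see
#'   \code{\link{simulate_flow_sample}} / \code{\link{read_flow_events}}).
#' @param threshold_multiplier Dead cells are events above
#'   \code{threshold_multiplier * median(viability_intensity)} of their
#'   sample; default 4.
#' @return The surviving events, with attribute \code{"viability_log"}
#'   (per-sample data.frame of \code{n_total}, \code{n_removed},
#'   \code{threshold}) and per-row provenance preserved.
#' @examples
#' ev <- simulate_flow_sample(trajectory_params(), 40, 1000, seed = 1)
#' gated <- gate_viable(ev)
#' attr(gated, "viability_log")
#' @export
gate_viable <- function(events, threshold_multiplier = 4) {
  events <- .validate_flow_events(events)
  if (!nrow(events)) stop("no events to gate", call. = FALSE)
  stopifnot(threshold_multiplier > 0)
  key <- interaction(events$day, events$condition, events$replicate,
                     events$role, drop = TRUE)
  keep <- logical(nrow(events))
  log_rows <- lapply(levels(key), function(k) {
    idx <- key == k
    thr <- threshold_multiplier * stats::median(events$viability_intensity[idx])
    ok <- idx & events$viability_intensity <= thr
    keep[ok] <<- TRUE
    d <- events[idx, ][1, c("day", "condition", "replicate", "role")]
    cbind(d, n_total = sum(idx), n_removed = sum(idx) - sum(ok),
          threshold = thr)
  })
  res <- events[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "viability_log") <- do.call(rbind, log_rows)
  class(res) <- c("flow_event_table", "data.frame")
  res
}

#' Positivity gate against a matched negative control
#'
#' Sets the reporter-positivity threshold at a high percentile (default
#' 99.9) of the matched negative-control sample's reporter channel — the
#' standard rule for a knock-in reporter gated against the parental,
#' reporter-free line at the same stage of differentiation — and reports
#' the percentage of viable sample events above it.
#'
#' @param sample Viability-gated \code{flow_event_table} of the reporter
#'   line (one sample).
#' @param control Viability-gated \code{flow_event_table} of the matched
#'   negative control, acquired at the same day. Required; there is no
#'   silent fallback.
#' @param percentile Control percentile defining the threshold, in
#'   (0, 100); default 99.9.
#' @return An object of class \code{"gate_result"}: \code{threshold},
#'   \code{positive_fraction} (percent of viable events), \code{n_viable},
#'   \code{n_total}, \code{day}, \code{condition}, \code{replicate}.
#' @examples
#' ev <- gate_viable(simulate_flow_sample(trajectory_params(), 45, 5000, seed = 2))
#' gate_positive(ev[ev$role == "reporter", ],
#'               ev[ev$role == "negative_control", ])
#' @export
gate_positive <- function(sample, control, percentile = 99.9) {
  sample <- .validate_flow_events(sample)
  if (missing(control) || is.null(control))
    stop("a matched negative-control sample is required; none was supplied",
         call. = FALSE)
  control <- .validate_flow_events(control)
  if (!nrow(sample) || !nrow(control))
    stop("empty sample or control after gating", call. = FALSE)
  stopifnot(percentile > 0, percentile < 100)
  d_s <- unique(sample$day); d_c <- unique(control$day)
  if (length(d_s) != 1L || length(d_c) != 1L || d_s != d_c)
    stop("control is not matched to the sample: sample day(s) ",
         paste(d_s, collapse = ","), " vs control day(s) ",
         paste(d_c, collapse = ","), call. = FALSE)
  thr <- unname(stats::quantile(control$reporter_intensity, percentile / 100))
  n_total <- attr(sample, "viability_log")
  n_total <- if (!is.null(n_total)) sum(n_total$n_total) else nrow(sample)
  structure(list(threshold = thr,
                 positive_fraction = 100 * mean(sample$reporter_intensity > thr),
                 n_viable = nrow(sample), n_total = n_total,
                 day = d_s, condition = sample$condition[1],
                 replicate = sample$replicate[1]),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(
    "Gate (day %s, %s, rep %s): %.2f%% positive of %d viable events (threshold %.1f)\n",
    format(x$day), x$condition, format(x$replicate),
    x$positive_fraction, x$n_viable, x$threshold))
  invisible(x)
}

#' Assemble gated samples into a differentiation timecourse
#'
#' Summarizes per-sample positive fractions into a per-(day, condition)
#' timecourse of mean +/- SEM across replicates. Days absent from the
#' input stay absent (no interpolation); duplicate
#' (day, condition, replicate) keys are an error.
#'
#' @param gated Either a list of \code{"gate_result"} objects or a
#'   data.frame with columns \code{day}, \code{condition},
#'   \code{replicate}, \code{positive_fraction}.
#' @return A \code{"timecourse"} data.frame with columns \code{day},
#'   \code{condition}, \code{n_replicates}, \code{positive_fraction}
#'   (mean, percent) and \code{sem} (NA for a single replicate), sorted by
#'   condition then day.
#' @export
build_timecourse <- function(gated) {
  if (is.list(gated) && !is.data.frame(gated) &&
      all(vapply(gated, inherits, logical(1), "gate_result"))) {
    gated <- do.call(rbind, lapply(gated, function(g)
      data.frame(day = g$day, condition = g$condition,
                 replicate = g$replicate,
                 positive_fraction = g$positive_fraction,
                 stringsAsFactors = FALSE)))
  }
  if (!is.data.frame(gated) ||
      !all(c("day", "condition", "replicate", "positive_fraction") %in% names(gated)))
    stop("'gated' must be gate_result objects or a data.frame with day, ",
         "condition, replicate, positive_fraction", call. = FALSE)
  key <- paste(gated$day, gated$condition, gated$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (day, condition, replicate) entries", call. = FALSE)
  grp <- paste(gated$condition, gated$day, sep = "\r")
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    d <- gated[grp == g, ]
    data.frame(day = d$day[1], condition = d$condition[1],
               n_replicates = nrow(d),
               positive_fraction = mean(d$positive_fraction),
               sem = if (nrow(d) > 1)
                 stats::sd(d$positive_fraction) / sqrt(nrow(d)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$day), ]
  rownames(out) <- NULL
  class(out) <- c("timecourse", "data.frame")
  out
}

#' Percent reduction of a treated value relative to a reference
#'
#' \code{100 * (reference - treated) / reference}; e.g. reporter-positive
#' percentages of 44.72 (control) and 24.62 (treated) give a 45 percent
#' reduction after rounding.
#'
#' @param reference Reference value (> 0).
#' @param treated Treated value.
#' @return Percent reduction (negative if treated exceeds reference).
#' @examples
#' percent_reduction(44.72, 24.62)
#' @export
percent_reduction <- function(reference, treated) {
  if (any(reference <= 0)) stop("'reference' must be > 0", call. = FALSE)
  100 * (reference - treated) / reference
}

#' Fold change of a reference over a treated value
#'
#' @param reference Reference value.
#' @param treated Treated value (> 0).
#' @return \code{reference / treated}.
#' @examples
#' fold_change(40, 10)  # 4
#' @export
fold_change <- function(reference, treated) {
  if (any(treated <= 0)) stop("'treated' must be > 0", call. = FALSE)
  reference / treated
}

.validate_flow_events <- function(events) {
  if (!is.data.frame(events)) stop("'events' must be a data.frame", call. = FALSE)
  need <- c("reporter_intensity", "viability_intensity", "day", "condition",
            "replicate", "role")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("flow event table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(events$reporter_intensity)) ||
      any(!is.finite(events$viability_intensity)) ||
      any(events$reporter_intensity < 0) || any(events$viability_intensity < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  events
}
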