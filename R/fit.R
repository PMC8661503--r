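#' Fit the cumulative-labeling linear model
#'
#' Ordinary least squares of the labeled fraction on exposure time, the
#' regression whose slope \eqn{m = GF/tc} and intercept \eqn{b = GF\,ts/tc}
#' are inverted by \code{\link{estimate_cycle_params}}. Fields are pooled
#' within each biological replicate (fractions weighted by field totals);
#' the returned coefficients come from the fully pooled curve and a
#' per-replicate sub-fit is retained for dispersion and condition
#' comparisons.
#'
#' Under \code{policy = "plateau_exclude"} the largest exposure times are
#' dropped, iteratively, while the fitted prediction at the largest
#' retained time reaches \code{(1 - plateau_tol)} of the growth fraction:
#' once \eqn{t \ge tc - ts} the labeled fraction saturates at \eqn{GF} and
#' points on the plateau bias the slope downward. This policy requires
#' \code{gf}. The exclusion set is decided on the pooled curve and applied
#' identically to every replicate sub-fit.
#'
#' @param curve A \code{labeling_curve} data.frame (see
#'   \code{\link{simulate_cumulative_labeling}} /
#'   \code{\link{read_labeling_curve}}).
#' @param policy \code{"all"} (default: every exposure time) or
#'   \code{"plateau_exclude"}.
#' @param gf Growth fraction, required for \code{"plateau_exclude"}.
#' @param subpop Which subpopulation to fit; may be omitted when the curve
#'   contains a single one.
#' @param plateau_tol Relative closeness to \code{gf} at which a time point
#'   is considered saturated (default 0.01).
#' @return An object of class \code{"linear_fit"} with elements \code{m},
#'   \code{b}, \code{r2}, \code{n_points}, \code{times_used},
#'   \code{sub_fits} (per-replicate slopes/intercepts), \code{policy} and
#'   \code{flags}.
#' @examples
#' pop <- cycle_population_params(tc = 40, ts = 16, gf = 0.9)
#' curve <- simulate_cumulative_labeling(mixture_spec(pop, seed = 1))
#' fit_labeling_curve(curve, policy = "plateau_exclude", gf = 0.9)
#' @export
fit_labeling_curve <- function(curve, policy = c("all", "plateau_exclude"),
                               gf = NULL, subpop = NULL, plateau_tol = 0.01) {
  policy <- match.arg(policy)
  curve <- .validate_curve(curve)
  subs <- unique(curve$subpop)
  if (is.null(subpop)) {
    if (length(subs) > 1L)
      stop("curve contains several subpopulations (",
           paste(subs, collapse = ", "), "); choose one via 'subpop'",
           call. = FALSE)
    subpop <- subs
  }
  curve <- curve[curve$subpop == subpop, , drop = FALSE]
  if (!nrow(curve)) stop("no rows for subpop '", subpop, "'", call. = FALSE)
  if (policy == "plateau_exclude" && is.null(gf))
    stop("'plateau_exclude' requires the growth fraction 'gf'", call. = FALSE)

  # field-pooled fractions: per (replicate, time) and fully pooled per time
  pool <- function(df, by) {
    lab <- tapply(df$n_labeled, by, sum)
    tot <- tapply(df$n_total, by, sum)
    data.frame(key = names(lab), frac = as.numeric(lab) / as.numeric(tot),
               stringsAsFactors = FALSE)
  }
  pooled <- pool(curve, format(curve$time, digits = 15))
  pooled$time <- as.numeric(pooled$key)
  pooled <- pooled[order(pooled$time), ]

  all_times <- sort(unique(curve$time))
  if (length(all_times) < 2L)
    stop("at least 2 distinct exposure times are required", call. = FALSE)

  ols <- function(df, times) {
    d <- df[df$time %in% times, ]
    stats::lm(frac ~ time, data = d)
  }

  times_used <- all_times
  fit <- ols(pooled, times_used)
  if (policy == "plateau_exclude") {
    repeat {
      if (length(times_used) <= 2L) break
      pred_max <- unname(stats::predict(fit,
                                        newdata = data.frame(time = max(times_used))))
      if (pred_max < (1 - plateau_tol) * gf) break
      times_used <- times_used[-length(times_used)]
      fit <- ols(pooled, times_used)
    }
  }

  co <- stats::coef(fit)
  flags <- character()
  if (all(pooled$frac == 0)) flags <- c(flags, "degenerate_fit_all_zero")
  r2 <- suppressWarnings(summary(fit)$r.squared)

  reps <- sort(unique(curve$replicate))
  sub_fits <- do.call(rbind, lapply(reps, function(r) {
    dr <- curve[curve$replicate == r, ]
    pr <- pool(dr, format(dr$time, digits = 15))
    pr$time <- as.numeric(pr$key)
    if (sum(pr$time %in% times_used) < 2L) return(NULL)
    cr <- stats::coef(ols(pr, times_used))
    data.frame(replicate = r, m = unname(cr[["time"]]),
               b = unname(cr[["(Intercept)"]]))
  }))

  structure(list(m = unname(co[["time"]]), b = unname(co[["(Intercept)"]]),
                 r2 = r2, n_points = length(times_used),
                 times_used = times_used, sub_fits = sub_fits,
                 policy = policy, subpop = subpop, flags = flags),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Cumulative-labeling fit (%s): slope m = %.5f /h, intercept b = %.4f, R2 = %.4f\n",
              x$subpop, x$m, x$b, x$r2))
  cat(sprintf("  policy = %s; times used: %s h; %d replicate sub-fit(s)\n",
              x$policy, paste(x$times_used, collapse = ", "),
              if (is.null(x$sub_fits)) 0L else nrow(x$sub_fits)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the growth fraction of a labeling curve
#'
#' The growth fraction \eqn{GF} (proportion of cells cycling) needed to
#' invert the cumulative-labeling fit. Three routes: \code{"supplied"}
#' passes a known value through, \code{"ki67"} uses an externally measured
#' Ki67-positive fraction, and \code{"plateau"} averages the field-pooled
#' labeled fraction over the saturated tail of the curve (times whose
#' pooled fraction is within \code{tol} of the curve maximum). The plateau
#' route refuses to guess when fewer than two time points are saturated.
#'
#' @param curve A \code{labeling_curve}; only needed for
#'   \code{method = "plateau"}.
#' @param method One of \code{"supplied"}, \code{"plateau"}, \code{"ki67"}.
#' @param gf Growth fraction for \code{method = "supplied"}.
#' @param ki67_fraction Ki67-positive fraction for \code{method = "ki67"}.
#' @param subpop Subpopulation to use when the curve has several.
#' @param tol Relative tolerance defining the saturated tail (default 0.02).
#' @return The growth fraction, a single number in `(0, 1]`.
#' @export
estimate_growth_fraction <- function(curve = NULL,
                                     method = c("supplied", "plateau", "ki67"),
                                     gf = NULL, ki67_fraction = NULL,
                                     subpop = NULL, tol = 0.02) {
  method <- match.arg(method)
  if (method == "supplied") {
    if (is.null(gf)) stop("method 'supplied' requires 'gf'", call. = FALSE)
    stopifnot(gf > 0, gf <= 1)
    return(gf)
  }
  if (method == "ki67") {
    if (is.null(ki67_fraction))
      stop("method 'ki67' requires 'ki67_fraction'", call. = FALSE)
    stopifnot(ki67_fraction > 0, ki67_fraction <= 1)
    return(ki67_fraction)
  }
  curve <- .validate_curve(curve)
  subs <- unique(curve$subpop)
  if (is.null(subpop)) {
    if (length(subs) > 1L)
      stop("curve contains several subpopulations; choose one via 'subpop'",
           call. = FALSE)
    subpop <- subs
  }
  curve <- curve[curve$subpop == subpop, , drop = FALSE]
  lab <- tapply(curve$n_labeled, curve$time, sum)
  tot <- tapply(curve$n_total, curve$time, sum)
  frac <- as.numeric(lab) / as.numeric(tot)
  times <- as.numeric(names(lab))
  sat <- frac >= (1 - tol) * max(frac)
  if (sum(sat) < 2L)
    stop("no saturated time points detected; the curve has not reached its ",
         "plateau. Supply gf directly (method 'supplied') or a Ki67 ",
         "fraction (method 'ki67').", call. = FALSE)
  sum(as.numeric(lab)[sat]) / sum(as.numeric(tot)[sat])
}

#' Invert a cumulative-labeling fit to cell-cycle and S-phase lengths
#'
#' Applies the growth-fraction inversion of the linear cumulative-labeling
#' model: \eqn{tc = GF/m} and \eqn{ts = b \cdot tc / GF}, where \eqn{m} and
#' \eqn{b} are the fitted slope and intercept. When the fit carries
#' per-replicate sub-fits, each replicate is inverted separately and the
#' SEM of the replicate-level \eqn{tc}, \eqn{ts} is reported as dispersion.
#'
#' @param fit A \code{"linear_fit"} from \code{\link{fit_labeling_curve}}.
#' @param gf Growth fraction in `(0, 1]` (see
#'   \code{\link{estimate_growth_fraction}}).
#' @return An object of class \code{"cycle_estimate"}: \code{tc_hat},
#'   \code{ts_hat} (hours), \code{gf_used}, \code{tc_sem}, \code{ts_sem},
#'   replicate-level values \code{tc_reps}, \code{ts_reps}, and quality
#'   \code{flags} (\code{"ts_exceeds_tc"}, \code{"negative_intercept"},
#'   \code{"replicate_nonpositive_slope"}).
#' @examples
#' fit <- structure(list(m = 0.025, b = 0.4, r2 = 1, n_points = 4,
#'                       times_used = c(2, 4, 8, 16), sub_fits = NULL,
#'                       policy = "all", subpop = "x", flags = character()),
#'                  class = "linear_fit")
#' estimate_cycle_params(fit, gf = 1)  # tc = 40 h, ts = 16 h
#' @export
estimate_cycle_params <- function(fit, gf) {
  stopifnot(inherits(fit, "linear_fit"))
  if (!is.numeric(gf) || length(gf) != 1L || gf <= 0 || gf > 1)
    stop("'gf' must be a single number in (0, 1]", call. = FALSE)
  if (fit$m <= 0)
    stop("fitted slope is non-positive; the labeled fraction does not ",
         "increase with exposure time, so no cycle-length estimate exists",
         call. = FALSE)
  tc_hat <- gf / fit$m
  ts_hat <- fit$b * tc_hat / gf
  flags <- fit$flags
  if (fit$b < 0) flags <- c(flags, "negative_intercept")
  if (ts_hat > tc_hat) flags <- c(flags, "ts_exceeds_tc")

  tc_reps <- ts_reps <- numeric(0)
  tc_sem <- ts_sem <- NA_real_
  if (!is.null(fit$sub_fits) && nrow(fit$sub_fits)) {
    ok <- fit$sub_fits$m > 0
    if (any(!ok)) flags <- c(flags, "replicate_nonpositive_slope")
    sf <- fit$sub_fits[ok, , drop = FALSE]
    if (nrow(sf)) {
      tc_reps <- stats::setNames(gf / sf$m, sf$replicate)
      ts_reps <- stats::setNames(sf$b * (gf / sf$m) / gf, sf$replicate)
      if (length(tc_reps) >= 2L) {
        tc_sem <- stats::sd(tc_reps) / sqrt(length(tc_reps))
        ts_sem <- stats::sd(ts_reps) / sqrt(length(ts_reps))
      }
    }
  }
  structure(list(tc_hat = tc_hat, ts_hat = ts_hat, gf_used = gf,
                 tc_sem = tc_sem, ts_sem = ts_sem,
                 tc_reps = tc_reps, ts_reps = ts_reps,
                 flags = unique(flags), fit = fit),
            class = "cycle_estimate")
}

#' @export
print.cycle_estimate <- function(x, ...) {
  fmt <- function(v, s) if (is.na(s)) sprintf("%.2f h", v)
    else sprintf("%.2f +/- %.2f h (SEM, %d replicates)", v, s, length(x$tc_reps))
  cat(sprintf("Cell-cycle estimate (GF = %.2f):\n  tc = %s\n  ts = %s\n",
              x$gf_used, fmt(x$tc_hat, x$tc_sem), fmt(x$ts_hat, x$ts_sem)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Compare cell-cycle estimates between two conditions
#'
#' Tests the replicate-level cell-cycle lengths (and S-phase lengths) of
#' two conditions against each other, delegating the choice of test to the
#' gatekept procedure of \code{\link{compare_groups}} (normality and
#' variance-homogeneity checks, parametric test with rank-based fallback).
#'
#' @param est_a,est_b \code{"cycle_estimate"} objects carrying replicate-
#'   level values (at least 2 per arm).
#' @param labels Length-2 character vector naming the conditions.
#' @return A list of class \code{"cycle_comparison"} with one
#'   \code{stat_result} per quantity (\code{tc}, \code{ts}) plus the mean
#'   differences (a minus b).
#' @export
compare_conditions <- function(est_a, est_b, labels = c("a", "b")) {
  stopifnot(inherits(est_a, "cycle_estimate"), inherits(est_b, "cycle_estimate"))
  if (length(est_a$tc_reps) < 2L || length(est_b$tc_reps) < 2L)
    stop("both estimates need >= 2 replicate-level values; refit with ",
         "replicate structure", call. = FALSE)
  one <- function(va, vb) {
    g <- stats::setNames(list(va, vb), labels)
    compare_groups(g, design = "two_group")
  }
  structure(list(
    tc = one(est_a$tc_reps, est_b$tc_reps),
    ts = one(est_a$ts_reps, est_b$ts_reps),
    tc_diff = mean(est_a$tc_reps) - mean(est_b$tc_reps),
    ts_diff = mean(est_a$ts_reps) - mean(est_b$ts_reps),
    labels = labels), class = "cycle_comparison")
}

#' @export
print.cycle_comparison <- function(x, ...) {
  cat(sprintf("Condition comparison (%s vs %s):\n", x$labels[1], x$labels[2]))
  cat(sprintf("  tc: diff = %.2f h, %s p = %.4g\n",
              x$tc_diff, x$tc$test_name, x$tc$p_value))
  cat(sprintf("  ts: diff = %.2f h, %s p = %.4g\n",
              x$ts_diff, x$ts$test_name, x$ts$p_value))
  invisible(x)
}

.validate_curve <- function(curve) {
  if (!is.data.frame(curve)) stop("'curve' must be a data.frame", call. = FALSE)
  need <- c("time", "replicate", "field", "subpop", "n_total", "n_labeled")
  miss <- setdiff(need, names(curve))
  if (length(miss))
    stop("labeling curve is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(curve$n_labeled > curve$n_total) || any(curve$n_labeled < 0))
    stop("counts must satisfy 0 <= n_labeled <= n_total", call. = FALSE)
  if (any(curve$time <= 0)) stop("exposure times must be > 0", call. = FALSE)
  curve
}
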