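# Shared fixture builders. Noise-free curves are constructed with
# fractional "counts" lying exactly on the analytic line so that exactness
# properties can be asserted to floating-point precision.

noise_free_curve <- function(tc, ts, gf, times, n_total = 1000,
                             n_replicates = 2, subpop = "marker_pos") {
  frac <- gf * pmin((ts + times) / tc, 1)
  grid <- expand.grid(time = seq_along(times), replicate = seq_len(n_replicates))
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    j <- grid$time[i]
    data.frame(time = times[j], replicate = grid$replicate[i], field = 1L,
               subpop = subpop, n_total = n_total,
               n_labeled = frac[j] * n_total)
  }))
  class(out) <- c("labeling_curve", "data.frame")
  out
}

# curve from explicit (time, fraction) points, single replicate/field
curve_from_points <- function(times, fracs, subpop = "marker_pos",
                              n_replicates = 1) {
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r)
    data.frame(time = times, replicate = r, field = 1L, subpop = subpop,
               n_total = 1000, n_labeled = fracs * 1000)))
  class(out) <- c("labeling_curve", "data.frame")
  out
}

# minimal cycle_estimate carrying given replicate-level values
manual_estimate <- function(tc_reps, ts_reps = tc_reps * 0.4, gf = 1) {
  structure(list(tc_hat = mean(tc_reps), ts_hat = mean(ts_reps),
                 gf_used = gf,
                 tc_sem = stats::sd(tc_reps) / sqrt(length(tc_reps)),
                 ts_sem = stats::sd(ts_reps) / sqrt(length(ts_reps)),
                 tc_reps = tc_reps, ts_reps = ts_reps,
                 flags = character(), fit = NULL),
            class = "cycle_estimate")
}

# one exit-count row set for a constructed table
exit_table <- function(counts) {
  # counts: data.frame(marker, edu, ki67, count); single field/replicate
  counts$replicate <- 1L
  counts$field <- 1L
  out <- counts[, c("replicate", "field", "marker", "edu", "ki67", "count")]
  class(out) <- c("exit_count_table", "data.frame")
  out
}
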