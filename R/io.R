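#' Read and write the pipeline's tidy CSV formats
#'
#' The three tables the pipeline consumes are plain tidy CSVs:
#' \describe{
#'   \item{labeling curve}{columns \code{time}, \code{replicate},
#'     \code{field}, \code{subpop}, \code{n_total}, \code{n_labeled} — one
#'     row per exposure time, field, replicate and subpopulation.}
#'   \item{exit count table}{columns \code{replicate}, \code{field},
#'     \code{marker}, \code{edu}, \code{ki67}, \code{count} with
#'     \code{edu}/\code{ki67} coded \code{pos}/\code{neg}.}
#'   \item{flow event table}{columns \code{reporter_intensity},
#'     \code{viability_intensity}, \code{day}, \code{condition},
#'     \code{replicate}, \code{role} — one row per event; \code{role} is
#'     \code{reporter} or \code{negative_control}.}
#' }
#' Readers validate the invariants (count bounds, positivity of exposure
#' times, finite non-negative intensities) and attach the matching class.
#'
#' @param path CSV file path.
#' @param x Table to write.
#' @return Readers return the validated table; writers return \code{path}
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_labeling_curve <- function(path) {
  curve <- .validate_curve(utils::read.csv(path, stringsAsFactors = FALSE))
  class(curve) <- c("labeling_curve", "data.frame")
  curve
}

#' @rdname pipeline_io
#' @export
write_labeling_curve <- function(x, path) {
  .validate_curve(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_exit_counts <- function(path) {
  tab <- .validate_exit_counts(utils::read.csv(path, stringsAsFactors = FALSE))
  class(tab) <- c("exit_count_table", "data.frame")
  tab
}

#' @rdname pipeline_io
#' @export
write_exit_counts <- function(x, path) {
  .validate_exit_counts(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_flow_events <- function(path) {
  ev <- .validate_flow_events(utils::read.csv(path, stringsAsFactors = FALSE))
  class(ev) <- c("flow_event_table", "data.frame")
  ev
}

#' @rdname pipeline_io
#' @export
write_flow_events <- function(x, path) {
  .validate_flow_events(x)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
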