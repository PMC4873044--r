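#' Read and write trajectories as CSV
#'
#' Trajectories are exchanged as plain CSV with a header `time,x,y,z`
#' (seconds and arbitrary position units).
#'
#' @param path File path.
#' @return `read_trajectory_csv()` returns a tibble `time, x, y, z`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trajectory CSV must have columns time,x,y,z", call. = FALSE)
  }
  tibble::as_tibble(df[need])
}

#' @rdname read_trajectory_csv
#' @param traj A trajectory tibble.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Read a toy recording from a one-channel-per-column CSV
#'
#' @param path File path; every column is one channel's samples.
#' @param sampling_rate Sampling rate in Hz, attached as an attribute.
#' @return A channels x samples numeric matrix with attribute
#'   `sampling_rate`.
#' @export
read_recording_csv <- function(path, sampling_rate) {
  df <- utils::read.csv(path)
  rec <- t(as.matrix(df))
  attr(rec, "sampling_rate") <- sampling_rate
  rec
}

#' Serialize a decoding experiment report to JSON
#'
#' Writes the tabular surfaces of a [run_experiment()] result (selected
#' hyperparameters, per-coordinate criteria, delays, influence weights) as a
#' versioned JSON document; the fitted model itself is saved separately via
#' `saveRDS()`.
#'
#' @param result A `decode_experiment`.
#' @param path Output path.
#' @export
write_report_json <- function(result, path) {
  stopifnot(inherits(result, "decode_experiment"))
  doc <- list(
    schema = "smoothpls-report/1",
    method = result$method,
    selected = result$selected,
    metrics = result$metrics,
    delay = result$delay,
    influence = if (!is.null(result$influence)) {
      lapply(unclass(result$influence), as.numeric)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
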