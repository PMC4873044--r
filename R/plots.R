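#' Plot an influence profile
#'
#' Bar panels of the per-element weights of each modality (frequency,
#' temporal, spatial).
#'
#' @param object An `influence_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot influence_profile
#' @export
autoplot.influence_profile <- function(object, ...) {
  df <- tidy.influence_profile(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~modality, scales = "free_x") +
    ggplot2::labs(x = "element", y = "influence weight")
}

#' Plot observed vs predicted test trajectories
#'
#' One panel per coordinate, observed and decoded streams overlaid over the
#' test epochs.
#'
#' @param object A `decode_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decode_experiment
#' @export
autoplot.decode_experiment <- function(object, ...) {
  obs <- object$observed
  pred <- object$predictions
  cn <- colnames(obs)
  if (is.null(cn)) cn <- paste0("y", seq_len(ncol(obs)))
  n <- nrow(obs)
  df <- dplyr::bind_rows(lapply(seq_len(ncol(obs)), function(j) {
    tibble::tibble(
      epoch = rep(seq_len(n), 2L),
      coordinate = cn[j],
      stream = rep(c("observed", "predicted"), each = n),
      value = c(obs[, j], pred[, j])
    )
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$stream)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coordinate, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = "test epoch", y = "position",
                  title = sprintf("method: %s", object$method))
}

#' Plot the delay-search correlation profile
#'
#' Correlation between the observed stream and the prediction advanced by
#' each candidate shift; the returned delay is the smallest maximizer.
#'
#' @param object A `delay_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot delay_estimate
#' @export
autoplot.delay_estimate <- function(object, ...) {
  df <- tibble::tibble(
    shift = (seq_along(object$correlations) - 1L) * object$dt,
    correlation = object$correlations
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$correlation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$delay, linetype = 2) +
    ggplot2::labs(x = "shift (s)", y = "correlation")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
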