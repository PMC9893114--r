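#' Plot an oscillation-balance time course
#'
#' Raw `H_in`, `H_se`, and normalized balance traces over time, with phase
#' windows shaded when annotations are present.
#'
#' @param object An `osc_indices` tibble from [index_time_course()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.osc_indices <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("time", "H_in", "H_se", "H_sb_norm")],
    -"time", names_to = "index", values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~index, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (samples)", y = NULL,
                  title = "Oscillation-balance time course") +
    ggplot2::theme_minimal()
  if ("phase" %in% names(object)) {
    shade <- dplyr::summarise(
      dplyr::group_by(
        tibble::tibble(time = object$time, phase = object$phase), .data$phase),
      xmin = min(.data$time), xmax = max(.data$time), .groups = "drop")
    shade <- shade[!is.na(shade$phase), ]
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.12,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf, fill = .data$phase))
  }
  p
}

#' Plot a balance-index kernel density
#'
#' @param object An `hsb_density` from [kde_hsb()].
#' @param ... Unused.
#' @return A ggplot with the peak location marked.
#' @export
autoplot.hsb_density <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$grid, y = .data$density)) +
    ggplot2::geom_area(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$peak_x, linetype = "dashed",
                        colour = "navy") +
    ggplot2::labs(x = "H_sb (normalized)", y = "density",
                  title = sprintf("Balance-index density (peak at %.2f)",
                                  object$peak_x)) +
    ggplot2::theme_minimal()
}

#' Plot a peak-location track with plunge episodes
#'
#' @param object A `plunge_stats` from [peak_track()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plunge_stats <- function(object, ...) {
  pk <- object$peaks
  p <- ggplot2::ggplot(pk, ggplot2::aes(x = .data$interval,
                                        y = .data$peak_x)) +
    ggplot2::geom_line(colour = "navy", linetype = "dashed") +
    ggplot2::geom_point(colour = "navy") +
    ggplot2::labs(x = "interval", y = "density-peak H_sb",
                  title = sprintf("Peak track: %d plunge episode(s)",
                                  object$plunge_count)) +
    ggplot2::theme_minimal()
  if (nrow(object$episodes)) {
    mins <- pk[pk$interval %in% object$episodes$minimum, ]
    p <- p + ggplot2::geom_point(data = mins, colour = "red", size = 3,
                                 shape = 1)
  }
  p
}

#' Heatmap of one effective-network snapshot
#'
#' @param network An `effective_network`.
#' @param t Snapshot index (default: last).
#' @return A ggplot tile map (rows = source node).
#' @export
plot_snapshot <- function(network, t = length(network$times)) {
  A <- snapshot_matrix(network, t)
  df <- tibble::as_tibble(as.data.frame.table(A, responseName = "weight"))
  names(df)[1:2] <- c("from", "to")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev(rownames(A))) +
    ggplot2::labs(title = sprintf("Effective network at sample %d",
                                  network$times[t]),
                  x = "target", y = "source") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
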