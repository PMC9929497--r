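#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of the fuzzy response surface
#'
#' @param object A `wake_grid` from [wake_response_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wake_grid <- function(object, ...) {
  free <- setdiff(names(object), "output")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data[[free[1]]], y = .data[[free[2]]],
                               fill = .data$output)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "in-wake") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste0(free[1], " (m)"), y = paste0(free[2], " (m)"),
      title = sprintf("Defuzzified output (%s = %g m)",
                      attr(object, "plane"), attr(object, "value"))
    ) +
    ggplot2::theme_minimal()
}

#' Leader-preference histograms with null intervals
#'
#' One panel per follower: observed per-leader following proportions (bars),
#' the bootstrap no-preference interval (error bars) and the favourite
#' leader (point).
#'
#' @param object A `leader_preference` from [leader_preference()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.leader_preference <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prop, y = .data$leader)) +
    ggplot2::geom_col(fill = "seagreen", alpha = 0.8) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0.3, linewidth = 0.3) +
    ggplot2::geom_point(data = df[df$favourite, ],
                        ggplot2::aes(x = .data$prop + 0.02), shape = 8) +
    ggplot2::facet_wrap(~follower) +
    ggplot2::labs(x = "proportion of in-wake snapshots", y = "leader") +
    ggplot2::theme_minimal()
}

#' Positional histograms of the two models
#'
#' Faceted by axis and (optionally) subset; the signature comparison of the
#' fuzzy model against the frontal nearest neighbour.
#'
#' @param object A `model_agreement` from [model_agreement()].
#' @param subset `"all"`, `"disagreement"` or both (default).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.model_agreement <- function(object,
                                     subset = c("all", "disagreement"),
                                     ...) {
  subset <- match.arg(subset, several.ok = TRUE)
  df <- object$histograms
  df <- df[df$subset %in% subset, , drop = FALSE]
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                   fill = .data$model)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55) +
    ggplot2::facet_grid(subset ~ axis, scales = "free") +
    ggplot2::scale_fill_manual(values = c(fis = "steelblue",
                                          fnn = "darkorange")) +
    ggplot2::labs(x = "follower position relative to chosen leader (m)",
                  y = "snapshots") +
    ggplot2::theme_minimal()
}

#' Top-down snapshot of a flock with wake arrows
#'
#' Plots bird positions at one snapshot and an arrow from each in-wake
#' follower to its wake provider, coloured by the defuzzified output.
#'
#' @param fit A `wake_fis` from [run_wake_fis()].
#' @param positions The positions table the model was run on.
#' @param t Snapshot timestamp (s); defaults to the median analysed
#'   snapshot.
#' @return A ggplot.
#' @export
plot_flock_snapshot <- function(fit, positions, t = NULL) {
  stopifnot(inherits(fit, "wake_fis"))
  if (is.null(t)) t <- stats::median(unique(fit$assignments$t))
  snap_t <- unique(fit$assignments$t)
  t <- snap_t[which.min(abs(snap_t - t))]
  pos <- positions[abs(positions$t - t) < 1e-9, , drop = FALSE]
  arrows <- fit$assignments |>
    dplyr::filter(.data$t == !!t, .data$state == "in_wake") |>
    dplyr::inner_join(dplyr::select(pos, follower = "bird_id",
                                    fx = "x", fy = "y"),
                      by = "follower") |>
    dplyr::inner_join(dplyr::select(pos, leader = "bird_id",
                                    lx = "x", ly = "y"),
                      by = "leader")
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = arrows,
      ggplot2::aes(x = .data$fx, y = .data$fy, xend = .data$lx,
                   yend = .data$ly, colour = .data$output),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      inherit.aes = FALSE) +
    ggplot2::geom_point(size = 2, colour = "grey30") +
    ggplot2::scale_colour_gradient(low = "blue", high = "red",
                                   limits = c(0, 1), name = "strength") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Flock at t = %.1f s", t),
                  x = "east (m)", y = "north (m)") +
    ggplot2::theme_minimal()
}

#' Bar plot of alone-time proportions
#'
#' @param alone Output of [alone_stats()].
#' @return A ggplot with the two alone components stacked.
#' @export
plot_alone_stats <- function(alone) {
  df <- alone |>
    tidyr::pivot_longer(c("prop_no_front", "prop_front_not_in_wake"),
                        names_to = "component", values_to = "prop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$follower, y = .data$prop,
                                   fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(prop_no_front = "grey70",
                 prop_front_not_in_wake = "grey40"),
      labels = c(prop_no_front = "no bird in front",
                 prop_front_not_in_wake = "front bird, not in wake")) +
    ggplot2::labs(x = NULL, y = "proportion of snapshots flying alone",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
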