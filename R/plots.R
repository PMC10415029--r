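#' Plot a project's intake-label timeline
#'
#' Shows the day's per-image intake labels as a rug over time with the
#' detected eating episodes (if supplied) as shaded spans — the headless
#' counterpart of the episode panel an annotator scrolls.
#'
#' @param object a [camera_project()].
#' @param episodes optional [detect_episodes()] tibble to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.camera_project <- function(object, episodes = NULL, ...) {
  imgs <- object$images
  p <- ggplot2::ggplot(imgs, ggplot2::aes(x = .data$timestamp, y = .data$label)) +
    ggplot2::geom_step(color = "grey40") +
    ggplot2::scale_y_continuous(breaks = c(0, 1), limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "Intake label",
      title = paste0(
        "Participant ", object$participant_id, ", ",
        format(object$day_id)
      )
    ) +
    ggplot2::theme_minimal()
  if (!is.null(episodes) && nrow(episodes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = episodes,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.25
    )
  }
  p
}

#' Plot a day's energy intake by meal
#'
#' @param object a [day_annotation()].
#' @param ... unused.
#' @return a ggplot of consumed energy per annotated episode.
#' @export
autoplot.day_annotation <- function(object, ...) {
  s <- summarize_meals(object)
  ggplot2::ggplot(
    s,
    ggplot2::aes(
      x = stats::reorder(
        paste0(.data$aeep_id, ": ", .data$meal_label), .data$aeep_id
      ),
      y = .data$energy_kcal
    )
  ) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "Annotated eating episode", y = "Consumed energy (kcal)",
      title = "Energy intake by eating episode"
    ) +
    ggplot2::theme_minimal()
}
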