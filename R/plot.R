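#' Plot a tag record with optional detections and truth marks
#'
#' Facetted time-series view of the sensor streams the detector consumes:
#' depth (axis reversed, surface up), roll, flow noise, and the one-second
#' binned jerk mode. Detections are drawn as vertical lines, ground-truth
#' lunges as points on the depth panel.
#'
#' @param object A [tag_record()].
#' @param detections Optional `lunge_detections` tibble.
#' @param truth Optional ground-truth tibble (`time_s`, `depth_m`).
#' @param config A `lunge_config` (for the binning). Default
#'   [default_config()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tag_record
#' @export
autoplot.tag_record <- function(object, detections = NULL, truth = NULL,
                                config = default_config(), ...) {
  feats <- bin_features(object, config)
  long <- bind_rows(
    tibble(t_s = object$depth$t_s, value = -object$depth$depth_m, panel = "depth (m, surface up)"),
    tibble(t_s = object$motion$t_s, value = object$motion$roll_deg, panel = "roll (deg)"),
    if (!is.null(object$flow)) {
      tibble(t_s = object$flow$t_s, value = object$flow$flow_db, panel = "flow noise (dB)")
    },
    tibble(t_s = feats$bin_start_s, value = feats$jerk_mode, panel = "jerk mode (m/s^3)")
  )
  long$panel <- factor(long$panel, levels = unique(long$panel))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = sprintf("whale %s", object$whale_id)) +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(detections) && nrow(detections) > 0) {
    p <- p + ggplot2::geom_vline(
      data = tibble(time_s = detections$time_s),
      ggplot2::aes(xintercept = .data$time_s),
      color = "firebrick", linetype = "dashed", linewidth = 0.3
    )
  }
  if (!is.null(truth) && nrow(truth) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble(
        t_s = truth$time_s, value = -truth$depth_m,
        panel = factor("depth (m, surface up)", levels = levels(long$panel))
      ),
      color = "dodgerblue3", size = 1.6
    )
  }
  p
}

#' Plot an evaluation report
#'
#' Bar chart of TP and FP rates per depth category.
#'
#' @param object A `lunge_eval` from [evaluate_detections()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lunge_eval
#' @export
autoplot.lunge_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$table, c("tp_rate", "fp_rate"),
    names_to = "rate", values_to = "percent"
  )
  df$rate <- ifelse(df$rate == "tp_rate", "true positive", "false positive")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$percent, fill = .data$rate)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("true positive" = "seagreen", "false positive" = "firebrick")) +
    ggplot2::labs(x = NULL, y = "rate (%)", fill = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal(base_size = 10)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
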