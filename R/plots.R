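#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

key_parts <- c(jaw = 1L, head = 3L, chest = 6L, abdomen = 8L,
               hand_l = 16L, hand_r = 17L, foot_l = 22L, foot_r = 23L)

#' Plot tracked part heights over time
#'
#' Height traces of the behaviorally relevant parts (chest, abdomen, hip
#' midpoint, feet) with the event thresholds overlaid; the standard visual
#' check of a tracked or ground-truth trajectory.
#'
#' @param object A trajectory tibble.
#' @param scene A [scene_geometry()] supplying threshold lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skf_trajectory <- function(object, scene = scene_geometry(), ...) {
  traj <- tibble::as_tibble(object)
  hip <- traj |>
    dplyr::filter(sphere %in% c(9L, 10L)) |>
    dplyr::group_by(frame, time_s) |>
    dplyr::summarise(z = mean(z), .groups = "drop") |>
    dplyr::mutate(part = "hip midpoint")
  parts <- traj |>
    dplyr::filter(sphere %in% c(6L, 8L, 22L, 23L)) |>
    dplyr::transmute(frame, time_s, z, part = label)
  df <- dplyr::bind_rows(parts, hip)
  thr <- tibble::tibble(
    threshold = c("jump (feet)", "crawl (chest)", "crouch (hip)"),
    z = c(scene$jump_foot_min, scene$crawl_chest_max, scene$crouch_hip_max)
  )
  ggplot2::ggplot(df, ggplot2::aes(time_s, 100 * z, color = part)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = 100 * z,
                                     linetype = threshold),
                        color = "grey40") +
    ggplot2::labs(x = "time (s)", y = "height above floor (cm)",
                  color = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Chronogram of detected behavioral events
#'
#' @param object An events tibble (rows from the detectors, possibly several
#'   kinds bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_events <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = onset_s, xend = offset_s, y = kind, yend = kind,
                   color = kind),
      linewidth = 5
    ) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::guides(color = "none") +
    ggplot2::theme_minimal()
}

#' Side and top view of a fitted pose inside its point cloud
#'
#' @param pose A pose tibble (e.g. `fit$pose`).
#' @param model The `skf_model` (for bone segments).
#' @param cloud Optional cloud tibble drawn behind the skeleton (subsampled).
#' @param max_points Cloud points to draw.
#' @return A ggplot object (x-z projection).
#' @export
plot_pose <- function(pose, model, cloud = NULL, max_points = 4000L) {
  segs <- tibble::tibble(
    x = pose$x[match(model$joints$parent, pose$sphere)],
    z = pose$z[match(model$joints$parent, pose$sphere)],
    xend = pose$x[match(model$joints$child, pose$sphere)],
    zend = pose$z[match(model$joints$child, pose$sphere)]
  )
  p <- ggplot2::ggplot()
  if (!is.null(cloud) && nrow(cloud)) {
    idx <- seq(1, nrow(cloud), length.out = min(max_points, nrow(cloud)))
    p <- p + ggplot2::geom_point(
      data = cloud[idx, ], ggplot2::aes(x, z),
      color = "grey70", size = 0.3, alpha = 0.5
    )
  }
  p +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = x, y = z, xend = xend,
                                       yend = zend),
                          color = "steelblue") +
    ggplot2::geom_point(data = pose, ggplot2::aes(x, z), color = "navy",
                        size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "z (m)") +
    ggplot2::theme_minimal()
}
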