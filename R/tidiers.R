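#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a single-frame fit result
#'
#' @param x An `skf_fit` from [fit_frame()].
#' @param ... Unused.
#' @return The fitted pose tibble.
#' @export
tidy.skf_fit <- function(x, ...) x$pose

#' One-row summary of a fit result
#'
#' @inheritParams tidy.skf_fit
#' @return Tibble with `converged`, `iterations`, `final_max_shift_mm`.
#' @export
glance.skf_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 final_max_shift_mm = 1000 * x$final_max_shift)
}

#' Tidy a skeleton model
#'
#' @param x An `skf_model`.
#' @param ... Unused.
#' @return The sphere table joined with each sphere's parent joint data.
#' @export
tidy.skf_model <- function(x, ...) {
  dplyr::left_join(
    x$spheres,
    dplyr::select(x$joints, child, parent, dof, rest_length,
                  bend_min, bend_max),
    by = c("id" = "child")
  )
}

#' One-row summary of a tracked trajectory
#'
#' @param x An `skf_trajectory`.
#' @param ... Unused.
#' @return Tibble with frame counts, duration, convergence fraction and the
#'   number (and percentage) of corrected frames.
#' @export
glance.skf_trajectory <- function(x, ...) {
  frames <- unique(x$frame)
  per_frame <- x[!duplicated(x$frame), ]
  tibble::tibble(
    n_frames = length(frames),
    duration_s = max(x$time_s) - min(x$time_s),
    fps = traj_fps(x),
    fraction_converged = mean(per_frame$converged),
    n_corrected_frames = sum(per_frame$corrected),
    pct_corrected_frames = 100 * mean(per_frame$corrected)
  )
}

#' Tidy an event-list comparison
#'
#' @param x An `skf_event_comparison` from [compare_events()].
#' @param ... Unused.
#' @return The matched-pairs tibble.
#' @export
tidy.skf_event_comparison <- function(x, ...) x$pairs

#' One-row summary of an event-list comparison
#'
#' @inheritParams tidy.skf_event_comparison
#' @return Tibble with matched / unmatched counts and mean absolute timing
#'   differences (s).
#' @export
glance.skf_event_comparison <- function(x, ...) {
  tibble::tibble(
    n_matched = nrow(x$pairs),
    n_unmatched_a = x$n_unmatched_a,
    n_unmatched_b = x$n_unmatched_b,
    mean_d_onset_s = if (nrow(x$pairs)) mean(x$pairs$d_onset_s) else NA_real_,
    mean_d_offset_s = if (nrow(x$pairs)) mean(x$pairs$d_offset_s) else NA_real_,
    mean_d_duration_s = if (nrow(x$pairs)) {
      mean(x$pairs$d_duration_s)
    } else {
      NA_real_
    }
  )
}
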