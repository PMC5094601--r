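new_trajectory <- function(df, fps) {
  tibble::new_tibble(df, fps = fps, class = "skf_trajectory")
}

traj_fps <- function(traj) {
  fps <- attr(traj, "fps")
  if (!is.null(fps)) return(fps)
  tt <- sort(unique(traj$time_s))
  1 / stats::median(diff(tt))
}

# frames x spheres x 3 array, frames ascending, spheres by id
traj_array <- function(traj) {
  traj <- dplyr::arrange(traj, frame, sphere)
  frames <- unique(traj$frame)
  ns <- length(unique(traj$sphere))
  arr <- array(NA_real_, c(length(frames), ns, 3))
  arr[, , 1] <- matrix(traj$x, ncol = ns, byrow = TRUE)
  arr[, , 2] <- matrix(traj$y, ncol = ns, byrow = TRUE)
  arr[, , 3] <- matrix(traj$z, ncol = ns, byrow = TRUE)
  attr(arr, "frames") <- frames
  attr(arr, "times") <- traj$time_s[match(frames, traj$frame)]
  arr
}

normalize_frames <- function(frames) {
  if (inherits(frames, "skf_sequence")) {
    return(list(n = frames$n_frames, times = frames$times,
                fetch = frames$cloud, fps = frames$fps))
  }
  if (is.list(frames) && !is.function(frames) && !is.data.frame(frames)) {
    n <- length(frames)
    if (!n) abort("empty frame sequence")
    fps <- attr(frames, "fps") %||% 26.7
    return(list(n = n, times = (seq_len(n) - 1) / fps,
                fetch = function(i) frames[[i]], fps = fps))
  }
  if (is.function(frames)) {
    n <- attr(frames, "n_frames")
    fps <- attr(frames, "fps") %||% 26.7
    if (is.null(n)) abort("a frame function needs an `n_frames` attribute")
    return(list(n = n, times = (seq_len(n) - 1) / fps, fetch = frames,
                fps = fps))
  }
  abort("`frames` must be an skf_sequence, a list of clouds, or a function")
}

#' Track the skeleton model through a 3D video
#'
#' Sequential semi-automatic pose estimation: frame 1 is fitted from `init`
#' (in practice a pose placed near the hull), and each subsequent frame is
#' initialized from the previous frame's fitted pose. Corrections replace
#' the interactive fix-and-restart workflow reproducibly: at a corrected
#' frame the given sphere positions override the initialization before
#' fitting, and processing continues (restarts) from that frame. An optional
#' `callback(frame, fit)` inspecting each fitted frame may return override
#' positions to the same effect. The returned trajectory is raw
#' (unsmoothed); see [smooth_trajectory()].
#'
#' @param frames An `skf_sequence` from [render_sequence()], a list of cloud
#'   tibbles (attribute `fps` optional), or a `function(i)` returning frame
#'   `i`'s cloud with attributes `n_frames` and `fps`.
#' @param model A `skf_model`.
#' @param init Initial pose tibble for the first frame.
#' @param params A [fit_params()].
#' @param corrections Optional corrections tibble (`frame`, `sphere`, `x`,
#'   `y`, `z`) or path to a corrections JSON file (see
#'   [read_corrections()]).
#' @param callback Optional `function(frame, fit)` returning `NULL` or a
#'   data frame of overrides (`sphere`, `x`, `y`, `z`) for that frame.
#' @return A `skf_trajectory` tibble: one row per sphere per frame with
#'   columns `frame`, `time_s`, `sphere`, `label`, `x`, `y`, `z`,
#'   `converged`, `corrected`.
#' @export
track_sequence <- function(frames, model, init, params = fit_params(),
                           corrections = NULL, callback = NULL) {
  fr <- normalize_frames(frames)
  if (is.character(corrections)) corrections <- read_corrections(corrections)
  if (!is.null(corrections) && nrow(corrections)) {
    if (any(corrections$frame < 1 | corrections$frame > fr$n)) {
      abort("correction frame index outside the video")
    }
  }

  apply_overrides <- function(pose, ov) {
    idx <- match(ov$sphere, pose$sphere)
    pose$x[idx] <- ov$x; pose$y[idx] <- ov$y; pose$z[idx] <- ov$z
    pose
  }

  out <- vector("list", fr$n)
  pose <- init
  for (i in seq_len(fr$n)) {
    cloud <- fr$fetch(i)
    corrected <- FALSE
    if (!is.null(corrections)) {
      ov <- corrections[corrections$frame == i, , drop = FALSE]
      if (nrow(ov)) {
        pose <- apply_overrides(pose, ov)
        corrected <- TRUE
      }
    }
    fit <- fit_frame(cloud, model, pose, params)
    if (!is.null(callback)) {
      ov <- callback(i, fit)
      if (!is.null(ov) && nrow(ov)) {
        fit <- fit_frame(cloud, model, apply_overrides(fit$pose, ov), params)
        corrected <- TRUE
      }
    }
    pose <- fit$pose
    rec <- pose
    rec$time_s <- fr$times[[i]]
    rec$frame <- i
    rec$converged <- fit$converged
    rec$corrected <- corrected
    out[[i]] <- rec
  }
  traj <- dplyr::bind_rows(out)
  new_trajectory(traj[, c("frame", "time_s", "sphere", "label", "x", "y", "z",
                          "converged", "corrected")], fps = fr$fps)
}

# tricube-weighted local quadratic smoother rows for a uniform grid
loess_rows <- function(n, span) {
  h <- (span - 1) %/% 2
  row_for <- function(i) {
    win <- max(1, i - h):min(n, i + h)
    x <- win - i
    dmax <- max(abs(x))
    w <- (1 - (abs(x) / max(dmax, 1))^3)^3
    deg <- min(2, sum(w > 0) - 1)
    X <- outer(x, 0:deg, `^`)
    XtW <- t(X * w)
    coef <- solve(XtW %*% X, XtW)[1, ]
    list(win = win, coef = coef)
  }
  rows <- vector("list", n)
  interior <- NULL
  for (i in seq_len(n)) {
    if (i > h && i <= n - h) {
      if (is.null(interior)) interior <- row_for(i)$coef
      rows[[i]] <- list(win = (i - h):(i + h), coef = interior)
    } else {
      rows[[i]] <- row_for(i)
    }
  }
  rows
}

#' Loess-smooth a trajectory
#'
#' Replaces each sphere-coordinate time series by locally weighted quadratic
#' regression (tricube weights) over a time window, the smoothing
#' conventionally applied to the sphere traces before analysis. The span in
#' samples is `round(window * fps)` forced odd; windows truncate one-sided
#' at the ends of the record. Timestamps are unchanged, and polynomial
#' series of degree two or less pass through unchanged.
#'
#' @param traj A trajectory tibble.
#' @param window Smoothing time window in seconds (default 0.5 s).
#' @return The smoothed trajectory.
#' @export
smooth_trajectory <- function(traj, window = 0.5) {
  fps <- traj_fps(traj)
  arr <- traj_array(traj)
  n <- dim(arr)[1]
  if (n < 2) abort("need at least 2 frames to smooth")
  span <- round(window * fps)
  if (span %% 2 == 0) span <- span + 1
  if (span < 2) {
    warn("smoothing window shorter than 2 samples; returning input unchanged")
    return(traj)
  }
  span <- min(span, if (n %% 2 == 1) n else n - 1)
  rows <- loess_rows(n, span)
  Y <- matrix(arr, nrow = n)  # n x (spheres*3)
  S <- matrix(NA_real_, n, ncol(Y))
  for (i in seq_len(n)) {
    S[i, ] <- rows[[i]]$coef %*% Y[rows[[i]]$win, , drop = FALSE]
  }
  sm <- array(S, dim = dim(arr))
  out <- dplyr::arrange(tibble::as_tibble(traj), frame, sphere)
  ns <- dim(arr)[2]
  out$x <- as.vector(t(sm[, , 1]))
  out$y <- as.vector(t(sm[, , 2]))
  out$z <- as.vector(t(sm[, , 3]))
  new_trajectory(out, fps = fps)
}

#' Estimation differences between two trajectories
#'
#' Per-part framewise Euclidean distance between two estimates of the same
#' video (mean and SD, cm), plus the angular difference of the head
#' direction (head-to-jaw unit vector, degrees). In the abdomen-relative
#' frame each trajectory is first re-expressed with its own abdomen (sphere
#' 8) center as the per-frame origin, which removes whole-body placement
#' differences; head-direction angles are unaffected by the frame choice.
#'
#' @param traj_a,traj_b Trajectory tibbles with identical frame counts.
#' @param frame `"absolute"` (laboratory frame) or `"abdomen"` (relative).
#' @return Tibble with columns `part`, `sphere`, `metric`
#'   (`"position"`/`"head_direction"`), `mean`, `sd`, `unit`.
#' @export
estimation_error <- function(traj_a, traj_b,
                             frame = c("absolute", "abdomen")) {
  frame <- match.arg(frame)
  A <- traj_array(traj_a)
  B <- traj_array(traj_b)
  if (!identical(dim(A), dim(B))) abort("trajectories have different sizes")
  labs <- traj_a$label[match(sort(unique(traj_a$sphere)), traj_a$sphere)]
  ids <- sort(unique(traj_a$sphere))
  if (frame == "abdomen") {
    for (d in 1:3) {
      A[, , d] <- A[, , d] - A[, ids == 8L, d]
      B[, , d] <- B[, , d] - B[, ids == 8L, d]
    }
  }
  D <- sqrt((A[, , 1] - B[, , 1])^2 + (A[, , 2] - B[, , 2])^2 +
              (A[, , 3] - B[, , 3])^2)
  pos <- tibble::tibble(
    part = labs, sphere = ids, metric = "position",
    mean = colMeans(D) * 100, sd = apply(D, 2, stats::sd) * 100,
    unit = "cm"
  )
  dirs <- function(X) {
    d <- cbind(X[, ids == 1L, 1] - X[, ids == 3L, 1],
               X[, ids == 1L, 2] - X[, ids == 3L, 2],
               X[, ids == 1L, 3] - X[, ids == 3L, 3])
    d / pmax(sqrt(rowSums(d^2)), 1e-12)
  }
  ang <- rad2deg(acos(pmin(1, pmax(-1, rowSums(dirs(A) * dirs(B))))))
  hd <- tibble::tibble(part = "head_direction", sphere = NA_integer_,
                       metric = "head_direction", mean = mean(ang),
                       sd = stats::sd(ang), unit = "deg")
  dplyr::bind_rows(pos, hd)
}

#' Trajectory CSV input/output
#'
#' One row per sphere per frame with columns `frame`, `time_s`, `sphere_id`,
#' `x_m`, `y_m`, `z_m`, `converged`, `corrected` (and `label`).
#'
#' @param traj A trajectory tibble.
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a trajectory tibble.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(
    frame = traj$frame, time_s = traj$time_s, sphere_id = traj$sphere,
    label = traj$label, x_m = traj$x, y_m = traj$y, z_m = traj$z,
    converged = traj$converged, corrected = traj$corrected
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  traj <- tibble::tibble(
    frame = as.integer(df$frame), time_s = df$time_s,
    sphere = as.integer(df$sphere_id), label = as.character(df$label),
    x = df$x_m, y = df$y_m, z = df$z_m,
    converged = as.logical(df$converged), corrected = as.logical(df$corrected)
  )
  fps <- 1 / stats::median(diff(sort(unique(traj$time_s))))
  new_trajectory(traj, fps = fps)
}

#' Corrections JSON input/output
#'
#' Corrections are stored as a JSON array of objects
#' `{"frame": k, "spheres": {"16": [x, y, z], ...}}` (world metres) and
#' handled in R as a tibble with columns `frame`, `sphere`, `x`, `y`, `z`.
#'
#' @param corrections Corrections tibble.
#' @param path JSON file path.
#' @return `write_corrections` returns `path` invisibly; `read_corrections`
#'   the tibble form.
#' @export
write_corrections <- function(corrections, path) {
  by_frame <- split(corrections, corrections$frame)
  obj <- purrr::map(by_frame, function(g) {
    list(frame = g$frame[[1]],
         spheres = setNames(purrr::pmap(g[, c("x", "y", "z")], c),
                            as.character(g$sphere)))
  })
  jsonlite::write_json(unname(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_corrections
#' @export
read_corrections <- function(path) {
  obj <- jsonlite::read_json(path)
  purrr::map_dfr(obj, function(o) {
    tibble::tibble(
      frame = as.integer(o$frame),
      sphere = as.integer(names(o$spheres)),
      x = unname(purrr::map_dbl(o$spheres, 1)),
      y = unname(purrr::map_dbl(o$spheres, 2)),
      z = unname(purrr::map_dbl(o$spheres, 3))
    )
  })
}
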