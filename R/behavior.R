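#' Scene geometry and behavioral thresholds
#'
#' World-frame description of the cage used by the event detectors: the
#' floor height, the obstacle bar (a horizontal line given by a point and an
#' axis direction), the travel axis of the shuttling task, and the
#' behavioral thresholds. The defaults are the published event definitions:
#' jumping = both feet more than 20 cm above the floor; crawling = chest
#' lower than 20 cm with the chest at most 10 cm above the abdomen;
#' crouching = hip midpoint lower than 9 cm with chest speed below 8 cm/s.
#'
#' @param floor_z Floor height (m).
#' @param bar_point A point on the bar axis (m).
#' @param bar_axis Direction of the bar (horizontal unit vector).
#' @param travel_axis Direction of travel in the shuttling task.
#' @param jump_foot_min Foot height defining jumping (m).
#' @param crawl_chest_max Chest height defining crawling (m).
#' @param crawl_diff_max Max chest-minus-abdomen height while crawling (m).
#' @param crouch_hip_max Hip-midpoint height defining crouching (m).
#' @param crouch_speed_max Chest speed below which a low posture counts as
#'   crouching rather than low locomotion (m/s).
#' @param min_gap Optional merge window (s): consecutive same-kind events
#'   separated by less than this are merged (0 = off, the default; no
#'   debouncing is part of the published definitions).
#' @param cross_hysteresis Hysteresis half-band (m) for plane-crossing
#'   detection: a crossing only counts once the part has been confirmed at
#'   least this far on each side, which keeps tracking noise around the bar
#'   plane from registering as spurious crossings.
#' @return A `skf_scene` list.
#' @export
scene_geometry <- function(floor_z = 0, bar_point = c(0, 0, 0.35),
                           bar_axis = c(0, 1, 0), travel_axis = c(1, 0, 0),
                           jump_foot_min = 0.20, crawl_chest_max = 0.20,
                           crawl_diff_max = 0.10, crouch_hip_max = 0.09,
                           crouch_speed_max = 0.08, min_gap = 0,
                           cross_hysteresis = 0.02) {
  stopifnot(jump_foot_min > 0, crawl_chest_max > 0, crawl_diff_max > 0,
            crouch_hip_max > 0, crouch_speed_max > 0, min_gap >= 0,
            cross_hysteresis >= 0)
  structure(
    list(floor_z = floor_z, bar_point = as.numeric(bar_point),
         bar_axis = unitize(as.numeric(bar_axis)),
         travel_axis = unitize(as.numeric(travel_axis)),
         jump_foot_min = jump_foot_min, crawl_chest_max = crawl_chest_max,
         crawl_diff_max = crawl_diff_max, crouch_hip_max = crouch_hip_max,
         crouch_speed_max = crouch_speed_max, min_gap = min_gap,
         cross_hysteresis = cross_hysteresis),
    class = "skf_scene"
  )
}

part_series <- function(traj, sphere) {
  arr <- traj_array(traj)
  ids <- sort(unique(traj$sphere))
  m <- arr[, ids == sphere, , drop = FALSE]
  matrix(m, nrow = dim(arr)[1], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

traj_times <- function(traj) {
  traj <- dplyr::arrange(traj, frame)
  traj$time_s[match(sort(unique(traj$frame)), traj$frame)]
}

# central differences with one-sided endpoints; rows of P, times t
diff_speed <- function(P, t) {
  n <- nrow(P)
  if (n < 2) return(rep(NA_real_, n))
  V <- matrix(NA_real_, n, ncol(P))
  V[1, ] <- (P[2, ] - P[1, ]) / (t[2] - t[1])
  V[n, ] <- (P[n, ] - P[n - 1, ]) / (t[n] - t[n - 1])
  if (n > 2) {
    idx <- 2:(n - 1)
    V[idx, ] <- (P[idx + 1, , drop = FALSE] - P[idx - 1, , drop = FALSE]) /
      (t[idx + 1] - t[idx - 1])
  }
  sqrt(rowSums(V^2))
}

events_tibble <- function(onsets, offsets, times, kind) {
  tibble::tibble(
    kind = kind,
    onset_frame = onsets, offset_frame = offsets,
    onset_s = times[onsets], offset_s = times[offsets],
    duration_s = times[offsets] - times[onsets]
  )
}

events_from_mask <- function(mask, times, kind, min_gap = 0) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  if (min_gap > 0 && length(on) > 1) {
    keep_on <- on[1]; keep_off <- off[1]
    for (i in 2:length(on)) {
      if (times[on[i]] - times[keep_off[length(keep_off)]] < min_gap) {
        keep_off[length(keep_off)] <- off[i]
      } else {
        keep_on <- c(keep_on, on[i]); keep_off <- c(keep_off, off[i])
      }
    }
    on <- keep_on; off <- keep_off
  }
  events_tibble(on, off, times, kind)
}

#' Detect jumping events
#'
#' Maximal intervals during which both feet (spheres 22 and 23) are more
#' than `jump_foot_min` above the floor, i.e. neither foot touches it.
#'
#' @param traj A trajectory tibble (typically smoothed).
#' @param scene A [scene_geometry()].
#' @return Events tibble: `kind`, `onset_frame`, `offset_frame`, `onset_s`,
#'   `offset_s`, `duration_s`.
#' @export
detect_jumping <- function(traj, scene = scene_geometry()) {
  t <- traj_times(traj)
  fl <- part_series(traj, 22L)[, 3] - scene$floor_z
  fr <- part_series(traj, 23L)[, 3] - scene$floor_z
  events_from_mask(fl > scene$jump_foot_min & fr > scene$jump_foot_min,
                   t, "jumping", scene$min_gap)
}

#' Detect crawling events
#'
#' Maximal intervals during which the chest (sphere 6) is lower than
#' `crawl_chest_max` above the floor and at most `crawl_diff_max` higher
#' than the abdomen (sphere 8).
#'
#' @inheritParams detect_jumping
#' @return Events tibble, see [detect_jumping()].
#' @export
detect_crawling <- function(traj, scene = scene_geometry()) {
  t <- traj_times(traj)
  chest <- part_series(traj, 6L)[, 3] - scene$floor_z
  abd <- part_series(traj, 8L)[, 3] - scene$floor_z
  events_from_mask(chest < scene$crawl_chest_max &
                     (chest - abd) < scene$crawl_diff_max,
                   t, "crawling", scene$min_gap)
}

#' Detect bar-crossing events
#'
#' A crossing is operationalized on the vertical plane containing the bar
#' axis. Each traversal is anchored by the chest crossing that plane; the
#' event is bounded by the first crossing of that plane by either hand
#' (spheres 16/17) and the last crossing by either foot (spheres 22/23) in
#' the traversal direction (in forward locomotion the hands lead, so the
#' hand instant is the onset). Posture is irrelevant: passing between bars
#' still counts. Crossings use a small hysteresis band
#' (`scene$cross_hysteresis`) so estimation noise at the plane does not
#' register as extra crossings.
#'
#' @inheritParams detect_jumping
#' @return Events tibble, see [detect_jumping()].
#' @export
detect_bar_crossing <- function(traj, scene = scene_geometry()) {
  t <- traj_times(traj)
  nrm <- scene$travel_axis -
    sum(scene$travel_axis * scene$bar_axis) * scene$bar_axis
  nrm[3] <- 0
  if (vnorm(nrm) < 1e-9) abort("travel axis is parallel to the bar axis")
  nrm <- unitize(nrm)
  sdist <- function(sphere) {
    P <- part_series(traj, sphere)
    (P[, 1] - scene$bar_point[1]) * nrm[1] +
      (P[, 2] - scene$bar_point[2]) * nrm[2]
  }
  # confirmed plane crossings: the part must reach at least +/- hysteresis on
  # each side; the instant is the first sign flip after leaving the old side
  crossings <- function(s) {
    delta <- scene$cross_hysteresis
    conf <- ifelse(s >= delta, 1L, ifelse(s <= -delta, -1L, 0L))
    idx <- which(conf != 0L)
    if (length(idx) < 2) {
      return(tibble::tibble(frame = integer(), dir = integer()))
    }
    st <- conf[idx]
    chg <- which(st[-1] != st[-length(st)])
    frames <- integer(0); dirs <- integer(0)
    for (kk in chg) {
      a <- idx[kk]          # last frame confirmed on the old side
      b <- idx[kk + 1]      # first frame confirmed on the new side
      d <- st[kk + 1]
      seg <- a:b
      f <- seg[which(sign(s[seg]) == d | s[seg] == 0)[1]]
      frames <- c(frames, f); dirs <- c(dirs, d)
    }
    tibble::tibble(frame = frames, dir = dirs)
  }
  chest <- crossings(sdist(6L))
  if (!nrow(chest)) {
    return(events_tibble(integer(), integer(), t, "bar_crossing"))
  }
  hands <- dplyr::bind_rows(crossings(sdist(16L)), crossings(sdist(17L)))
  feet <- dplyr::bind_rows(crossings(sdist(22L)), crossings(sdist(23L)))
  n_fr <- length(t)
  bounds <- c(0L, chest$frame, n_fr + 1L)
  out <- purrr::map_dfr(seq_len(nrow(chest)), function(k) {
    lo <- bounds[k]; hi <- bounds[k + 2]
    d <- chest$dir[k]
    hk <- hands$frame[hands$dir == d & hands$frame > lo & hands$frame < hi]
    fk <- feet$frame[feet$dir == d & feet$frame > lo & feet$frame < hi]
    if (!length(hk) || !length(fk)) return(NULL)
    hand_instant <- min(hk)
    foot_instant <- max(fk)
    tibble::tibble(on = min(hand_instant, foot_instant),
                   off = max(hand_instant, foot_instant))
  })
  if (is.null(out) || !nrow(out)) {
    return(events_tibble(integer(), integer(), t, "bar_crossing"))
  }
  events_tibble(out$on, out$off, t, "bar_crossing")
}

#' Per-frame crouching state
#'
#' Crouching is a low static posture: hip midpoint (mean of spheres 9 and
#' 10) lower than `crouch_hip_max` above the floor while the chest moves
#' slower than `crouch_speed_max` (the speed gate removes locomotion in a
#' low posture). Chest speed comes from central differences on the supplied
#' (normally smoothed) trajectory.
#'
#' @inheritParams detect_jumping
#' @return Tibble with `frame`, `time_s`, `hip_height_m`, `chest_speed_m_s`,
#'   `crouching`.
#' @export
crouch_mask <- function(traj, scene = scene_geometry()) {
  t <- traj_times(traj)
  hip <- (part_series(traj, 9L)[, 3] + part_series(traj, 10L)[, 3]) / 2 -
    scene$floor_z
  speed <- diff_speed(part_series(traj, 6L), t)
  tibble::tibble(
    frame = seq_along(t), time_s = t, hip_height_m = hip,
    chest_speed_m_s = speed,
    crouching = hip < scene$crouch_hip_max & speed < scene$crouch_speed_max
  )
}

#' Kinematic summary of a trajectory
#'
#' The three motor-activity parameters: total path length of the chest
#' trace over the whole record; mean walking speed (chest speed averaged
#' over standing frames, standing meaning the hip midpoint is at or above
#' the crouch threshold); and mean head-rotation speed (the speed of the
#' jaw relative to the head, averaged over crouching frames, where head
#' motion is not dominated by locomotion). Speeds use central differences
#' on the supplied trajectory, which should normally be loess-smoothed
#' first. Quantities whose qualifying frame set is empty are reported as
#' `NA`, not zero.
#'
#' @inheritParams detect_jumping
#' @return One-row tibble: `total_path_length_cm`, `mean_walking_speed_cm_s`,
#'   `mean_walking_speed_cm_min`, `mean_head_rotation_speed_cm_s`,
#'   `mean_head_rotation_speed_cm_min`, `n_frames`, `n_standing_frames`,
#'   `n_crouching_frames`, `duration_s`.
#' @export
kinematic_summary <- function(traj, scene = scene_geometry()) {
  t <- traj_times(traj)
  chest <- part_series(traj, 6L)
  path_cm <- 100 * sum(sqrt(rowSums(diff(chest)^2)))
  cm <- crouch_mask(traj, scene)
  standing <- cm$hip_height_m >= scene$crouch_hip_max
  chest_speed <- cm$chest_speed_m_s
  walk_cm_s <- if (any(standing)) {
    100 * mean(chest_speed[standing])
  } else {
    NA_real_
  }
  rel <- part_series(traj, 1L) - part_series(traj, 3L)
  rel_speed <- diff_speed(rel, t)
  rot_cm_s <- if (any(cm$crouching)) {
    100 * mean(rel_speed[cm$crouching])
  } else {
    NA_real_
  }
  tibble::tibble(
    total_path_length_cm = path_cm,
    mean_walking_speed_cm_s = walk_cm_s,
    mean_walking_speed_cm_min = walk_cm_s * 60,
    mean_head_rotation_speed_cm_s = rot_cm_s,
    mean_head_rotation_speed_cm_min = rot_cm_s * 60,
    n_frames = length(t),
    n_standing_frames = sum(standing),
    n_crouching_frames = sum(cm$crouching),
    duration_s = t[length(t)] - t[1]
  )
}

#' Compare two event lists
#'
#' Greedy matching by temporal overlap (largest overlap first, each event
#' used once), yielding per-pair absolute onset/offset/duration differences
#' and the unmatched counts on each side (false positives/negatives when
#' one side is ground truth).
#'
#' @param events_a,events_b Events tibbles of the same kind.
#' @return A `skf_event_comparison`: list with `pairs` (tibble of matched
#'   pairs and absolute timing differences in seconds), `n_unmatched_a`,
#'   `n_unmatched_b`.
#' @export
compare_events <- function(events_a, events_b) {
  na <- nrow(events_a); nb <- nrow(events_b)
  pairs <- tibble::tibble(
    a = integer(), b = integer(), overlap_s = numeric(),
    d_onset_s = numeric(), d_offset_s = numeric(), d_duration_s = numeric()
  )
  if (na && nb) {
    ov <- outer(seq_len(na), seq_len(nb), function(i, j) {
      pmax(0, pmin(events_a$offset_s[i], events_b$offset_s[j]) -
             pmax(events_a$onset_s[i], events_b$onset_s[j]))
    })
    # zero-length events can only "touch": require interval contact at all
    touch <- outer(seq_len(na), seq_len(nb), function(i, j) {
      events_a$onset_s[i] <= events_b$offset_s[j] &
        events_b$onset_s[j] <= events_a$offset_s[i]
    })
    ov[!touch] <- -1
    used_a <- logical(na); used_b <- logical(nb)
    repeat {
      ov[used_a, ] <- -1; ov[, used_b] <- -1
      if (max(ov) < 0) break
      m <- which(ov == max(ov), arr.ind = TRUE)
      i <- m[1, 1]; j <- m[1, 2]
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        a = i, b = j, overlap_s = ov[i, j],
        d_onset_s = abs(events_a$onset_s[i] - events_b$onset_s[j]),
        d_offset_s = abs(events_a$offset_s[i] - events_b$offset_s[j]),
        d_duration_s = abs(events_a$duration_s[i] - events_b$duration_s[j])
      ))
      used_a[i] <- TRUE; used_b[j] <- TRUE
      if (all(used_a) || all(used_b)) break
    }
  }
  structure(
    list(pairs = pairs,
         n_unmatched_a = na - nrow(pairs),
         n_unmatched_b = nb - nrow(pairs)),
    class = "skf_event_comparison"
  )
}

#' @export
print.skf_event_comparison <- function(x, ...) {
  cat(sprintf("<skf_event_comparison> %d matched pairs, %d / %d unmatched\n",
              nrow(x$pairs), x$n_unmatched_a, x$n_unmatched_b))
  if (nrow(x$pairs)) {
    cat(sprintf("  mean |d onset| %.1f ms, |d offset| %.1f ms, |d duration| %.1f ms\n",
                1000 * mean(x$pairs$d_onset_s),
                1000 * mean(x$pairs$d_offset_s),
                1000 * mean(x$pairs$d_duration_s)))
  }
  invisible(x)
}
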