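#' Default four-camera rig around the recording cage
#'
#' Emulates the physical setup: depth cameras at the 3, 6, 9 and 12 o'clock
#' bearings around the cage center, alternating 1.6 m and 1.9 m from the
#' center, mounted 1.1 m above the floor and tilted 10 degrees below the
#' horizontal. Intrinsics approximate a consumer depth camera scaled to the
#' requested resolution.
#'
#' @param width,height Image resolution in pixels (default 320 x 240 for
#'   speed; 640 x 480 matches the physical sensor).
#' @param distances Distance of each camera from the cage center (m), in
#'   bearing order 3, 6, 9, 12 o'clock.
#' @param cam_height Mounting height above the floor (m).
#' @param tilt_deg Downward tilt from the horizontal (degrees).
#' @return List of four [camera_model()]s.
#' @export
default_cameras <- function(width = 320L, height = 240L,
                            distances = c(1.6, 1.9, 1.6, 1.9),
                            cam_height = 1.1, tilt_deg = 10) {
  stopifnot(length(distances) == 4)
  bearings <- list(c(1, 0), c(0, -1), c(-1, 0), c(0, 1))  # 3, 6, 9, 12 o'clock
  f <- 292.5 * width / 320
  tilt <- deg2rad(tilt_deg)
  purrr::imap(bearings, function(b, i) {
    d <- distances[[i]]
    pos <- c(d * b[1], d * b[2], cam_height)
    fh <- c(-b[1], -b[2], 0)
    fwd <- cos(tilt) * fh + sin(tilt) * c(0, 0, -1)
    xc <- unitize(cross3(fwd, c(0, 0, 1)))
    yc <- cross3(fwd, xc)
    camera_model(
      id = i, width = width, height = height, fx = f, fy = f,
      cx = (width - 1) / 2, cy = (height - 1) / 2,
      rotation = cbind(xc, yc, fwd), translation = pos
    )
  })
}

#' Articulated phantom: a renderable surface around the skeleton
#'
#' The phantom surface is the union of the 23 model spheres and one capsule
#' per bone (radius a fraction of the smaller endpoint sphere), which is
#' watertight enough for ray casting. The face region - the jaw sphere and
#' the head-jaw capsule - is painted red; the rest of the body is a dull
#' brown that fails the red HSV gate. Fur and surface roughness are emulated
#' only as per-pixel depth noise at render time.
#'
#' @param model A `skf_model`.
#' @param capsule_shrink Capsule radius as a fraction of the smaller
#'   endpoint sphere radius.
#' @param face_rgb,body_rgb Length-3 RGB in `[0, 1]`.
#' @return A `skf_phantom` object.
#' @export
skf_phantom <- function(model, capsule_shrink = 0.9,
                        face_rgb = c(0.80, 0.10, 0.15),
                        body_rgb = c(0.45, 0.35, 0.28)) {
  stopifnot(inherits(model, "skf_model"))
  structure(
    list(model = model, capsule_shrink = capsule_shrink,
         face_rgb = face_rgb, body_rgb = body_rgb),
    class = "skf_phantom"
  )
}

# sphere + capsule primitive table for a posed phantom; `face` flags the
# painted primitives (jaw sphere, head-jaw capsule)
phantom_primitives <- function(phantom, pose) {
  model <- phantom$model
  C <- pose_matrix(pose)
  jts <- model$joints
  rad <- model$spheres$radius
  cap_r <- phantom$capsule_shrink * pmin(rad[jts$parent], rad[jts$child])
  list(
    sph_c = C, sph_r = rad,
    cap_a = C[jts$parent, , drop = FALSE],
    cap_b = C[jts$child, , drop = FALSE],
    cap_r = cap_r,
    sph_face = model$spheres$id == 1L,
    cap_face = jts$parent == 3L & jts$child == 1L
  )
}

#' Unsigned distance from points to a posed phantom's surface
#'
#' Analytic oracle used to verify renders and back-projection: the minimum
#' over all surface primitives of the absolute distance to the primitive's
#' surface.
#'
#' @param phantom A [skf_phantom()].
#' @param pose Pose tibble.
#' @param P `n x 3` matrix of world points.
#' @return Numeric vector of distances (m).
#' @export
phantom_surface_distance <- function(phantom, pose, P) {
  pr <- phantom_primitives(phantom, pose)
  n <- nrow(P)
  best <- rep(Inf, n)
  for (i in seq_along(pr$sph_r)) {
    d <- sqrt((P[, 1] - pr$sph_c[i, 1])^2 + (P[, 2] - pr$sph_c[i, 2])^2 +
                (P[, 3] - pr$sph_c[i, 3])^2)
    best <- pmin(best, abs(d - pr$sph_r[i]))
  }
  for (i in seq_along(pr$cap_r)) {
    a <- pr$cap_a[i, ]; b <- pr$cap_b[i, ]
    ab <- b - a
    L2 <- sum(ab^2)
    tpar <- ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
               (P[, 3] - a[3]) * ab[3]) / L2
    tpar <- pmin(pmax(tpar, 0), 1)
    d <- sqrt((P[, 1] - a[1] - tpar * ab[1])^2 +
                (P[, 2] - a[2] - tpar * ab[2])^2 +
                (P[, 3] - a[3] - tpar * ab[3])^2)
    best <- pmin(best, abs(d - pr$cap_r[i]))
  }
  best
}

#' Render one virtual depth + color view of a posed phantom
#'
#' Z-buffer ray cast of the phantom surface through the camera's pixel grid.
#' Depth is the camera-axis distance in millimetres with i.i.d. Gaussian
#' noise added per valid pixel and values rounded to integer mm (0 = miss /
#' background, as from a real sensor). The color image is flat-shaded with
#' the phantom paint and registered to the depth grid.
#'
#' @param phantom A [skf_phantom()].
#' @param pose Pose tibble.
#' @param camera A [camera_model()].
#' @param noise_sd_mm Depth noise standard deviation (mm).
#' @return List with `depth` (height x width integer mm matrix), `color`
#'   (height x width x 3 array in `[0,1]`), and `label` (0 background,
#'   1 body, 2 face).
#' @export
render_view <- function(phantom, pose, camera, noise_sd_mm = 5) {
  pr <- phantom_primitives(phantom, pose)
  w <- camera$width; h <- camera$height
  u <- rep(0:(w - 1), each = h)
  v <- rep(0:(h - 1), times = w)
  dirs_cam <- cbind((u - camera$cx) / camera$fx, (v - camera$cy) / camera$fy, 1)
  dirs <- dirs_cam %*% t(camera$rotation)
  hit <- cpp_raycast(camera$translation, dirs, pr$sph_c, pr$sph_r,
                     pr$cap_a, pr$cap_b, pr$cap_r)
  ns <- length(pr$sph_r)
  face_prim <- c(pr$sph_face, pr$cap_face)

  depth_mm <- numeric(length(u))
  ok <- is.finite(hit$t)
  depth_mm[ok] <- hit$t[ok] * 1000
  if (noise_sd_mm > 0 && any(ok)) {
    depth_mm[ok] <- depth_mm[ok] + stats::rnorm(sum(ok), 0, noise_sd_mm)
  }
  depth_mm[ok] <- pmin(pmax(round(depth_mm[ok]), 1), 65535)
  depth <- matrix(depth_mm, nrow = h, ncol = w)

  lab <- integer(length(u))
  lab[ok] <- ifelse(face_prim[hit$prim[ok]], 2L, 1L)
  label <- matrix(lab, nrow = h, ncol = w)

  color <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    pl <- matrix(0, h, w)
    pl[label == 1L] <- phantom$body_rgb[ch]
    pl[label == 2L] <- phantom$face_rgb[ch]
    color[, , ch] <- pl
  }
  list(depth = depth, color = color, label = label)
}

## ---- motion scripts -------------------------------------------------------

seg <- function(kind, duration, ...) {
  stopifnot(duration > 0)
  structure(list(kind = kind, duration = duration, params = list(...)),
            class = "skf_segment")
}

#' Motion-script segments
#'
#' Timed posture primitives chained by [motion_script()]: quadrupedal
#' standing, walking at constant speed (sinusoidal limb swing), a ballistic
#' jump carrying both feet above the jump threshold, crawling in a lowered
#' posture, and crouching with a sinusoidal head sweep. `direction` is the
#' sign of travel along the x axis (the phantom always faces +x; return
#' traversals are walked backwards).
#'
#' @param duration Segment duration (s).
#' @param speed Travel speed (m/s).
#' @param direction +1 or -1 along the x axis.
#' @param distance Horizontal distance covered by the jump (m).
#' @param height Apex lift of the feet during the jump (m).
#' @param sweep_amp_deg,sweep_freq Amplitude (degrees) and frequency (Hz) of
#'   the head sweep while crouching.
#' @return A `skf_segment`.
#' @name segments
NULL

#' @rdname segments
#' @export
seg_stand <- function(duration = 1) seg("stand", duration)

#' @rdname segments
#' @export
seg_walk <- function(duration, speed = 0.3, direction = 1) {
  seg("walk", duration, speed = speed, direction = sign(direction))
}

#' @rdname segments
#' @export
seg_jump <- function(duration = 0.9, distance = 1.2, height = 0.25,
                     direction = 1) {
  seg("jump", duration, distance = distance, height = height,
      direction = sign(direction))
}

#' @rdname segments
#' @export
seg_crawl <- function(duration, speed = 0.25, direction = 1) {
  seg("crawl", duration, speed = speed, direction = sign(direction))
}

#' @rdname segments
#' @export
seg_crouch <- function(duration = 3, sweep_amp_deg = 60, sweep_freq = 0.5) {
  seg("crouch", duration, sweep_amp_deg = sweep_amp_deg,
      sweep_freq = sweep_freq)
}

#' Assemble a motion script
#'
#' Chains segments into a deterministic, continuous whole-body motion plan.
#' Posture parameters are blended linearly over `blend` seconds at each
#' segment boundary so heights and limb targets are continuous. Frames are
#' sampled at `t = 0, 1/fps, ...`; a script of duration `T` yields
#' `floor(T * fps) + 1` frames.
#'
#' @param segments List of segments from [seg_stand()] and friends.
#' @param fps Frame rate (frames/s).
#' @param start_x Body (abdomen) x position at t = 0 (m).
#' @param blend Posture blend time at segment boundaries (s).
#' @return A `skf_script`.
#' @export
motion_script <- function(segments, fps = 26.7, start_x = -1.5, blend = 0.3) {
  stopifnot(length(segments) >= 1,
            all(purrr::map_lgl(segments, inherits, "skf_segment")))
  t0 <- 0; x0 <- start_x
  rows <- purrr::map(segments, function(sg) {
    p <- sg$params
    dx <- switch(sg$kind,
                 walk = , crawl = p$direction * p$speed * sg$duration,
                 jump = p$direction * p$distance,
                 0)
    r <- tibble::tibble(kind = sg$kind, duration = sg$duration, t0 = t0,
                        x0 = x0, params = list(p))
    t0 <<- t0 + sg$duration
    x0 <<- x0 + dx
    r
  })
  structure(
    list(segments = dplyr::bind_rows(rows), fps = fps, blend = blend,
         duration = t0, n_frames = floor(t0 * fps) + 1L),
    class = "skf_script"
  )
}

#' Canonical shuttling script: walk, jump the bar, walk, crawl back, crouch
#'
#' A single shuttling cycle inside the camera ring emulating the obstacle
#' task: the phantom stands, walks up to the bar, jumps it, walks on, crawls
#' back under it, and ends crouching with a head sweep. With the default
#' frame rate this gives 301 frames (11.25 s).
#'
#' @param n_cycles Number of shuttling cycles (>= 1).
#' @param fps Frame rate.
#' @return A [motion_script()].
#' @export
script_shuttle <- function(n_cycles = 1, fps = 26.7) {
  cycle <- list(seg_stand(0.85), seg_walk(1.6, 0.3), seg_jump(0.8, 0.72, 0.25),
                seg_walk(1.0, 0.3), seg_crawl(5.0, 0.3, -1), seg_crouch(2.0))
  motion_script(rep(cycle, n_cycles), fps = fps, start_x = -0.75)
}

#' @export
print.skf_script <- function(x, ...) {
  cat(sprintf("<skf_script> %.1f s, %d frames at %.1f fps: %s\n",
              x$duration, x$n_frames, x$fps,
              paste(x$segments$kind, collapse = " > ")))
  invisible(x)
}

# posture parameter set for one segment kind at local time tau
stance_params <- function(kind, params, tau, duration) {
  base <- list(
    z_abd = 0.30, z_chest = 0.33, z_pelvis = 0.29, hip_drop = 0.02,
    neck_pitch = 30, head_pitch = 42, jaw_pitch = -30, head_yaw = 0,
    hand_dx = 0.30, hand_dy = 0.09, hand_z = 0.025,
    foot_dx = -0.11, foot_dy = 0.075, foot_z = 0.03,
    stride_amp = 0, stride_lift = 0, stride_freq = 1.3,
    bump = 0, hand_bump = 0, foot_bump = 0
  )
  tprim <- tau / duration
  bump4 <- 4 * tprim * (1 - tprim)
  switch(kind,
    stand = base,
    walk = utils::modifyList(base, list(
      stride_amp = 0.06, stride_lift = 0.04,
      stride_freq = max(0.9, params$speed / 0.23)
    )),
    jump = utils::modifyList(base, list(
      hand_dx = 0.28, foot_dx = -0.10,
      bump = 0.6 * params$height * bump4,
      hand_bump = 0.88 * params$height * bump4 + 0.005,
      foot_bump = params$height * bump4 + 0.005
    )),
    crawl = utils::modifyList(base, list(
      z_abd = 0.13, z_chest = 0.15, z_pelvis = 0.125, hip_drop = 0.005,
      neck_pitch = 10, head_pitch = 35, jaw_pitch = -25,
      hand_dx = 0.32, foot_dx = -0.20, foot_dy = 0.10,
      stride_amp = 0.05, stride_lift = 0.03,
      stride_freq = max(0.9, params$speed / 0.23)
    )),
    crouch = utils::modifyList(base, list(
      z_abd = 0.10, z_chest = 0.23, z_pelvis = 0.085, hip_drop = 0.035,
      neck_pitch = 35, head_pitch = 50, jaw_pitch = -35,
      head_yaw = params$sweep_amp_deg *
        sin(2 * pi * params$sweep_freq * tau),
      hand_dx = 0.28, foot_dx = -0.18, foot_dy = 0.13
    )),
    stopf("unknown segment kind '%s'", kind)
  )
}

mix_stance <- function(a, b, w) {
  purrr::map2(a, b, function(x, y) (1 - w) * x + w * y)
}

segment_at <- function(script, t) {
  segs <- script$segments
  k <- findInterval(t, segs$t0, rightmost.closed = FALSE)
  k <- min(max(k, 1L), nrow(segs))
  k
}

# body x position and stance at absolute script time t (with blending)
script_state <- function(script, t) {
  segs <- script$segments
  k <- segment_at(script, t)
  srow <- segs[k, ]
  p <- srow$params[[1]]
  tau <- min(max(t - srow$t0, 0), srow$duration)
  x <- srow$x0 + switch(srow$kind,
                        walk = , crawl = p$direction * p$speed * tau,
                        jump = p$direction * p$distance * tau / srow$duration,
                        0)
  st <- stance_params(srow$kind, p, tau, srow$duration)
  bl <- min(script$blend, srow$duration / 2)
  if (k > 1 && tau < bl) {
    prow <- segs[k - 1, ]
    prev <- stance_params(prow$kind, prow$params[[1]], prow$duration,
                          prow$duration)
    st <- mix_stance(prev, st, tau / bl)
  }
  list(x = x, stance = st, kind = srow$kind)
}

solve_2link <- function(base, target, L1, L2, bend_dir) {
  d <- target - base
  dist <- vnorm(d)
  lo <- abs(L1 - L2) + 1e-4
  hi <- L1 + L2 - 1e-4
  dist_c <- min(max(dist, lo), hi)
  dhat <- d / max(dist, 1e-12)
  target <- base + dhat * dist_c
  a <- (L1^2 - L2^2 + dist_c^2) / (2 * dist_c)
  hh <- sqrt(max(L1^2 - a^2, 0))
  w <- bend_dir - sum(bend_dir * dhat) * dhat
  if (vnorm(w) < 1e-9) {
    w <- cross3(dhat, c(0, 0, 1))
    if (vnorm(w) < 1e-9) w <- cross3(dhat, c(0, 1, 0))
  }
  w <- w / vnorm(w)
  list(mid = base + a * dhat + hh * w, end = target)
}

pitch_dir <- function(pitch_deg, yaw_deg = 0) {
  p <- deg2rad(pitch_deg); yw <- deg2rad(yaw_deg)
  c(cos(p) * cos(yw), cos(p) * sin(yw), sin(p))
}

joint_len <- function(model, parent, child) {
  jts <- model$joints
  jts$rest_length[jts$parent == parent & jts$child == child]
}

# world-space pose construction from a stance parameter set
build_stance_pose <- function(model, x, st, t, time = NA_real_) {
  L <- function(p, c) joint_len(model, p, c)
  C <- matrix(NA_real_, 23, 3)
  bump <- st$bump

  abd <- c(x, 0, st$z_abd + bump)
  lax <- L(8, 7) + L(7, 6)
  pt <- asin(min(max((st$z_chest - st$z_abd) / lax, -0.99), 0.99))
  axd <- c(cos(pt), 0, sin(pt))
  spine <- abd + L(8, 7) * axd
  chest <- spine + L(7, 6) * axd
  p2 <- asin(min(max((st$z_pelvis - st$z_abd) / L(8, 11), -0.99), 0.99))
  pelvis <- abd + L(8, 11) * c(-cos(p2), 0, sin(p2))
  C[8, ] <- abd; C[7, ] <- spine; C[6, ] <- chest; C[11, ] <- pelvis

  neck <- chest + L(6, 2) * pitch_dir(st$neck_pitch, st$head_yaw / 2)
  head <- neck + L(2, 3) * pitch_dir(st$head_pitch, st$head_yaw * 0.75)
  jaw <- head + L(3, 1) * pitch_dir(st$jaw_pitch, st$head_yaw)
  C[2, ] <- neck; C[3, ] <- head; C[1, ] <- jaw

  tb_dir <- unitize(unitize(pelvis - abd) + c(0, 0, 0.18))
  tail_base <- pelvis + L(11, 18) * tb_dir
  tail_tip <- tail_base + L(18, 21) * unitize(tb_dir + c(0, 0, 0.12))
  C[18, ] <- tail_base; C[21, ] <- tail_tip

  phase <- 2 * pi * st$stride_freq * t
  limb <- function(side, shoulder_sphere, mid_sphere, wrist_sphere,
                   end_sphere, base, dxy, zt, ph, bend_dir, L1, L2a, L2b) {
    xoff <- st$stride_amp * sin(ph)
    lift <- st$stride_lift * max(0, cos(ph))^2
    target <- c(x + dxy[1] + xoff, side * dxy[2], zt + lift)
    ik <- solve_2link(base, target, L1, L2a + L2b, bend_dir)
    C[mid_sphere, ] <<- ik$mid
    if (!is.na(wrist_sphere)) {
      C[wrist_sphere, ] <<- ik$mid + (ik$end - ik$mid) * L2a / (L2a + L2b)
    }
    C[end_sphere, ] <<- ik$end
  }

  for (side in c(1, -1)) {
    sh_id <- if (side > 0) 4L else 5L
    el_id <- if (side > 0) 12L else 13L
    wr_id <- if (side > 0) 14L else 15L
    ha_id <- if (side > 0) 16L else 17L
    shoulder <- chest + L(6, sh_id) * unitize(c(0, side * 0.075, -0.013))
    C[sh_id, ] <- shoulder
    limb(side, sh_id, el_id, wr_id, ha_id, shoulder,
         c(st$hand_dx, st$hand_dy), st$hand_z + st$hand_bump,
         phase + if (side > 0) 0 else pi, c(-1, 0, 0),
         L(sh_id, el_id), L(el_id, wr_id), L(wr_id, ha_id))

    hp_id <- if (side > 0) 9L else 10L
    kn_id <- if (side > 0) 19L else 20L
    ft_id <- if (side > 0) 22L else 23L
    hip <- pelvis + L(11, hp_id) * unitize(c(0, side * 0.06, -st$hip_drop))
    C[hp_id, ] <- hip
    limb(side, hp_id, kn_id, NA, ft_id, hip,
         c(st$foot_dx, st$foot_dy), st$foot_z + st$foot_bump,
         phase + if (side > 0) pi else 0, c(1, 0, 0.2),
         L(hp_id, kn_id), L(kn_id, ft_id), 0)
  }
  matrix_to_pose(model, C, time)
}

#' Ground-truth pose (and event labels) from a motion script
#'
#' Deterministic whole-body pose at time `t`, built geometrically with exact
#' bone lengths, plus the behavioral state implied by the same threshold
#' rules the detectors use (both feet above 20 cm = jumping; chest below
#' 20 cm with chest-abdomen difference below 10 cm = crawling; hip midpoint
#' below 9 cm with chest speed below 8 cm/s = crouching).
#'
#' @param script A [motion_script()].
#' @param model A `skf_model` (the phantom's skeleton).
#' @param t Time in seconds within the script.
#' @return List with `pose` (tibble) and `labels` (named logical vector
#'   `jumping`, `crawling`, `crouching`).
#' @export
pose_from_script <- function(script, model, t) {
  stopifnot(inherits(script, "skf_script"))
  if (t < 0 || t > script$duration + 1e-9) {
    stopf("t = %.3f s outside the script span [0, %.3f]", t, script$duration)
  }
  stt <- script_state(script, t)
  pose <- build_stance_pose(model, stt$x, stt$stance, t, time = t)
  C <- pose_matrix(pose)
  h <- 0.02
  c0 <- script_state(script, max(t - h, 0))
  c1 <- script_state(script, min(t + h, script$duration))
  p0 <- build_stance_pose(model, c0$x, c0$stance, max(t - h, 0))
  p1 <- build_stance_pose(model, c1$x, c1$stance, min(t + h, script$duration))
  chest_speed <- vnorm(pose_matrix(p1)[6, ] - pose_matrix(p0)[6, ]) /
    (min(t + h, script$duration) - max(t - h, 0))
  hip_mid_z <- (C[9, 3] + C[10, 3]) / 2
  labels <- c(
    jumping = C[22, 3] > 0.20 && C[23, 3] > 0.20,
    crawling = C[6, 3] < 0.20 && (C[6, 3] - C[8, 3]) < 0.10,
    crouching = hip_mid_z < 0.09 && chest_speed < 0.08
  )
  list(pose = pose, labels = labels)
}

#' Ground-truth trajectory sampled from a script
#'
#' @inheritParams pose_from_script
#' @param fps Sampling rate; defaults to the script's own frame rate (pass a
#'   multiple for oversampled reference trajectories).
#' @return A trajectory tibble (see [track_sequence()]) with `converged = TRUE`.
#' @export
script_trajectory <- function(script, model, fps = script$fps) {
  n <- floor(script$duration * fps) + 1L
  times <- (seq_len(n) - 1L) / fps
  rows <- purrr::map2(seq_len(n), times, function(i, t) {
    st <- script_state(script, t)
    pose <- build_stance_pose(model, st$x, st$stance, t, time = t)
    pose$frame <- i
    pose
  })
  traj <- dplyr::bind_rows(rows)
  traj$converged <- TRUE
  traj$corrected <- FALSE
  new_trajectory(traj[, c("frame", "time_s", "sphere", "label",
                          "x", "y", "z", "converged", "corrected")],
                 fps = fps)
}

#' Render a scripted sequence through the virtual camera rig
#'
#' Produces a lazily rendered multi-view depth/color sequence plus its
#' ground truth. Rendering frame `i` is deterministic given `seed`
#' (independent of evaluation order), so repeated runs are bit-identical.
#'
#' @param phantom A [skf_phantom()].
#' @param script A [motion_script()].
#' @param cameras List of [camera_model()]s.
#' @param noise_sd_mm Depth noise SD (mm).
#' @param seed Integer seed controlling all rendering noise.
#' @param k_normals Neighbourhood size for normal estimation in `cloud()`.
#' @return A `skf_sequence`: list with `n_frames`, `times`, `fps`,
#'   `frame(i)` returning the four rendered views of frame `i`, `cloud(i)`
#'   returning the merged world-frame cloud with normals and colors, and
#'   `gt` the ground-truth trajectory.
#' @export
render_sequence <- function(phantom, script, cameras = default_cameras(),
                            noise_sd_mm = 5, seed = 1L, k_normals = 16L) {
  stopifnot(inherits(phantom, "skf_phantom"), inherits(script, "skf_script"))
  model <- phantom$model
  n <- script$n_frames
  times <- (seq_len(n) - 1L) / script$fps

  frame_fn <- function(i) {
    stopifnot(i >= 1, i <= n)
    st <- script_state(script, times[[i]])
    pose <- build_stance_pose(model, st$x, st$stance, times[[i]],
                              time = times[[i]])
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed * 1000L + i)
    purrr::map(cameras, function(cam) {
      render_view(phantom, pose, cam, noise_sd_mm = noise_sd_mm)
    })
  }
  cloud_fn <- function(i) {
    views <- frame_fn(i)
    clouds <- purrr::map2(views, cameras, function(vw, cam) {
      map_colors(depth_to_points(vw$depth, cam), vw$color, cam)
    })
    estimate_normals(merge_views(clouds, cameras), k = k_normals,
                     cameras = cameras)
  }

  structure(
    list(n_frames = n, times = times, fps = script$fps,
         frame = frame_fn, cloud = cloud_fn,
         gt = script_trajectory(script, model),
         phantom = phantom, script = script, cameras = cameras,
         noise_sd_mm = noise_sd_mm, seed = seed),
    class = "skf_sequence"
  )
}

#' @export
print.skf_sequence <- function(x, ...) {
  cat(sprintf("<skf_sequence> %d frames (%.1f s at %.1f fps), %d cameras, depth noise %.1f mm\n",
              x$n_frames, x$n_frames / x$fps, x$fps, length(x$cameras),
              x$noise_sd_mm))
  invisible(x)
}
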