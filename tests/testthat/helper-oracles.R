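# Brute-force O(N*M) reference implementations of the three force fields,
# written as plain double loops straight from the definitions. They stay
# independent of the production code paths.

oracle_attraction <- function(cloud, model, pose, params) {
  S <- skelfit:::pose_matrix(pose)
  P <- cbind(cloud$x, cloud$y, cloud$z)
  r <- model$spheres$radius
  F <- matrix(0, 23, 3)
  active <- rep(list(integer()), 23)
  for (j in seq_len(nrow(P))) {
    d_all <- sqrt((S[, 1] - P[j, 1])^2 + (S[, 2] - P[j, 2])^2 +
                    (S[, 3] - P[j, 3])^2)
    in_B <- d_all <= params$regionB_factor * r
    for (i in 1:23) {
      if (d_all[i] > params$regionA_factor * r[i]) next
      if (any(in_B[-i])) next
      F[i, ] <- F[i, ] + (P[j, ] - S[i, ])
      active[[i]] <- c(active[[i]], j)
    }
  }
  F <- F * params$alpha * model$spheres$mass
  list(F = F, active = active)
}

oracle_repulsion <- function(cloud, model, pose, params) {
  S <- skelfit:::pose_matrix(pose)
  P <- cbind(cloud$x, cloud$y, cloud$z)
  N <- cbind(cloud$nx, cloud$ny, cloud$nz)
  r <- model$spheres$radius
  F <- matrix(0, 23, 3)
  for (j in seq_len(nrow(P))) {
    if (any(!is.finite(N[j, ]))) next
    for (i in 1:23) {
      d <- sqrt(sum((P[j, ] - S[i, ])^2))
      if (d > params$regionC_factor * r[i] || d < 1e-12) next
      if (sum(N[j, ] * (P[j, ] - S[i, ])) <= 0) next
      F[i, ] <- F[i, ] + params$repulsion_sign * (P[j, ] - S[i, ]) / d
    }
  }
  F * params$beta * model$spheres$mass
}

oracle_jaw <- function(cloud, model, pose, params) {
  S <- skelfit:::pose_matrix(pose)
  g <- params$hsv_gate
  f <- c(0, 0, 0)
  for (j in seq_len(nrow(cloud))) {
    h <- cloud$h[j]; s <- cloud$s[j]; v <- cloud$v[j]
    if (any(is.na(c(h, s, v)))) next
    hin <- if (g$h_min <= g$h_max) h >= g$h_min && h <= g$h_max else
      (h >= g$h_min || h <= g$h_max)
    if (!hin || s < g$s_min || v < g$v_min) next
    P <- c(cloud$x[j], cloud$y[j], cloud$z[j])
    if (sqrt(sum((P - S[3, ])^2)) > params$regionA3_radius) next
    f <- f + (P - S[1, ])
  }
  params$gamma * model$spheres$mass[1] * f
}

# minimal cloud constructor for hand-built cases
make_cloud <- function(P, N = NULL, hsv = NULL, camera = 1L) {
  n <- nrow(P)
  if (is.null(N)) N <- matrix(NA_real_, n, 3)
  tibble::tibble(
    x = P[, 1], y = P[, 2], z = P[, 3],
    nx = N[, 1], ny = N[, 2], nz = N[, 3],
    red = NA_real_, green = NA_real_, blue = NA_real_,
    h = if (is.null(hsv)) NA_real_ else hsv[, 1],
    s = if (is.null(hsv)) NA_real_ else hsv[, 2],
    v = if (is.null(hsv)) NA_real_ else hsv[, 3],
    camera = camera, u = NA_integer_, v_px = NA_integer_
  )
}

random_cloud_near_pose <- function(pose, n, spread = 0.25) {
  S <- skelfit:::pose_matrix(pose)
  anchor <- S[sample.int(23, n, replace = TRUE), ]
  P <- anchor + matrix(runif(3 * n, -spread, spread), n, 3)
  N <- matrix(rnorm(3 * n), n, 3)
  N <- N / sqrt(rowSums(N^2))
  make_cloud(P, N)
}

mean_pose_error_cm <- function(a, b) {
  100 * mean(sqrt(rowSums((skelfit:::pose_matrix(a) -
                             skelfit:::pose_matrix(b))^2)))
}

# lazily rendered shared fixture: a standing phantom seen by the 4 cameras
.fixture_env <- new.env(parent = emptyenv())

standing_fixture <- function() {
  if (is.null(.fixture_env$stand)) {
    m <- default_model()
    ph <- skf_phantom(m)
    cams <- default_cameras()
    sc <- motion_script(list(seg_stand(1)), start_x = 0)
    gt <- pose_from_script(sc, m, 0.5)$pose
    withr::with_seed(101, {
      views <- lapply(cams, function(cm) render_view(ph, gt, cm, 5))
    })
    clouds <- mapply(function(vw, cm) {
      map_colors(depth_to_points(vw$depth, cm), vw$color, cm)
    }, views, cams, SIMPLIFY = FALSE)
    cloud <- estimate_normals(merge_views(clouds, cams), 16, cams)
    .fixture_env$stand <- list(model = m, phantom = ph, cameras = cams,
                               pose = gt, views = views, cloud = cloud)
  }
  .fixture_env$stand
}
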