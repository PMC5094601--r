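test_that("attraction force follows the region-gated sum", {
  m <- default_model()
  pose <- rest_pose(m)
  S <- skelfit:::pose_matrix(pose)
  pp <- fit_params(alpha = 1)
  m1 <- m; m1$spheres$mass <- rep(1, 23)  # unit masses isolate the sum

  # empty cloud: all forces zero
  fa <- attraction_forces(make_cloud(matrix(numeric(0), 0, 3)), m1, pose, pp)
  expect_true(all(fa$forces$fx == 0 & fa$forces$fy == 0 & fa$forces$fz == 0))

  # a single admissible point: force is exactly the offset d
  d <- c(0.05, 0.02, 0.01)  # inside A_1, outside every B_k
  cl <- make_cloud(matrix(S[1, ] + d, 1, 3))
  fa <- attraction_forces(cl, m1, pose, pp)
  expect_equal(unlist(fa$forces[1, c("fx", "fy", "fz")]), d,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(fa$active[[1]], 1L)

  # two symmetric admissible points: zero net force
  d2 <- c(0.02, 0.05, 0)  # symmetric pair clear of every other claim ball
  cl2 <- make_cloud(rbind(S[1, ] + d2, S[1, ] - d2))
  fa2 <- attraction_forces(cl2, m1, pose, pp)
  expect_equal(unlist(fa2$forces[1, c("fx", "fy", "fz")]), c(0, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-12)

  # gate disjointness: a point inside B_k of sphere k attracts no other sphere
  inside_b6 <- make_cloud(matrix(S[6, ] + c(0.02, 0, 0), 1, 3))
  fa3 <- attraction_forces(inside_b6, m, pose, fit_params())
  for (i in setdiff(1:23, 6)) expect_length(fa3$active[[i]], 0)
  expect_equal(fa3$active[[6]], 1L)
})

test_that("repulsion force respects the visibility gate", {
  m <- default_model()
  m1 <- m; m1$spheres$mass <- rep(1, 23)
  pose <- rest_pose(m)
  S <- skelfit:::pose_matrix(pose)
  pp <- fit_params(beta = 1)

  # single active point: unit vector from the point toward the center
  off <- c(0.05, 0, 0)
  P <- matrix(S[6, ] + off, 1, 3)
  N <- matrix(c(1, 0, 0), 1, 3)  # normal away from the center: gate open
  fr <- repulsion_forces(make_cloud(P, N), m1, pose, pp)
  expect_equal(unlist(fr$forces[6, c("fx", "fy", "fz")]), c(-1, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-12)

  # flipped normal: the sphere center is on the outside, gate closed
  fr0 <- repulsion_forces(make_cloud(P, -N), m1, pose, pp)
  expect_equal(unlist(fr0$forces[6, c("fx", "fy", "fz")]), c(0, 0, 0),
               ignore_attr = TRUE)

  # full shell around the sphere: net force ~ 0 by symmetry
  withr::with_seed(21, {
    u <- matrix(rnorm(3 * 2000), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
  })
  shell <- make_cloud(sweep(u * 0.08, 2, S[6, ], "+"), u)
  frs <- repulsion_forces(shell, m1, pose, pp)
  # per-point mean residual well below the unit per-point magnitude
  expect_lt(max(abs(unlist(frs$forces[6, c("fx", "fy", "fz")]))),
            0.05 * length(frs$active[[6]]))

  # printed-sign variant points toward the cloud point instead
  frp <- repulsion_forces(make_cloud(P, N), m1, pose,
                          fit_params(beta = 1, repulsion_sign = 1))
  expect_equal(unlist(frp$forces[6, c("fx", "fy", "fz")]), c(1, 0, 0),
               ignore_attr = TRUE, tolerance = 1e-12)

  # undefined normals among gated points are skipped with a warning
  expect_warning(
    repulsion_forces(make_cloud(P), m1, pose, pp),
    "undefined normals"
  )
})

test_that("jaw color force sums red points inside the head region", {
  m <- default_model()
  m1 <- m; m1$spheres$mass <- rep(1, 23)
  pose <- rest_pose(m)
  S <- skelfit:::pose_matrix(pose)
  pp <- fit_params(gamma = 1)
  red <- c(0.99, 0.8, 0.7)
  brown <- c(0.08, 0.3, 0.4)

  # no red points: zero force
  P <- matrix(S[1, ] + c(0.05, 0, 0), 1, 3)
  f0 <- jaw_color_force(make_cloud(P, hsv = matrix(brown, 1)), m1, pose, pp)
  expect_equal(f0$force, c(0, 0, 0))

  # one red point at S_1 + d inside A_3: force d
  d <- c(0.01, 0.01, 0.02)
  f1 <- jaw_color_force(make_cloud(matrix(S[1, ] + d, 1, 3),
                                   hsv = matrix(red, 1)), m1, pose, pp)
  expect_equal(f1$force, d, tolerance = 1e-12)

  # red point outside A_3: region gate closes
  far <- matrix(S[3, ] + c(0.2, 0, 0), 1, 3)
  f2 <- jaw_color_force(make_cloud(far, hsv = matrix(red, 1)), m1, pose, pp)
  expect_equal(f2$force, c(0, 0, 0))

  # hue wrap: h slightly above zero also passes the red gate
  f3 <- jaw_color_force(make_cloud(matrix(S[1, ] + d, 1, 3),
                                   hsv = matrix(c(0.02, 0.8, 0.7), 1)),
                        m1, pose, pp)
  expect_equal(f3$force, d, tolerance = 1e-12)
})

test_that("production forces equal the brute-force double loop", {
  m <- default_model()
  pose <- rest_pose(m)
  pp <- fit_params()
  withr::with_seed(33, {
    for (rep in 1:5) {
      cl <- random_cloud_near_pose(pose, 400)
      cl$h <- runif(400); cl$s <- runif(400); cl$v <- runif(400)

      fa <- attraction_forces(cl, m, pose, pp)
      oa <- oracle_attraction(cl, m, pose, pp)
      expect_equal(as.matrix(fa$forces[, c("fx", "fy", "fz")]), oa$F,
                   ignore_attr = TRUE, tolerance = 1e-12)
      expect_identical(lapply(fa$active, as.integer), oa$active)

      fr <- repulsion_forces(cl, m, pose, pp)
      or <- oracle_repulsion(cl, m, pose, pp)
      expect_equal(as.matrix(fr$forces[, c("fx", "fy", "fz")]), or,
                   ignore_attr = TRUE, tolerance = 1e-12)

      fj <- jaw_color_force(cl, m, pose, pp)
      expect_equal(fj$force, oracle_jaw(cl, m, pose, pp),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  })
})

test_that("step_dynamics is a constrained overdamped update", {
  m <- default_model()
  pose <- rest_pose(m)
  pp <- fit_params()

  # zero forces: fixed point
  same <- step_dynamics(pose, matrix(0, 23, 3), m, pp)
  expect_equal(skelfit:::pose_matrix(same), skelfit:::pose_matrix(pose),
               tolerance = 1e-9)

  # force on a leaf sphere: it moves, its bone length is restored exactly
  F <- matrix(0, 23, 3)
  F[21, ] <- c(0, 0, 0.05) * m$spheres$mass[21]
  new <- step_dynamics(pose, F, m, pp)
  Cn <- skelfit:::pose_matrix(new); C0 <- skelfit:::pose_matrix(pose)
  expect_gt(Cn[21, 3] - C0[21, 3], 0)        # moved along the force
  expect_gt(sum(abs(Cn[18, ] - C0[18, ])), 0)  # parent dragged too
  L <- m$joints$rest_length[m$joints$child == 21]
  expect_equal(sqrt(sum((Cn[21, ] - Cn[18, ])^2)), unname(L),
               tolerance = 1e-6)
  expect_equal(nrow(pose_violations(m, new)), 0L)

  # a displacement carrying a joint past its limit is clamped exactly onto it
  C3 <- skelfit:::pose_matrix(pose)
  u <- C3[12, ] - C3[4, ]
  # fold the forearm back along the upper arm: bend angle near 180 degrees
  C3[14, ] <- C3[12, ] - 0.12 * u / sqrt(sum(u^2))
  p3 <- project_pose(m, skelfit:::matrix_to_pose(m, C3), sweeps = 0L)
  C3p <- skelfit:::pose_matrix(p3)
  u2 <- C3p[12, ] - C3p[4, ]; v2 <- C3p[14, ] - C3p[12, ]
  bend <- acos(sum(u2 * v2) / sqrt(sum(u2^2) * sum(v2^2))) * 180 / pi
  lim <- m$joints$bend_max[m$joints$parent == 12 & m$joints$child == 14]
  expect_equal(bend, unname(lim), tolerance = 0.01)

  expect_error(step_dynamics(pose, matrix(NaN, 23, 3), m, pp), "non-finite")
})

test_that("fitting a frame recovers the phantom pose", {
  fx <- standing_fixture()
  pp <- fit_params()

  # from ground truth: tiny drift, quick convergence
  f0 <- fit_frame(fx$cloud, fx$model, fx$pose, pp)
  expect_true(f0$converged)
  expect_lt(mean_pose_error_cm(f0$pose, fx$pose), 3)

  # from a perturbed initialization
  withr::with_seed(17, {
    init <- perturb_pose(fx$model, fx$pose, 0.05)
  })
  f1 <- fit_frame(fx$cloud, fx$model, init, pp)
  expect_true(f1$converged)
  expect_lt(f1$final_max_shift, pp$convergence_eps)
  expect_lt(mean_pose_error_cm(f1$pose, fx$pose), 3)

  # re-fitting a converged pose barely moves it (steady-state fixed point)
  f2 <- fit_frame(fx$cloud, fx$model, f1$pose, pp)
  expect_true(f2$converged)
  expect_lt(mean_pose_error_cm(f2$pose, f1$pose), 0.5)

  # empty and single-point clouds terminate cleanly
  fe <- fit_frame(make_cloud(matrix(numeric(0), 0, 3)), fx$model, fx$pose, pp)
  expect_true(fe$converged)
  expect_equal(skelfit:::pose_matrix(fe$pose),
               skelfit:::pose_matrix(fx$pose), tolerance = 1e-9)
  one <- make_cloud(matrix(c(0, 0, 0.3), 1, 3))
  f1p <- suppressWarnings(fit_frame(one, fx$model, fx$pose, pp))
  expect_s3_class(f1p, "skf_fit")
  expect_equal(nrow(pose_violations(fx$model, f1p$pose)), 0L)

  # broom-style accessors
  expect_equal(tidy(f1), f1$pose)
  expect_true(glance(f1)$converged)
})

test_that("fitting is equivariant under joint translation of cloud and init", {
  fx <- standing_fixture()
  pp <- fit_params()
  shift <- c(0.4, -0.3, 0.1)
  cl2 <- fx$cloud
  cl2$x <- cl2$x + shift[1]; cl2$y <- cl2$y + shift[2]
  cl2$z <- cl2$z + shift[3]
  init2 <- fx$pose
  init2$x <- init2$x + shift[1]; init2$y <- init2$y + shift[2]
  init2$z <- init2$z + shift[3]
  f0 <- fit_frame(fx$cloud, fx$model, fx$pose, pp)
  f2 <- fit_frame(cl2, fx$model, init2, pp)
  expect_lt(max(abs(skelfit:::pose_matrix(f2$pose) -
                      (skelfit:::pose_matrix(f0$pose) +
                         matrix(shift, 23, 3, byrow = TRUE)))), 5e-4)
})
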