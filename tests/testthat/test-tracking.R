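test_that("a single-frame video reduces to fit_frame", {
  fx <- standing_fixture()
  frames <- list(fx$cloud)
  attr(frames, "fps") <- 26.7
  withr::with_seed(23, init <- perturb_pose(fx$model, fx$pose, 0.03))
  traj <- track_sequence(frames, fx$model, init)
  f <- fit_frame(fx$cloud, fx$model, init)
  expect_equal(nrow(traj), 23L)
  expect_equal(cbind(traj$x, traj$y, traj$z),
               skelfit:::pose_matrix(f$pose), ignore_attr = TRUE)
  expect_error(track_sequence(list(), fx$model, init), "empty")
})

test_that("a static phantom tracks to a stationary trajectory", {
  fx <- standing_fixture()
  frames <- rep(list(fx$cloud), 8)
  attr(frames, "fps") <- 26.7
  traj <- track_sequence(frames, fx$model, fx$pose)
  arr <- skelfit:::traj_array(traj)
  # successive fits re-converge within the steady-state threshold, so frame
  # to frame motion stays at the convergence_eps scale and total drift small
  step_shift <- sapply(2:8, function(f) {
    max(sqrt(rowSums((arr[f, , ] - arr[f - 1, , ])^2)))
  })
  expect_lt(max(step_shift), 5 * fit_params()$convergence_eps)
  drift <- apply(arr, 2, function(s) {
    max(sqrt(rowSums(sweep(s, 2, s[1, ])^2)))
  })
  expect_lt(max(drift), 0.012)
  expect_true(all(traj$converged))
})

test_that("corrections override the initialization at their frame", {
  fx <- standing_fixture()
  frames <- rep(list(fx$cloud), 3)
  attr(frames, "fps") <- 26.7
  # plant the jaw far off at frame 2; the fit must recover from the override
  corr <- tibble::tibble(frame = 2L, sphere = 1L,
                         x = fx$pose$x[1] + 0.01,
                         y = fx$pose$y[1], z = fx$pose$z[1])
  traj <- track_sequence(frames, fx$model, fx$pose, corrections = corr)
  per_frame <- traj[!duplicated(traj$frame), ]
  expect_equal(per_frame$corrected, c(FALSE, TRUE, FALSE))
  expect_error(
    track_sequence(frames, fx$model, fx$pose,
                   corrections = tibble::tibble(frame = 99L, sphere = 1L,
                                                x = 0, y = 0, z = 0)),
    "outside"
  )
})

test_that("corrections JSON round-trips", {
  corr <- tibble::tibble(frame = c(5L, 5L, 9L), sphere = c(16L, 17L, 22L),
                         x = c(0.1, 0.2, 0.3), y = c(-0.1, 0, 0.1),
                         z = c(0.5, 0.6, 0.7))
  path <- withr::local_tempfile(fileext = ".json")
  write_corrections(corr, path)
  back <- read_corrections(path)
  expect_equal(dplyr::arrange(back, frame, sphere),
               dplyr::arrange(corr, frame, sphere))
})

test_that("trajectory CSV round-trips", {
  m <- default_model()
  sc <- motion_script(list(seg_stand(0.3)))
  traj <- script_trajectory(sc, m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$x, traj$x)
  expect_equal(back$sphere, traj$sphere)
  expect_equal(skelfit:::traj_fps(back), 26.7, tolerance = 1e-6)
})

make_synthetic_traj <- function(n, fps = 26.7, f = function(t) cbind(t, 0, 0)) {
  m <- default_model()
  base <- rest_pose(m)
  times <- (seq_len(n) - 1) / fps
  purrr::map_dfr(seq_len(n), function(i) {
    p <- base
    off <- f(times[[i]])
    p$x <- p$x + off[1]; p$y <- p$y + off[2]; p$z <- p$z + off[3]
    p$frame <- i
    p$time_s <- times[[i]]
    p$converged <- TRUE; p$corrected <- FALSE
    p
  }) |>
    (\(d) skelfit:::new_trajectory(d[, c("frame", "time_s", "sphere", "label",
                                         "x", "y", "z", "converged",
                                         "corrected")], fps = fps))()
}

test_that("loess smoothing reproduces polynomials up to degree two", {
  quad <- function(t) cbind(0.2 + 0.3 * t - 0.1 * t^2, 0.05 * t, 0.02 * t^2)
  traj <- make_synthetic_traj(80, f = quad)
  sm <- smooth_trajectory(traj, window = 0.5)
  expect_equal(sm$x, traj$x, tolerance = 1e-9)
  expect_equal(sm$y, traj$y, tolerance = 1e-9)
  expect_equal(sm$z, traj$z, tolerance = 1e-9)
  expect_equal(sm$time_s, traj$time_s)

  # constant series (rest pose) unchanged
  cst <- make_synthetic_traj(40, f = function(t) cbind(0, 0, 0))
  expect_equal(smooth_trajectory(cst, 0.5)$z, cst$z, tolerance = 1e-11)
})

test_that("loess smoothing cuts noise variance on quadratic trends", {
  sigma <- 0.01
  withr::with_seed(41, {
    noise <- rnorm(400, 0, sigma)
  })
  traj <- make_synthetic_traj(400, f = function(t) cbind(0.1 * t^2, 0, 0))
  noisy <- traj
  idx1 <- noisy$sphere == 1L
  noisy$x[idx1] <- noisy$x[idx1] + noise
  sm <- smooth_trajectory(noisy, window = 0.5)
  interior <- which(noisy$frame > 10 & noisy$frame < 390)
  resid <- (sm$x - traj$x)[intersect(interior, which(idx1))]
  expect_lt(stats::var(resid), 0.5 * sigma^2)
})

test_that("smoothing commutes with global translation and warns when degenerate", {
  traj <- make_synthetic_traj(60, f = function(t) cbind(sin(t), cos(t), 0))
  sm <- smooth_trajectory(traj, 0.5)
  shifted <- traj; shifted$x <- shifted$x + 2; shifted$z <- shifted$z - 1
  sm2 <- smooth_trajectory(shifted, 0.5)
  expect_equal(sm2$x, sm$x + 2, tolerance = 1e-9)
  expect_equal(sm2$z, sm$z - 1, tolerance = 1e-9)

  slow <- make_synthetic_traj(10, fps = 2)
  expect_warning(out <- smooth_trajectory(slow, window = 0.5), "unchanged")
  expect_equal(out$x, slow$x)
})

test_that("estimation errors report absolute and abdomen-relative distances", {
  traj <- make_synthetic_traj(50, f = function(t) cbind(0.3 * t, 0, 0))

  same <- estimation_error(traj, traj)
  expect_true(all(same$mean == 0))
  expect_equal(same$unit, c(rep("cm", 23), "deg"))

  # pure translation: 10 cm absolute everywhere, 0 in the abdomen frame
  shifted <- traj; shifted$x <- shifted$x + 0.10
  abs_err <- estimation_error(traj, shifted, frame = "absolute")
  expect_equal(abs_err$mean[abs_err$metric == "position"], rep(10, 23),
               tolerance = 1e-9)
  rel_err <- estimation_error(traj, shifted, frame = "abdomen")
  expect_equal(rel_err$mean[rel_err$metric == "position"], rep(0, 23),
               tolerance = 1e-9)
  expect_equal(rel_err$mean[rel_err$metric == "head_direction"], 0,
               tolerance = 1e-9)

  # symmetry
  e1 <- estimation_error(traj, shifted)
  e2 <- estimation_error(shifted, traj)
  expect_equal(e1$mean, e2$mean)

  # two independently jittered copies: mean distance matches the
  # closed form E||X - Y||, X, Y ~ N(0, sigma^2 I3)
  sigma <- 0.02
  jitter <- function(tr, seed) {
    withr::with_seed(seed, {
      tr$x <- tr$x + rnorm(nrow(tr), 0, sigma)
      tr$y <- tr$y + rnorm(nrow(tr), 0, sigma)
      tr$z <- tr$z + rnorm(nrow(tr), 0, sigma)
    })
    tr
  }
  big <- make_synthetic_traj(400, f = function(t) cbind(0, 0, 0))
  e <- estimation_error(jitter(big, 1), jitter(big, 2))
  # E||X - Y|| = sigma * sqrt(2) * E||N(0, I3)||, and
  # E||N(0, I3)|| = sqrt(2) * gamma(2) / gamma(3/2) = 2 * sqrt(2/pi)
  expected_cm <- 100 * sigma * sqrt(2) * 2 * sqrt(2 / pi)
  got <- mean(e$mean[e$metric == "position"])
  expect_equal(got, expected_cm, tolerance = 0.03)

  bad <- make_synthetic_traj(10)
  expect_error(estimation_error(traj, bad), "different sizes")
})

test_that("tracking a rendered sequence is deterministic and accurate", {
  m <- default_model()
  ph <- skf_phantom(m)
  cams <- default_cameras()
  sc <- motion_script(list(seg_stand(0.3), seg_walk(0.8, 0.3)), start_x = -0.2)
  seq1 <- render_sequence(ph, sc, cams, noise_sd_mm = 5, seed = 12)
  init <- dplyr::filter(seq1$gt, frame == 1)
  t1 <- track_sequence(seq1, m, init)
  t2 <- track_sequence(seq1, m, init)
  expect_identical(t1, t2)  # bit-identical given identical inputs
  err <- estimation_error(t1, seq1$gt)
  expect_lt(mean(err$mean[err$metric == "position"]), 5)
  expect_true(all(t1$converged))
  g <- glance(t1)
  expect_equal(g$n_frames, seq1$n_frames)
  expect_equal(g$fraction_converged, 1)
})
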