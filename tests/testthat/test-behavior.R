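# hand-built trajectories with chosen part heights / positions
flat_traj <- function(n, fps = 26.7, edit = NULL) {
  m <- default_model()
  base <- rest_pose(m)
  times <- (seq_len(n) - 1) / fps
  df <- purrr::map_dfr(seq_len(n), function(i) {
    p <- base
    p$frame <- i; p$time_s <- times[[i]]
    p$converged <- TRUE; p$corrected <- FALSE
    if (!is.null(edit)) p <- edit(p, i, times[[i]])
    p
  })
  skelfit:::new_trajectory(df[, c("frame", "time_s", "sphere", "label", "x",
                                  "y", "z", "converged", "corrected")],
                           fps = fps)
}

set_z <- function(p, sphere, z) { p$z[p$sphere %in% sphere] <- z; p }

test_that("jumping requires both feet above the threshold", {
  tr <- flat_traj(30, edit = function(p, i, t) {
    if (i >= 10 && i <= 20) p <- set_z(p, c(22, 23), 0.25)
    p
  })
  ev <- detect_jumping(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_frame, 10L)
  expect_equal(ev$offset_frame, 20L)
  expect_equal(ev$duration_s, 10 / 26.7, tolerance = 1e-9)

  # one foot high, the other on the floor: no event
  tr1 <- flat_traj(30, edit = function(p, i, t) set_z(p, 22, 0.25))
  expect_equal(nrow(detect_jumping(tr1)), 0L)

  # exactly at 20 cm does not count (strictly greater per the definition)
  tr2 <- flat_traj(10, edit = function(p, i, t) set_z(p, c(22, 23), 0.20))
  expect_equal(nrow(detect_jumping(tr2)), 0L)
})

test_that("crawling combines the chest height and chest-abdomen gates", {
  mk <- function(chest, abd) {
    flat_traj(8, edit = function(p, i, t) set_z(set_z(p, 6, chest), 8, abd))
  }
  expect_equal(nrow(detect_crawling(mk(0.15, 0.10))), 1L)  # 5 < 10, 15 < 20
  expect_equal(nrow(detect_crawling(mk(0.15, 0.02))), 0L)  # diff 13 >= 10
  expect_equal(nrow(detect_crawling(mk(0.25, 0.20))), 0L)  # chest >= 20
})

test_that("events are disjoint, maximal and sorted", {
  tr <- flat_traj(60, edit = function(p, i, t) {
    if ((i >= 5 && i <= 9) || (i >= 30 && i <= 42) || i == 55) {
      p <- set_z(p, c(22, 23), 0.30)
    }
    p
  })
  ev <- detect_jumping(tr)
  expect_equal(ev$onset_frame, c(5L, 30L, 55L))
  expect_equal(ev$offset_frame, c(9L, 42L, 55L))
  expect_true(all(diff(ev$onset_frame) > 0))
  expect_true(all(ev$onset_s <= ev$offset_s))
})

test_that("bar crossing spans first-hand to last-foot plane crossings", {
  # scripted traversal: hands cross the x = 0 plane around frame 40,
  # chest around 50, feet around 70
  tr <- flat_traj(120, edit = function(p, i, t) {
    cross_at <- c("16" = 40, "17" = 43, "6" = 50, "22" = 70, "23" = 67)
    for (s in names(cross_at)) {
      sp <- as.integer(s)
      p$x[p$sphere == sp] <- 0.01 * (i - cross_at[[s]]) - 0.005
    }
    p
  })
  scene <- scene_geometry()
  ev <- detect_bar_crossing(tr, scene)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$onset_frame, 41L)   # first frame on the far side
  expect_equal(ev$offset_frame, 71L)
  expect_error(detect_bar_crossing(tr, scene_geometry(travel_axis = c(0, 1, 0))),
               "parallel")

  # no plane contact: no events
  expect_equal(nrow(detect_bar_crossing(flat_traj(20))), 0L)

  # flipping the travel axis preserves the event window
  ev2 <- detect_bar_crossing(tr, scene_geometry(travel_axis = c(-1, 0, 0)))
  expect_equal(ev2$onset_frame, ev$onset_frame)
  expect_equal(ev2$offset_frame, ev$offset_frame)
})

test_that("detectors are invariant under horizontal scene translation", {
  m <- default_model()
  sc <- script_shuttle()
  tr <- script_trajectory(sc, m)
  scene <- scene_geometry()
  base <- list(detect_jumping(tr, scene), detect_crawling(tr, scene),
               detect_bar_crossing(tr, scene))
  shift <- c(0.8, -0.5)
  tr2 <- tr; tr2$x <- tr2$x + shift[1]; tr2$y <- tr2$y + shift[2]
  scene2 <- scene_geometry(bar_point = c(shift[1], shift[2], 0.35))
  moved <- list(detect_jumping(tr2, scene2), detect_crawling(tr2, scene2),
                detect_bar_crossing(tr2, scene2))
  for (k in 1:3) expect_equal(moved[[k]], base[[k]])
})

test_that("crouching needs a low hip and a quiet chest", {
  mk <- function(hipz, chest_step) {
    flat_traj(40, edit = function(p, i, t) {
      p <- set_z(p, c(9, 10), hipz)
      p$x <- p$x + chest_step * i
      p
    })
  }
  cm <- crouch_mask(mk(0.05, 0))           # low and still
  expect_true(all(cm$crouching))
  cm2 <- crouch_mask(mk(0.05, 0.01))       # low but moving ~27 cm/s
  expect_true(!any(cm2$crouching))
  cm3 <- crouch_mask(mk(0.15, 0))          # hip too high
  expect_true(!any(cm3$crouching))
})

test_that("kinematic summary matches closed-form paths and rotations", {
  fps <- 26.7
  # stationary: zero path length, no crouching frames -> NA rotation speed
  still <- flat_traj(30)
  ks <- kinematic_summary(still)
  expect_equal(ks$total_path_length_cm, 0, tolerance = 1e-9)
  expect_true(is.na(ks$mean_head_rotation_speed_cm_s))
  expect_equal(ks$n_crouching_frames, 0L)

  # chest on a 0.5 m circle, one revolution: path = 2*pi*50 cm within 1%
  n <- round(10 * fps)
  omega <- 2 * pi / ((n - 1) / fps)
  circ <- flat_traj(n, edit = function(p, i, t) {
    p$x[p$sphere == 6] <- 0.5 * cos(omega * t)
    p$y[p$sphere == 6] <- 0.5 * sin(omega * t)
    p
  })
  ks2 <- kinematic_summary(circ)
  expect_equal(ks2$total_path_length_cm, 2 * pi * 50,
               tolerance = 0.01)

  # jaw orbiting the head at rate omega with lever L while crouching:
  # head rotation speed = omega * L within 1%
  L <- 0.07; om <- 2
  orbit <- flat_traj(200, edit = function(p, i, t) {
    p <- set_z(p, c(9, 10), 0.05)  # crouching posture, chest still
    hx <- p$x[p$sphere == 3]; hy <- p$y[p$sphere == 3]
    p$x[p$sphere == 1] <- hx + L * cos(om * t)
    p$y[p$sphere == 1] <- hy + L * sin(om * t)
    p$z[p$sphere == 1] <- p$z[p$sphere == 3]
    p
  })
  ks3 <- kinematic_summary(orbit)
  expect_gt(ks3$n_crouching_frames, 190)
  expect_equal(ks3$mean_head_rotation_speed_cm_s, 100 * om * L,
               tolerance = 0.01)
  expect_equal(ks3$mean_head_rotation_speed_cm_min,
               60 * ks3$mean_head_rotation_speed_cm_s)

  # path length is additive over concatenated segments
  seg1 <- flat_traj(40, edit = function(p, i, t) {
    p$x[p$sphere == 6] <- 0.3 * t; p
  })
  whole <- kinematic_summary(seg1)$total_path_length_cm
  half_a <- dplyr::filter(seg1, frame <= 20)
  half_b <- dplyr::filter(seg1, frame >= 20)
  expect_equal(kinematic_summary(half_a)$total_path_length_cm +
                 kinematic_summary(half_b)$total_path_length_cm,
               whole, tolerance = 1e-9)
})

test_that("event comparison matches pairs and counts mismatches", {
  ev <- function(on, off) {
    tibble::tibble(kind = "jumping", onset_frame = NA_integer_,
                   offset_frame = NA_integer_, onset_s = on, offset_s = off,
                   duration_s = off - on)
  }
  a <- dplyr::bind_rows(ev(1, 2), ev(5, 6.5), ev(10, 11))

  same <- compare_events(a, a)
  expect_equal(nrow(same$pairs), 3L)
  expect_true(all(same$pairs$d_onset_s == 0))
  expect_equal(same$n_unmatched_a, 0L)
  expect_equal(same$n_unmatched_b, 0L)

  # constant shift by 2 frames at 26.7 fps
  dt <- 2 / 26.7
  b <- a; b$onset_s <- b$onset_s + dt; b$offset_s <- b$offset_s + dt
  sh <- compare_events(a, b)
  expect_equal(sh$pairs$d_onset_s, rep(dt, 3), tolerance = 1e-12)
  expect_equal(sh$pairs$d_offset_s, rep(dt, 3), tolerance = 1e-12)
  expect_equal(sh$pairs$d_duration_s, rep(0, 3), tolerance = 1e-12)

  # an extra spurious event on one side is a false positive
  c2 <- dplyr::bind_rows(a, ev(20, 21))
  fp <- compare_events(a, c2)
  expect_equal(fp$n_unmatched_b, 1L)
  expect_equal(fp$n_unmatched_a, 0L)
  expect_equal(glance(fp)$n_matched, 3L)
  expect_equal(nrow(tidy(fp)), 3L)
})
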