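#' Build an articulated 23-sphere skeleton model
#'
#' Validates a model configuration (a YAML file or an equivalent nested list)
#' and returns a `skf_model`. The model is a tree of 23 spheres connected by
#' 22 joints; each joint stores its rest length, the rest direction of the
#' child bone, a bend-angle limit in degrees (the angle between consecutive
#' bone vectors; 0 means the chain continues straight) and an anatomical
#' degree-of-freedom count kept as metadata. Sphere masses default to
#' volume-proportional values (`radius^3`, normalized to sum to 1); force
#' constants absorb the unit, so only relative masses matter.
#'
#' @param config Path to a YAML model configuration, or a list with elements
#'   `root`, `spheres` and `joints` (see the shipped
#'   `extdata/macaque_model.yaml` for the schema).
#' @return A `skf_model` object: list with tibbles `spheres` and `joints`
#'   (joints in root-to-leaf order), the root sphere id and the accumulated
#'   per-segment `subject_scale`.
#' @seealso [default_model()], [scale_model()], [pose_violations()]
#' @export
build_model <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$spheres) || is.null(config$joints)) {
    abort("model config must contain `spheres` and `joints`")
  }

  sph <- purrr::map_dfr(config$spheres, function(s) {
    tibble::tibble(
      id = as.integer(s$id), label = as.character(s$label),
      segment = as.character(s$segment %||% "body"),
      radius = as.numeric(s$radius),
      mass = as.numeric(s$mass %||% NA_real_),
      rest_x = s$rest[[1]], rest_y = s$rest[[2]], rest_z = s$rest[[3]]
    )
  })
  if (nrow(sph) != 23L) {
    stopf("model must have exactly 23 spheres, got %d", nrow(sph))
  }
  if (anyDuplicated(sph$id) || !setequal(sph$id, 1:23)) {
    abort("sphere ids must be the integers 1..23, each exactly once")
  }
  if (any(!is.finite(sph$radius)) || any(sph$radius <= 0)) {
    abort("all sphere radii must be positive")
  }
  if (all(is.na(sph$mass))) {
    sph$mass <- sph$radius^3 / sum(sph$radius^3)
  } else if (anyNA(sph$mass) || any(sph$mass <= 0)) {
    abort("sphere masses must either all be given and positive, or all absent")
  }
  sph <- sph[order(sph$id), ]

  root <- as.integer(config$root %||% 8L)
  jts <- purrr::map_dfr(config$joints, function(j) {
    tibble::tibble(
      parent = as.integer(j$parent), child = as.integer(j$child),
      dof = as.integer(j$dof %||% 3L),
      bend_min = as.numeric(j$bend[[1]]), bend_max = as.numeric(j$bend[[2]])
    )
  })
  bad <- setdiff(c(jts$parent, jts$child, root), sph$id)
  if (length(bad)) stopf("joint references missing sphere id %s", bad[[1]])
  if (any(jts$bend_min > jts$bend_max)) {
    abort("joint bend limits must satisfy min <= max")
  }
  if (nrow(jts) != 22L || anyDuplicated(jts$child) || root %in% jts$child) {
    abort("joints must form a spanning tree: 22 joints, each non-root sphere the child of exactly one joint")
  }

  # BFS from root: connectivity check and root-to-leaf joint order
  kids <- split(seq_len(nrow(jts)), jts$parent)
  order_idx <- integer(0)
  queue <- root
  seen <- root
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (ji in kids[[as.character(p)]]) {
      ch <- jts$child[[ji]]
      if (ch %in% seen) abort("cycle detected in joint graph")
      order_idx <- c(order_idx, ji)
      seen <- c(seen, ch)
      queue <- c(queue, ch)
    }
  }
  if (length(seen) != 23L) abort("joint graph is not connected")
  jts <- jts[order_idx, ]

  parent_of <- setNames(jts$parent, jts$child)
  rest <- cbind(sph$rest_x, sph$rest_y, sph$rest_z)
  rownames(rest) <- sph$id
  d <- rest[as.character(jts$child), , drop = FALSE] -
    rest[as.character(jts$parent), , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 1e-9)) abort("rest positions give a zero-length bone")

  jts$segment <- sph$segment[jts$child]
  jts$rest_length <- len
  jts$dir_x <- d[, 1] / len
  jts$dir_y <- d[, 2] / len
  jts$dir_z <- d[, 3] / len
  g <- unname(parent_of[as.character(jts$parent)])
  jts$grand <- ifelse(is.na(g), NA_integer_, as.integer(g))
  jts <- jts[, c("parent", "child", "grand", "segment", "dof",
                 "rest_length", "bend_min", "bend_max",
                 "dir_x", "dir_y", "dir_z")]

  segs <- unique(sph$segment)
  structure(
    list(
      name = config$name %||% "model",
      spheres = sph[, c("id", "label", "segment", "radius", "mass")],
      joints = jts,
      root = root,
      root_pos = unname(rest[as.character(root), ]),
      subject_scale = setNames(rep(1, length(segs)), segs)
    ),
    class = "skf_model"
  )
}

#' Default macaque skeleton model shipped with the package
#'
#' @return A `skf_model`, see [build_model()].
#' @export
default_model <- function() {
  build_model(system.file("extdata", "macaque_model.yaml",
                          package = "skelfit", mustWork = TRUE))
}

#' @export
print.skf_model <- function(x, ...) {
  cat(sprintf("<skf_model '%s'>: %d spheres, %d joints, root = %d\n",
              x$name, nrow(x$spheres), nrow(x$joints), x$root))
  cat("segments:", paste(sprintf("%s x%.2f", names(x$subject_scale),
                                 x$subject_scale), collapse = ", "), "\n")
  invisible(x)
}

#' Scale a skeleton model to a subject
#'
#' Multiplies sphere radii and bone rest lengths by per-segment factors,
#' leaving joint angle limits untouched (joint ranges are constant across
#' subjects; only dimensions change). Masses are re-derived from the scaled
#' radii and the rest pose is re-anchored so the lowest sphere touches the
#' floor.
#'
#' @param model A `skf_model`.
#' @param factors A single positive number (uniform scaling) or a named
#'   numeric vector of positive per-segment multipliers; unnamed segments
#'   keep factor 1. Segment names are those in `model$spheres$segment`
#'   (e.g. `trunk`, `head`, `forelimb_l`, ...).
#' @return The scaled `skf_model`.
#' @export
scale_model <- function(model, factors) {
  stopifnot(inherits(model, "skf_model"))
  segs <- names(model$subject_scale)
  if (is.null(names(factors))) {
    if (length(factors) != 1L) abort("unnamed `factors` must be a single number")
    factors <- setNames(rep(factors, length(segs)), segs)
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("all scale factors must be positive")
  }
  unknown <- setdiff(names(factors), segs)
  if (length(unknown)) stopf("unknown segment '%s'", unknown[[1]])
  f <- setNames(rep(1, length(segs)), segs)
  f[names(factors)] <- factors

  m <- model
  m$spheres$radius <- m$spheres$radius * unname(f[m$spheres$segment])
  m$spheres$mass <- m$spheres$radius^3 / sum(m$spheres$radius^3)
  m$joints$rest_length <- m$joints$rest_length * unname(f[m$joints$segment])
  m$subject_scale <- m$subject_scale * f

  # re-anchor the rest pose on the floor
  centers <- fk_centers(m, m$root_pos)
  drop <- min(centers[, 3] - m$spheres$radius)
  m$root_pos[3] <- m$root_pos[3] - drop
  m
}

# forward kinematics on rest directions; `local_rot` is an optional
# n_joints x 3 matrix of intrinsic XYZ Euler angles (radians) applied per
# joint, rows in model joint order
fk_centers <- function(model, root_pos = model$root_pos, local_rot = NULL) {
  jts <- model$joints
  centers <- matrix(NA_real_, 23, 3)
  rots <- vector("list", 23)
  centers[model$root, ] <- root_pos
  rots[[model$root]] <- diag(3)
  for (i in seq_len(nrow(jts))) {
    p <- jts$parent[i]; ch <- jts$child[i]
    Rloc <- diag(3)
    if (!is.null(local_rot)) {
      a <- local_rot[i, ]
      cx <- cos(a[1]); sx <- sin(a[1])
      cy <- cos(a[2]); sy <- sin(a[2])
      cz <- cos(a[3]); sz <- sin(a[3])
      Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
      Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
      Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
      Rloc <- Rx %*% Ry %*% Rz
    }
    Racc <- rots[[p]] %*% Rloc
    dir <- Racc %*% c(jts$dir_x[i], jts$dir_y[i], jts$dir_z[i])
    centers[ch, ] <- centers[p, ] + jts$rest_length[i] * as.numeric(dir)
    rots[[ch]] <- Racc
  }
  centers
}

#' Forward-kinematics pose of a skeleton model
#'
#' Poses the model by chaining each bone's rest direction through optional
#' per-joint rotations; with no rotations this is the rest pose. Mainly a
#' ground-truth generator for tests and phantoms.
#'
#' @param model A `skf_model`.
#' @param local_rot Optional `n_joints x 3` matrix of intrinsic XYZ Euler
#'   angles in radians, one row per joint in `model$joints` order.
#' @param root_pos World position of the root sphere (length-3).
#' @param time Timestamp in seconds attached to the pose.
#' @return A pose tibble with columns `sphere`, `label`, `x`, `y`, `z`,
#'   `time_s` (one row per sphere, metres).
#' @export
fk_pose <- function(model, local_rot = NULL, root_pos = model$root_pos,
                    time = NA_real_) {
  matrix_to_pose(model, fk_centers(model, root_pos, local_rot), time)
}

#' Rest pose of a skeleton model
#'
#' @inheritParams fk_pose
#' @return A pose tibble, see [fk_pose()].
#' @export
rest_pose <- function(model, time = NA_real_) fk_pose(model, time = time)

#' Anatomical constraint violations of a pose
#'
#' Checks every bone length against its rest length and every constrained
#' joint bend angle against its limits. A pose produced by forward kinematics
#' with in-range angles, or by the fitting dynamics, yields an empty result.
#'
#' @param model A `skf_model`.
#' @param pose A pose tibble (23 rows).
#' @param length_tol Allowed absolute deviation from the rest length (m).
#' @param angle_tol_deg Allowed excursion beyond a bend limit (degrees).
#' @return Tibble with one row per violation: `parent`, `child`, `kind`
#'   (`"length"` or `"angle"`) and `magnitude` (absolute deviation from the
#'   rest length in metres, or degrees beyond the nearest limit).
#' @export
pose_violations <- function(model, pose, length_tol = 1e-6,
                            angle_tol_deg = 1e-6) {
  stopifnot(inherits(model, "skf_model"))
  if (nrow(pose) != 23L) abort("pose must have 23 sphere centers")
  C <- pose_matrix(pose)
  if (any(!is.finite(C))) abort("pose contains non-finite coordinates")
  jts <- model$joints
  out <- list()

  v <- C[jts$child, , drop = FALSE] - C[jts$parent, , drop = FALSE]
  len <- sqrt(rowSums(v^2))
  dlen <- abs(len - jts$rest_length)
  bad <- which(dlen > length_tol)
  if (length(bad)) {
    out$len <- tibble::tibble(parent = jts$parent[bad], child = jts$child[bad],
                              kind = "length", magnitude = dlen[bad])
  }

  hasg <- which(!is.na(jts$grand))
  if (length(hasg)) {
    u <- C[jts$parent[hasg], , drop = FALSE] - C[jts$grand[hasg], , drop = FALSE]
    w <- v[hasg, , drop = FALSE]
    cosb <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
    bend <- rad2deg(acos(pmin(1, pmax(-1, cosb))))
    over <- pmax(jts$bend_min[hasg] - bend, bend - jts$bend_max[hasg])
    bad <- which(over > angle_tol_deg)
    if (length(bad)) {
      out$ang <- tibble::tibble(
        parent = jts$parent[hasg][bad], child = jts$child[hasg][bad],
        kind = "angle", magnitude = over[bad]
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(parent = integer(), child = integer(),
                          kind = character(), magnitude = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Head direction of a pose
#'
#' The unit vector from the head sphere (3) to the jaw sphere (1), the
#' quantity used for head-direction error reporting and head-rotation speed.
#'
#' @param pose A pose tibble.
#' @return Unit length-3 numeric vector.
#' @export
head_direction <- function(pose) {
  C <- pose_matrix(pose)
  d <- C[1, ] - C[3, ]
  if (vnorm(d) < 1e-9) abort("jaw and head centers coincide")
  unname(d / vnorm(d))
}

#' Project a pose onto the model's constraints
#'
#' Runs the positional constraint solver used inside the fitting dynamics:
#' Gauss-Seidel distance sweeps followed by an exact root-to-leaf pass that
#' restores bone lengths and clamps bend angles into their limits.
#'
#' @inheritParams pose_violations
#' @param sweeps Number of bilateral distance-projection sweeps.
#' @return The projected pose tibble.
#' @export
project_pose <- function(model, pose, sweeps = 10L) {
  C <- pose_matrix(pose)
  jts <- model$joints
  grand <- ifelse(is.na(jts$grand), -1L, jts$grand - 1L)
  out <- cpp_project_constraints(
    C, jts$parent - 1L, jts$child - 1L, as.integer(grand),
    jts$rest_length, deg2rad(jts$bend_min), deg2rad(jts$bend_max),
    1 / model$spheres$mass, as.integer(sweeps)
  )
  matrix_to_pose(model, out, pose$time_s[[1]] %||% NA_real_)
}

#' Randomly perturb a pose, then restore validity
#'
#' Adds independent uniform offsets of at most `max_shift` per sphere and
#' projects the result back onto the skeleton constraints; used to create
#' imperfect initializations for fitting experiments.
#'
#' @inheritParams project_pose
#' @param max_shift Maximum per-sphere displacement (m).
#' @return A valid pose tibble near the input.
#' @export
perturb_pose <- function(model, pose, max_shift = 0.05) {
  C <- pose_matrix(pose)
  n <- nrow(C)
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  dir <- dir / pmax(sqrt(rowSums(dir^2)), 1e-12)
  C <- C + dir * stats::runif(n, 0, max_shift)
  project_pose(model, matrix_to_pose(model, C, pose$time_s[[1]] %||% NA_real_))
}
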