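#' @importFrom rlang %||% abort warn
#' @importFrom stats setNames
NULL

# 23 x 3 matrix of sphere centers, rows ordered by sphere id
pose_matrix <- function(pose) {
  pose <- pose[order(pose$sphere), , drop = FALSE]
  m <- cbind(pose$x, pose$y, pose$z)
  rownames(m) <- pose$sphere
  m
}

matrix_to_pose <- function(model, centers, time = NA_real_) {
  tibble::tibble(
    sphere = model$spheres$id,
    label = model$spheres$label,
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    time_s = time
  )
}

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotation about z by yaw (radians), applied to rows of a matrix or a vector
rot_z <- function(yaw) {
  c_ <- cos(yaw); s_ <- sin(yaw)
  matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
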