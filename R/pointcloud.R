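#' Pinhole camera model
#'
#' Intrinsics plus the camera-to-world rigid transform. The camera frame is
#' the usual computer-vision one: `z` along the optical axis, `x` right, `y`
#' down; the world frame is right-handed with `z` up and the cage floor at
#' `z = 0`.
#'
#' @param id Camera identifier (small integer).
#' @param width,height Image size in pixels.
#' @param fx,fy Focal lengths in pixels.
#' @param cx,cy Principal point in pixels (0-based pixel coordinates).
#' @param rotation 3x3 camera-to-world rotation (orthonormal, det +1).
#' @param translation Camera position in world coordinates (m).
#' @return A `skf_camera` object.
#' @export
camera_model <- function(id, width, height, fx, fy, cx, cy,
                         rotation, translation) {
  if (fx <= 0 || fy <= 0) abort("focal lengths must be positive")
  rotation <- unname(as.matrix(rotation))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6) {
    abort("rotation must be orthonormal with determinant +1")
  }
  structure(
    list(id = as.integer(id), width = as.integer(width),
         height = as.integer(height), fx = fx, fy = fy, cx = cx, cy = cy,
         rotation = rotation, translation = as.numeric(translation)),
    class = "skf_camera"
  )
}

#' @export
print.skf_camera <- function(x, ...) {
  cat(sprintf("<skf_camera %d> %dx%d px, f = (%.1f, %.1f), at (%.2f, %.2f, %.2f) m\n",
              x$id, x$width, x$height, x$fx, x$fy,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

empty_cloud <- function() {
  tibble::tibble(
    x = numeric(), y = numeric(), z = numeric(),
    nx = numeric(), ny = numeric(), nz = numeric(),
    red = numeric(), green = numeric(), blue = numeric(),
    h = numeric(), s = numeric(), v = numeric(),
    camera = integer(), u = integer(), v_px = integer()
  )
}

#' Back-project a depth image to a camera-frame point cloud
#'
#' Each valid pixel (depth > 0) becomes one 3D point by pinhole
#' back-projection; a zero depth is a no-return and is dropped. Depth values
#' are millimetres along the optical axis.
#'
#' @param depth Integer/numeric matrix, `height x width`, depth in mm,
#'   0 = invalid.
#' @param camera A [camera_model()] whose size matches the image.
#' @return Point-cloud tibble in the camera frame: columns `x,y,z` (m),
#'   undefined normals `nx,ny,nz`, color slots, the source `camera` id and
#'   the pixel coordinates `u`, `v_px` used for color registration.
#' @export
depth_to_points <- function(depth, camera) {
  stopifnot(inherits(camera, "skf_camera"))
  if (nrow(depth) != camera$height || ncol(depth) != camera$width) {
    stopf("depth image is %dx%d but camera expects %dx%d",
          nrow(depth), ncol(depth), camera$height, camera$width)
  }
  idx <- which(is.finite(depth) & depth > 0)
  if (!length(idx)) return(empty_cloud())
  vr <- (idx - 1L) %% nrow(depth)        # 0-based row = v
  uc <- (idx - 1L) %/% nrow(depth)       # 0-based col = u
  z <- depth[idx] / 1000
  tibble::tibble(
    x = (uc - camera$cx) / camera$fx * z,
    y = (vr - camera$cy) / camera$fy * z,
    z = z,
    nx = NA_real_, ny = NA_real_, nz = NA_real_,
    red = NA_real_, green = NA_real_, blue = NA_real_,
    h = NA_real_, s = NA_real_, v = NA_real_,
    camera = camera$id, u = as.integer(uc), v_px = as.integer(vr)
  )
}

#' Attach colors to a camera-frame point cloud
#'
#' Samples the RGB image at each point's source pixel (color and depth share
#' the pixel grid) and stores both RGB and HSV, hue wrapped to `[0, 1)`.
#'
#' @param cloud A cloud from [depth_to_points()] (same camera).
#' @param color `height x width x 3` array with values in `[0, 1]`.
#' @inheritParams depth_to_points
#' @return The cloud with `red,green,blue,h,s,v` filled in.
#' @export
map_colors <- function(cloud, color, camera) {
  if (dim(color)[1] != camera$height || dim(color)[2] != camera$width) {
    abort("color image size does not match the camera")
  }
  if (!nrow(cloud)) return(cloud)
  ii <- cbind(cloud$v_px + 1L, cloud$u + 1L)
  r <- color[, , 1][ii]; g <- color[, , 2][ii]; b <- color[, , 3][ii]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 1)
  cloud$red <- r; cloud$green <- g; cloud$blue <- b
  cloud$h <- hsv[1, ] %% 1; cloud$s <- hsv[2, ]; cloud$v <- hsv[3, ]
  cloud
}

#' Merge per-camera clouds into the world frame
#'
#' Applies each camera's extrinsic transform and concatenates; per-point
#' source camera ids are preserved. Normals, if present, are rotated.
#'
#' @param clouds List of camera-frame clouds, one per camera.
#' @param cameras List of [camera_model()]s, same order.
#' @return A single world-frame cloud tibble.
#' @export
merge_views <- function(clouds, cameras) {
  if (length(clouds) != length(cameras)) {
    abort("need exactly one cloud per camera")
  }
  if (!length(clouds)) return(empty_cloud())
  out <- purrr::map2(clouds, cameras, function(cl, cam) {
    stopifnot(inherits(cam, "skf_camera"))
    if (!nrow(cl)) return(cl)
    P <- cbind(cl$x, cl$y, cl$z) %*% t(cam$rotation)
    cl$x <- P[, 1] + cam$translation[1]
    cl$y <- P[, 2] + cam$translation[2]
    cl$z <- P[, 3] + cam$translation[3]
    if (any(is.finite(cl$nx))) {
      N <- cbind(cl$nx, cl$ny, cl$nz) %*% t(cam$rotation)
      cl$nx <- N[, 1]; cl$ny <- N[, 2]; cl$nz <- N[, 3]
    }
    cl
  })
  dplyr::bind_rows(out)
}

#' Estimate surface normals by local PCA
#'
#' Each point's normal is the smallest-eigenvalue eigenvector of the
#' covariance of its `k` nearest neighbours, sign-oriented toward the
#' observing camera (so normals point outward, off the animal's surface,
#' which makes the repulsion visibility gate well defined). Points whose
#' neighbourhood cannot be formed keep undefined (`NA`) normals.
#'
#' @param cloud A world-frame cloud tibble.
#' @param k Neighbourhood size (>= 3).
#' @param cameras Optional list of [camera_model()]s used to orient normals
#'   via each point's `camera` id; without it the PCA sign is arbitrary.
#' @return The cloud with `nx,ny,nz` filled (unit vectors or `NA`).
#' @export
estimate_normals <- function(cloud, k = 16L, cameras = NULL) {
  if (k < 3) abort("k must be at least 3")
  if (!nrow(cloud)) return(cloud)
  campos <- matrix(NA_real_, nrow(cloud), 3)
  if (!is.null(cameras)) {
    pos <- do.call(rbind, purrr::map(cameras, "translation"))
    ids <- purrr::map_int(cameras, "id")
    m <- match(cloud$camera, ids)
    ok <- !is.na(m)
    campos[ok, ] <- pos[m[ok], , drop = FALSE]
  }
  N <- cpp_knn_normals(cbind(cloud$x, cloud$y, cloud$z), as.integer(k), campos)
  cloud$nx <- N[, 1]; cloud$ny <- N[, 2]; cloud$nz <- N[, 3]
  cloud
}

#' Spatial include/exclude regions
#'
#' Axis-aligned boxes and spheres used to separate the animal from background
#' structure: points are kept when they fall inside the union of the include
#' regions (all space if none is given) and outside every exclude region.
#'
#' @param include,exclude Lists of [region_box()] / [region_sphere()] objects.
#' @return A `skf_regions` object.
#' @export
region_set <- function(include = list(), exclude = list()) {
  chk <- function(r) inherits(r, "skf_region")
  if (!all(purrr::map_lgl(include, chk)) || !all(purrr::map_lgl(exclude, chk))) {
    abort("regions must be created with region_box() or region_sphere()")
  }
  structure(list(include = include, exclude = exclude), class = "skf_regions")
}

#' @rdname region_set
#' @param min,max Opposite corners of the box (length-3, m).
#' @export
region_box <- function(min, max) {
  stopifnot(length(min) == 3, length(max) == 3, all(min <= max))
  structure(list(type = "box", min = as.numeric(min), max = as.numeric(max)),
            class = "skf_region")
}

#' @rdname region_set
#' @param center Sphere center (length-3, m).
#' @param radius Sphere radius (m, > 0).
#' @export
region_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  structure(list(type = "sphere", center = as.numeric(center),
                 radius = radius), class = "skf_region")
}

region_mask <- function(region, P) {
  if (region$type == "box") {
    P[, 1] >= region$min[1] & P[, 1] <= region$max[1] &
      P[, 2] >= region$min[2] & P[, 2] <= region$max[2] &
      P[, 3] >= region$min[3] & P[, 3] <= region$max[3]
  } else {
    d2 <- (P[, 1] - region$center[1])^2 + (P[, 2] - region$center[2])^2 +
      (P[, 3] - region$center[3])^2
    d2 <= region$radius^2
  }
}

#' Filter a cloud by include/exclude regions
#'
#' @param cloud A cloud tibble.
#' @param regions A [region_set()].
#' @return The filtered cloud (idempotent).
#' @export
filter_regions <- function(cloud, regions) {
  stopifnot(inherits(regions, "skf_regions"))
  if (!nrow(cloud)) return(cloud)
  P <- cbind(cloud$x, cloud$y, cloud$z)
  keep <- rep(TRUE, nrow(cloud))
  if (length(regions$include)) {
    keep <- Reduce(`|`, purrr::map(regions$include, region_mask, P = P))
  }
  if (length(regions$exclude)) {
    excl <- Reduce(`|`, purrr::map(regions$exclude, region_mask, P = P))
    keep <- keep & !excl
  }
  cloud[keep, , drop = FALSE]
}
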