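# Camera, depth-frame and manifest file formats: depth as 16-bit grayscale
# TIFF in millimetres (0 = no return), color as 8-bit PNG on the same pixel
# grid, cameras and manifests as JSON.

camera_to_list <- function(cam) {
  list(id = cam$id, width = cam$width, height = cam$height,
       fx = cam$fx, fy = cam$fy, cx = cam$cx, cy = cam$cy,
       rotation = as.vector(cam$rotation), translation = cam$translation)
}

camera_from_list <- function(l) {
  camera_model(l$id, l$width, l$height, l$fx, l$fy, l$cx, l$cy,
               matrix(unlist(l$rotation), 3, 3), unlist(l$translation))
}

#' Camera file input/output
#'
#' Cameras are stored as a JSON array of intrinsics + camera-to-world pose.
#'
#' @param cameras List of [camera_model()]s.
#' @param path JSON file.
#' @return `write_cameras` returns `path` invisibly; `read_cameras` a list
#'   of cameras.
#' @export
write_cameras <- function(cameras, path) {
  jsonlite::write_json(purrr::map(cameras, camera_to_list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cameras
#' @export
read_cameras <- function(path) {
  purrr::map(jsonlite::read_json(path), camera_from_list)
}

#' Write a depth image (16-bit TIFF, millimetres)
#'
#' @param depth Integer matrix of mm depths (0 = invalid).
#' @param path Output TIFF.
#' @return `path`, invisibly.
#' @export
write_depth <- function(depth, path) {
  tiff::writeTIFF(depth / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  round(tiff::readTIFF(path) * 65535)
}

#' Write a rendered sequence to disk
#'
#' Materializes an in-memory [render_sequence()] as the on-disk layout the
#' tracking pipeline consumes: per-frame per-camera depth TIFFs and color
#' PNGs, a `cameras.json`, a `manifest.json` (fps, timestamps, file table)
#' and the ground truth (`gt_trajectory.csv`).
#'
#' @param sequence An `skf_sequence`.
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_sequence <- function(sequence, out_dir) {
  stopifnot(inherits(sequence, "skf_sequence"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cams <- sequence$cameras
  write_cameras(cams, file.path(out_dir, "cameras.json"))
  frames <- purrr::map(seq_len(sequence$n_frames), function(i) {
    views <- sequence$frame(i)
    depth_files <- character(length(cams))
    color_files <- character(length(cams))
    for (c_i in seq_along(cams)) {
      depth_files[c_i] <- sprintf("frame%04d_cam%d_depth.tif", i, c_i)
      color_files[c_i] <- sprintf("frame%04d_cam%d_color.png", i, c_i)
      write_depth(views[[c_i]]$depth, file.path(out_dir, depth_files[c_i]))
      png::writePNG(views[[c_i]]$color, file.path(out_dir, color_files[c_i]))
    }
    list(frame = i, time_s = sequence$times[[i]], depth = depth_files,
         color = color_files)
  })
  manifest <- list(fps = sequence$fps, n_frames = sequence$n_frames,
                   cameras = "cameras.json", frames = frames)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  write_trajectory(sequence$gt, file.path(out_dir, "gt_trajectory.csv"))
  invisible(path)
}

#' Lazily load frames from an on-disk manifest
#'
#' Returns a frame source usable by [track_sequence()]: each access reads
#' that frame's four depth/color images, back-projects, merges, filters and
#' estimates normals.
#'
#' @param manifest Path to a `manifest.json` written by [write_sequence()].
#' @param regions Optional [region_set()] applied after merging.
#' @param k_normals Neighbourhood size for normals.
#' @return A `function(i)` with attributes `n_frames` and `fps`.
#' @export
frames_from_manifest <- function(manifest, regions = NULL, k_normals = 16L) {
  man <- jsonlite::read_json(manifest)
  base <- dirname(manifest)
  cams <- read_cameras(file.path(base, man$cameras))
  fetch <- function(i) {
    fr <- man$frames[[i]]
    clouds <- purrr::map(seq_along(cams), function(c_i) {
      depth <- read_depth(file.path(base, fr$depth[[c_i]]))
      color <- png::readPNG(file.path(base, fr$color[[c_i]]))
      map_colors(depth_to_points(depth, cams[[c_i]]), color, cams[[c_i]])
    })
    cl <- merge_views(clouds, cams)
    if (!is.null(regions)) cl <- filter_regions(cl, regions)
    estimate_normals(cl, k = k_normals, cameras = cams)
  }
  attr(fetch, "n_frames") <- man$n_frames
  attr(fetch, "fps") <- man$fps
  fetch
}

#' Events JSON input/output
#'
#' @param events Events tibble (see [detect_jumping()]).
#' @param path JSON file.
#' @return `write_events` returns `path` invisibly; `read_events` the tibble.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(events, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (!length(df)) {
    return(tibble::tibble(kind = character(), onset_frame = integer(),
                          offset_frame = integer(), onset_s = numeric(),
                          offset_s = numeric(), duration_s = numeric()))
  }
  tibble::as_tibble(df)
}

#' Run the full analysis pipeline on a recorded sequence
#'
#' Executes track, smooth, detect and summarize on an on-disk sequence,
#' writing the trajectory CSVs, events JSON, kinematic summary JSON and a
#' run-metadata JSON (config hash, seed, package version, convergence and
#' correction statistics). Any stage failure aborts with a diagnostic naming
#' the stage; artifacts are only written on success.
#'
#' @param config A YAML file path or list with fields `manifest` (path),
#'   `model` (YAML path; defaults to the shipped model), `out_dir`, and
#'   optional `params` (arguments for [fit_params()]), `scene` (arguments
#'   for [scene_geometry()]), `corrections` (JSON path), `init` (trajectory
#'   CSV whose first frame is the initial pose; defaults to the ground-truth
#'   file next to the manifest if present, else the model rest pose),
#'   `smooth_window` (s), `seed`.
#' @return Invisibly, a list of artifact paths and the run metadata.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("manifest", "out_dir")) {
    if (is.null(config[[field]])) stopf("config is missing `%s`", field)
  }
  if (!file.exists(config$manifest)) {
    stopf("manifest '%s' does not exist", config$manifest)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  model <- stage("model", {
    if (is.null(config$model)) default_model() else build_model(config$model)
  })
  params <- stage("params", do.call(fit_params, config$params %||% list()))
  scene <- stage("scene", do.call(scene_geometry, config$scene %||% list()))
  seed <- config$seed %||% 1L
  set.seed(seed)

  frames <- stage("frames", frames_from_manifest(config$manifest))
  init <- stage("init", {
    if (!is.null(config$init)) {
      tr <- read_trajectory(config$init)
      dplyr::filter(tr, frame == min(frame))
    } else {
      gt_path <- file.path(dirname(config$manifest), "gt_trajectory.csv")
      if (file.exists(gt_path)) {
        tr <- read_trajectory(gt_path)
        dplyr::filter(tr, frame == min(frame))
      } else {
        rest_pose(model)
      }
    }
  })
  traj <- stage("track", {
    track_sequence(frames, model, init, params,
                   corrections = config$corrections)
  })
  sm <- stage("smooth", smooth_trajectory(traj, config$smooth_window %||% 0.5))
  events <- stage("detect", dplyr::bind_rows(
    detect_bar_crossing(sm, scene),
    detect_jumping(sm, scene),
    detect_crawling(sm, scene)
  ))
  summary <- stage("summarize", kinematic_summary(sm, scene))

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_file)
  meta <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = seed,
    skelfit_version = as.character(utils::packageVersion("skelfit")),
    n_frames = length(unique(traj$frame)),
    fraction_converged = mean(traj$converged),
    n_corrected_frames = length(unique(traj$frame[traj$corrected])),
    smooth_window_s = config$smooth_window %||% 0.5
  )
  paths <- list(
    trajectory = file.path(out, "trajectory.csv"),
    trajectory_smoothed = file.path(out, "trajectory_smoothed.csv"),
    events = file.path(out, "events.json"),
    summary = file.path(out, "summary.json"),
    metadata = file.path(out, "run_metadata.json")
  )
  write_trajectory(traj, paths$trajectory)
  write_trajectory(sm, paths$trajectory_smoothed)
  write_events(events, paths$events)
  jsonlite::write_json(c(meta["config_hash"], as.list(summary)),
                       paths$summary, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(meta, paths$metadata, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, metadata = meta, summary = summary,
                 events = events))
}
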