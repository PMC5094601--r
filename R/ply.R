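# Minimal PLY vertex-cloud I/O (ascii and binary_little_endian), carrying
# position, normal, RGB and source camera id. Property names follow the
# common convention (x y z nx ny nz red green blue camera_id).

ply_type_info <- list(
  char = c(1, "integer"), uchar = c(1, "integer"),
  int8 = c(1, "integer"), uint8 = c(1, "integer"),
  short = c(2, "integer"), ushort = c(2, "integer"),
  int16 = c(2, "integer"), uint16 = c(2, "integer"),
  int = c(4, "integer"), uint = c(4, "integer"),
  int32 = c(4, "integer"), uint32 = c(4, "integer"),
  float = c(4, "double"), float32 = c(4, "double"),
  double = c(8, "double"), float64 = c(8, "double")
)

#' Write a point cloud to a PLY file
#'
#' @param cloud A cloud tibble (world or camera frame).
#' @param path Output file.
#' @param format `"ascii"` or `"binary_little_endian"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  n <- nrow(cloud)
  rgb255 <- function(x) {
    x <- ifelse(is.finite(x), pmin(pmax(x, 0), 1), 0)
    as.integer(round(x * 255))
  }
  cols <- list(
    x = cloud$x, y = cloud$y, z = cloud$z,
    nx = ifelse(is.finite(cloud$nx), cloud$nx, 0),
    ny = ifelse(is.finite(cloud$ny), cloud$ny, 0),
    nz = ifelse(is.finite(cloud$nz), cloud$nz, 0),
    red = rgb255(cloud$red), green = rgb255(cloud$green),
    blue = rgb255(cloud$blue),
    camera_id = as.integer(cloud$camera %||% rep(0L, n))
  )
  types <- c(x = "float", y = "float", z = "float", nx = "float", ny = "float",
             nz = "float", red = "uchar", green = "uchar", blue = "uchar",
             camera_id = "uchar")
  header <- c(
    "ply", paste("format", format, "1.0"),
    "comment skelfit point cloud",
    paste("element vertex", n),
    paste("property", types, names(types)),
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (format == "ascii") {
    m <- do.call(cbind, lapply(cols, function(x) {
      if (is.integer(x)) format(x, scientific = FALSE)
      else formatC(x, format = "g", digits = 9)
    }))
    writeLines(apply(m, 1, paste, collapse = " "), con, sep = "\n")
  } else {
    for (i in seq_len(n)) {
      for (nm in names(types)) {
        tp <- types[[nm]]
        if (tp == "float") {
          writeBin(as.numeric(cols[[nm]][i]), con, size = 4,
                   endian = "little")
        } else {
          writeBin(as.integer(cols[[nm]][i]), con, size = 1,
                   endian = "little")
        }
      }
    }
  }
  invisible(path)
}

#' Read a PLY vertex cloud
#'
#' Supports ascii and binary_little_endian files with scalar vertex
#' properties; recognizes `x y z`, `nx ny nz`, `red green blue` and
#' `camera_id`, ignoring other elements.
#'
#' @param path PLY file.
#' @return A cloud tibble; HSV columns are derived from RGB when present.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line)) abort("unexpected end of PLY header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", header, value = TRUE)[1])
  fmt <- strsplit(fmt, " ")[[1]][1]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stopf("unsupported PLY format '%s'", fmt)
  }
  # vertex element and its properties (other elements only supported after it)
  elem_lines <- grep("^element ", header)
  vert_line <- grep("^element vertex ", header)[1]
  if (is.na(vert_line)) abort("PLY file has no vertex element")
  nvert <- as.integer(strsplit(header[vert_line], " ")[[1]][3])
  stop_at <- c(elem_lines[elem_lines > vert_line], length(header))[1]
  props <- header[(vert_line + 1):(stop_at - 1)]
  props <- props[startsWith(props, "property ")]
  if (any(grepl("^property list", props))) {
    abort("list properties on vertices are not supported")
  }
  parts <- strsplit(props, " +")
  ptypes <- purrr::map_chr(parts, 2)
  pnames <- purrr::map_chr(parts, 3)
  unknown <- setdiff(ptypes, names(ply_type_info))
  if (length(unknown)) stopf("unsupported PLY property type '%s'", unknown[[1]])

  if (fmt == "ascii") {
    lines <- readLines(con, n = nvert)
    vals <- scan(text = lines, what = numeric(), quiet = TRUE)
    dat <- as.data.frame(matrix(vals, nrow = nvert, byrow = TRUE))
    names(dat) <- pnames
  } else {
    sizes <- as.integer(purrr::map_chr(ply_type_info[ptypes], 1))
    whats <- purrr::map_chr(ply_type_info[ptypes], 2)
    raw <- readBin(con, "raw", n = nvert * sum(sizes))
    dat <- as.data.frame(matrix(0, nvert, length(pnames)))
    names(dat) <- pnames
    offs <- cumsum(c(0, sizes))[seq_along(sizes)]
    rec <- sum(sizes)
    for (j in seq_along(pnames)) {
      idx <- as.vector(outer(seq_len(sizes[j]), offs[j] + rec * (seq_len(nvert) - 1L), `+`))
      bytes <- raw[idx]
      dat[[j]] <- readBin(bytes, whats[j], n = nvert, size = sizes[j],
                          endian = "little",
                          signed = !(ptypes[j] %in% c("uchar", "uint8", "ushort", "uint16")))
    }
  }

  get <- function(nm, default = NA_real_) {
    if (nm %in% names(dat)) as.numeric(dat[[nm]]) else rep(default, nvert)
  }
  r <- get("red"); g <- get("green"); b <- get("blue")
  if (any(is.finite(r))) { r <- r / 255; g <- g / 255; b <- b / 255 }
  cl <- tibble::tibble(
    x = get("x"), y = get("y"), z = get("z"),
    nx = get("nx"), ny = get("ny"), nz = get("nz"),
    red = r, green = g, blue = b,
    h = NA_real_, s = NA_real_, v = NA_real_,
    camera = as.integer(get("camera_id", 0)),
    u = NA_integer_, v_px = NA_integer_
  )
  nrm <- sqrt(cl$nx^2 + cl$ny^2 + cl$nz^2)
  und <- !is.finite(nrm) | nrm < 1e-6
  cl$nx[und] <- NA_real_; cl$ny[und] <- NA_real_; cl$nz[und] <- NA_real_
  ok <- is.finite(cl$red)
  if (any(ok)) {
    hsv <- grDevices::rgb2hsv(rbind(cl$red[ok], cl$green[ok], cl$blue[ok]),
                              maxColorValue = 1)
    cl$h[ok] <- hsv[1, ] %% 1; cl$s[ok] <- hsv[2, ]; cl$v[ok] <- hsv[3, ]
  }
  cl
}
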