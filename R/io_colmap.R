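# Sparse-model text I/O (cameras.txt / images.txt / points3D.txt).
# Only the ubiquitous three-file text dialect is supported; the binary
# dialect is a possible extension.  Observation indices are 0-based in the
# files and 1-based inside R.

fmt_num <- function(x) sprintf("%.17g", x)

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

#' Read a sparse reconstruction from a text model directory
#'
#' Parses `cameras.txt`, `images.txt` and `points3D.txt` and verifies full
#' referential integrity between frame observations and point tracks.
#'
#' @param path directory containing the three text-model files.
#' @return A [sparse_reconstruction()].
#' @export
read_colmap_sparse <- function(path) {
  files <- file.path(path, c("cameras.txt", "images.txt", "points3D.txt"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("format error: missing sparse-model file(s): ",
         paste(basename(missing), collapse = ", "), call. = FALSE)

  # cameras
  cameras <- list()
  for (line in readLines(files[1], warn = FALSE)) {
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- split_fields(line)
    cameras[[length(cameras) + 1L]] <- camera_intrinsics(
      camera_id = as.integer(f[1]), model = f[2],
      width = as.integer(f[3]), height = as.integer(f[4]),
      params = as.numeric(f[-(1:4)])
    )
  }

  # images: two lines per record
  frames <- list()
  lines <- readLines(files[2], warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#")]
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- split_fields(lines[i])
    obs_line <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    o <- if (nzchar(trimws(obs_line))) as.numeric(split_fields(obs_line))
         else numeric()
    if (length(o) %% 3L != 0L)
      stop("format error: malformed observation line for image ", f[1],
           call. = FALSE)
    om <- matrix(o, ncol = 3L, byrow = TRUE)
    ids3d <- as.integer(om[, 3])
    ids3d[ids3d == -1L] <- NA_integer_
    frames[[length(frames) + 1L]] <- frame_pose(
      frame_id = as.integer(f[1]),
      qvec = as.numeric(f[2:5]), tvec = as.numeric(f[6:8]),
      camera_id = as.integer(f[9]),
      name = if (length(f) >= 10) f[10] else "",
      xys = om[, 1:2, drop = FALSE], point3d_ids = ids3d
    )
    i <- i + 2L
  }

  # points
  ids <- integer(); xyz <- list(); rgb <- list(); err <- numeric()
  track <- list()
  for (line in readLines(files[3], warn = FALSE)) {
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    f <- as.numeric(split_fields(line))
    k <- length(ids) + 1L
    ids[k] <- as.integer(f[1])
    xyz[[k]] <- f[2:4]
    rgb[[k]] <- as.integer(f[5:7])
    err[k] <- f[8]
    tr <- f[-(1:8)]
    if (length(tr) %% 2L != 0L)
      stop("format error: malformed track for point ", f[1], call. = FALSE)
    tm <- matrix(as.integer(tr), ncol = 2L, byrow = TRUE)
    tm[, 2] <- tm[, 2] + 1L   # 0-based in file -> 1-based in R
    track[[k]] <- tm
  }
  points <- list(
    ids = ids,
    xyz = if (length(ids)) do.call(rbind, xyz) else matrix(numeric(), 0, 3),
    rgb = if (length(ids)) do.call(rbind, rgb) else matrix(integer(), 0, 3),
    error = err, track = track
  )
  sparse_reconstruction(cameras, frames, points, validate = TRUE)
}

#' Write a sparse reconstruction as a text model directory
#'
#' Emits the three-file text dialect readable by [read_colmap_sparse()];
#' reals are written with 17 significant digits so a write/read round trip
#' is an identity well below 1e-9.
#'
#' @param recon a [sparse_reconstruction()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_colmap_sparse <- function(recon, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)

  cam_lines <- c(
    "# Camera list with one line of data per camera:",
    "#   CAMERA_ID, MODEL, WIDTH, HEIGHT, PARAMS[]",
    paste("# Number of cameras:", length(recon$cameras)),
    vapply(recon$cameras, function(cam) {
      paste(cam$camera_id, cam$model, cam$width, cam$height,
            paste(fmt_num(cam$params), collapse = " "))
    }, "")
  )
  writeLines(cam_lines, file.path(path, "cameras.txt"))

  img_lines <- c(
    "# Image list with two lines of data per image:",
    "#   IMAGE_ID, QW, QX, QY, QZ, TX, TY, TZ, CAMERA_ID, NAME",
    "#   POINTS2D[] as (X, Y, POINT3D_ID)",
    paste("# Number of images:", length(recon$frames))
  )
  for (f in recon$frames) {
    img_lines <- c(img_lines, paste(
      f$frame_id, paste(fmt_num(f$qvec), collapse = " "),
      paste(fmt_num(f$tvec), collapse = " "), f$camera_id, f$name
    ))
    ids3d <- f$point3d_ids
    ids3d[is.na(ids3d)] <- -1L
    obs <- if (nrow(f$xys)) {
      paste(as.vector(t(cbind(fmt_num(f$xys[, 1]), fmt_num(f$xys[, 2]),
                              ids3d))), collapse = " ")
    } else ""
    img_lines <- c(img_lines, obs)
  }
  writeLines(img_lines, file.path(path, "images.txt"))

  pt_lines <- c(
    "# 3D point list with one line of data per point:",
    "#   POINT3D_ID, X, Y, Z, R, G, B, ERROR, TRACK[] as (IMAGE_ID, POINT2D_IDX)",
    paste("# Number of points:", length(recon$points$ids))
  )
  p <- recon$points
  rec_lines <- vapply(seq_along(p$ids), function(i) {
    tr <- p$track[[i]]
    tr_txt <- if (nrow(tr)) {
      paste(as.vector(t(cbind(tr[, 1], tr[, 2] - 1L))), collapse = " ")
    } else ""
    trimws(paste(
      p$ids[i], paste(fmt_num(p$xyz[i, ]), collapse = " "),
      paste(p$rgb[i, ], collapse = " "), fmt_num(p$error[i]), tr_txt
    ))
  }, "")
  writeLines(c(pt_lines, rec_lines), file.path(path, "points3D.txt"))
  invisible(path)
}
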