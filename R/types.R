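#' @useDynLib gastro3d, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd
#' @importFrom utils head
NULL

as_points3 <- function(x, what = "points") {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must be an N x 3 matrix", call. = FALSE)
  storage.mode(x) <- "double"
  dimnames(x) <- NULL
  x
}

#' Camera intrinsics
#'
#' Intrinsic parameters of one camera in the sparse-model convention: a model
#' token plus a flat parameter vector whose layout depends on the model
#' (`PINHOLE`: fx fy cx cy; `SIMPLE_PINHOLE`: f cx cy; other models keep
#' their parameter vectors verbatim and expose the leading pinhole part).
#'
#' @param camera_id integer id.
#' @param model model token, e.g. `"PINHOLE"`.
#' @param width,height image size in pixels.
#' @param params numeric parameter vector (model-dependent length).
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(camera_id, model, width, height, params) {
  obj <- structure(list(
    camera_id = as.integer(camera_id), model = as.character(model),
    width = as.integer(width), height = as.integer(height),
    params = as.numeric(params)
  ), class = "camera_intrinsics")
  validate_camera_intrinsics(obj)
  obj
}

validate_camera_intrinsics <- function(cam) {
  pin <- pinhole_params(cam)
  if (!(pin["fx"] > 0) || !(pin["fy"] > 0))
    stop("focal length must be positive", call. = FALSE)
  if (pin["cx"] < 0 || pin["cx"] >= cam$width ||
      pin["cy"] < 0 || pin["cy"] >= cam$height)
    stop("principal point must lie inside the image", call. = FALSE)
  invisible(cam)
}

#' Pinhole part of a camera's intrinsics
#'
#' @param cam a [camera_intrinsics()] object.
#' @return Named vector `c(fx, fy, cx, cy)`.
#' @export
pinhole_params <- function(cam) {
  p <- cam$params
  switch(cam$model,
    SIMPLE_PINHOLE = ,
    SIMPLE_RADIAL = ,
    RADIAL = c(fx = p[1], fy = p[1], cx = p[2], cy = p[3]),
    # PINHOLE, OPENCV, OPENCV_FISHEYE, ... all start fx fy cx cy
    c(fx = p[1], fy = p[2], cx = p[3], cy = p[4])
  )
}

#' Frame pose
#'
#' World-to-camera pose of one registered frame, plus its 2D feature
#' observations.  The quaternion is stored in (w, x, y, z) order as in the
#' sparse-model text dialect.
#'
#' @param frame_id integer id.
#' @param qvec unit quaternion (w, x, y, z), world-to-camera rotation.
#' @param tvec length-3 translation, world-to-camera.
#' @param camera_id id of the owning camera.
#' @param name image file name.
#' @param xys n x 2 matrix of feature pixel coordinates (may have 0 rows).
#' @param point3d_ids integer vector of 3D point ids per observation
#'   (`NA` for features with no triangulated point).
#' @return An object of class `frame_pose`.
#' @export
frame_pose <- function(frame_id, qvec, tvec, camera_id, name = "",
                       xys = matrix(numeric(), 0, 2),
                       point3d_ids = integer()) {
  qvec <- as.numeric(qvec)
  nq <- sqrt(sum(qvec^2))
  if (abs(nq - 1) > 1e-9) stop("quaternion must have unit norm", call. = FALSE)
  xys <- as.matrix(xys)
  if (nrow(xys) != length(point3d_ids))
    stop("xys and point3d_ids must have equal length", call. = FALSE)
  structure(list(
    frame_id = as.integer(frame_id), qvec = qvec, tvec = as.numeric(tvec),
    camera_id = as.integer(camera_id), name = as.character(name),
    xys = xys, point3d_ids = as.integer(point3d_ids)
  ), class = "frame_pose")
}

#' Rotation matrix of a world-to-camera quaternion
#'
#' @param q unit quaternion (w, x, y, z).
#' @return 3 x 3 rotation matrix `R` with `x_cam = R x_world + t`.
#' @export
quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' @rdname quat_to_rotmat
#' @param R a rotation matrix.
#' @return `rotmat_to_quat`: unit quaternion (w, x, y, z) with `w >= 0`.
#' @export
rotmat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

#' Camera center in world coordinates
#'
#' @param pose a [frame_pose()].
#' @return Length-3 vector `C = -R' t`.
#' @export
camera_center <- function(pose) {
  R <- quat_to_rotmat(pose$qvec)
  as.numeric(-crossprod(R, pose$tvec))
}

#' Sparse reconstruction container
#'
#' The sparse structure-from-motion output: cameras, registered frame poses
#' with their 2D observations, and 3D points with feature tracks.  Points are
#' stored column-wise (ids / xyz / rgb / error) with a parallel list of
#' track matrices (columns `frame_id`, `obs_idx`; `obs_idx` is 1-based
#' internally and converted to the 0-based file convention on write).
#'
#' @param cameras list of [camera_intrinsics()].
#' @param frames list of [frame_pose()].
#' @param points list with elements `ids` (integer N), `xyz` (N x 3),
#'   `rgb` (N x 3 integer 0-255), `error` (numeric N), `track`
#'   (list of N two-column matrices).
#' @param validate check referential integrity (default `TRUE`).
#' @return An object of class `sparse_reconstruction`.
#' @export
sparse_reconstruction <- function(cameras = list(), frames = list(),
                                  points = empty_points(), validate = TRUE) {
  names(cameras) <- vapply(cameras, function(c) as.character(c$camera_id), "")
  names(frames) <- vapply(frames, function(f) as.character(f$frame_id), "")
  obj <- structure(list(cameras = cameras, frames = frames, points = points),
                   class = "sparse_reconstruction")
  if (validate) validate_reconstruction(obj)
  obj
}

empty_points <- function() {
  list(ids = integer(), xyz = matrix(numeric(), 0, 3),
       rgb = matrix(integer(), 0, 3), error = numeric(), track = list())
}

#' Validate referential integrity of a sparse reconstruction
#'
#' Checks that every frame references an existing camera, every non-missing
#' observation id references an existing 3D point, and every track entry is
#' the exact inverse of the corresponding frame observation.
#'
#' @param recon a [sparse_reconstruction()].
#' @return The reconstruction, invisibly; stops with an integrity error
#'   naming the offending id otherwise.
#' @export
validate_reconstruction <- function(recon) {
  pt_ids <- recon$points$ids
  frame_ids <- vapply(recon$frames, function(f) f$frame_id, integer(1))
  for (f in recon$frames) {
    if (is.null(recon$cameras[[as.character(f$camera_id)]]))
      stop("integrity error: frame ", f$frame_id, " references unknown camera ",
           f$camera_id, call. = FALSE)
    obs <- f$point3d_ids
    bad <- obs[!is.na(obs) & !(obs %in% pt_ids)]
    if (length(bad))
      stop("integrity error: frame ", f$frame_id,
           " observes unknown 3D point ", bad[1], call. = FALSE)
  }
  for (i in seq_along(pt_ids)) {
    tr <- recon$points$track[[i]]
    if (nrow(tr) == 0) next
    for (j in seq_len(nrow(tr))) {
      fid <- tr[j, 1]; oi <- tr[j, 2]
      fr <- recon$frames[[as.character(fid)]]
      if (is.null(fr))
        stop("integrity error: point ", pt_ids[i],
             " tracked in unregistered frame ", fid, call. = FALSE)
      if (oi < 1 || oi > length(fr$point3d_ids) ||
          is.na(fr$point3d_ids[oi]) || fr$point3d_ids[oi] != pt_ids[i])
        stop("integrity error: track of point ", pt_ids[i],
             " does not match observation ", oi, " of frame ", fid,
             call. = FALSE)
    }
  }
  # inverse direction: every non-missing observation appears in its track
  for (f in recon$frames) {
    obs <- f$point3d_ids
    for (oi in which(!is.na(obs))) {
      i <- match(obs[oi], pt_ids)
      tr <- recon$points$track[[i]]
      if (!any(tr[, 1] == f$frame_id & tr[, 2] == oi))
        stop("integrity error: observation ", oi, " of frame ", f$frame_id,
             " missing from track of point ", obs[oi], call. = FALSE)
    }
  }
  invisible(recon)
}

#' @export
print.sparse_reconstruction <- function(x, ...) {
  cat("<sparse_reconstruction>", length(x$cameras), "cameras,",
      length(x$frames), "frames,", length(x$points$ids), "points\n")
  invisible(x)
}

#' Triangle mesh
#'
#' @param vertices V x 3 numeric matrix.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param normals optional V x 3 unit vertex normals.
#' @param colors optional V x 3 integer vertex colors (0-255).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL, colors = NULL) {
  vertices <- as_points3(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L && nrow(faces) > 0)
    stop("faces must be an F x 3 index matrix", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range", call. = FALSE)
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate face (repeated vertex index)", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces,
                 normals = normals, colors = colors),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh>", nrow(x$vertices), "vertices,", nrow(x$faces),
      "faces\n")
  invisible(x)
}

#' Ordered frame sequence
#'
#' An ordered list of equally sized frames.  Each frame is an integer array,
#' `H x W` for single-channel sequences and `H x W x 3` for RGB, with
#' intensities in 0-255.
#'
#' @param frames list of integer arrays.
#' @param channel one of `"RGB"`, `"R"`, `"G"`, `"B"`.
#' @param index integer frame indices (defaults to `seq_along(frames)`).
#' @param names optional file names.
#' @param source_id free-form origin tag.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, channel = "RGB", index = seq_along(frames),
                           names = NULL, source_id = "") {
  channel <- match.arg(channel, c("RGB", "R", "G", "B"))
  if (length(frames)) {
    dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
    if (length(unique(dims)) > 1L) {
      off <- which(dims != dims[1])
      stop("frames have mixed dimensions (frames ",
           paste(off, collapse = ", "), ")", call. = FALSE)
    }
    nch <- if (length(dim(frames[[1]])) == 3L) dim(frames[[1]])[3] else 1L
    want <- if (channel == "RGB") 3L else 1L
    if (nch != want)
      stop("channel tag ", channel, " expects ", want, "-channel frames",
           call. = FALSE)
  }
  structure(list(frames = frames, channel = channel,
                 index = as.integer(index), names = names,
                 source_id = source_id),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  d <- if (length(x$frames)) paste(dim(x$frames[[1]]), collapse = "x") else "-"
  cat("<frame_sequence>", length(x$frames), "frames,", x$channel, d, "\n")
  invisible(x)
}

#' Labeled point-cloud stage
#'
#' A point set at one stage of the outlier-removal cascade, together with the
#' surviving original point ids and the bounding-box diagonal `r` recomputed
#' for this stage.
#'
#' @param points N x 3 matrix.
#' @param ids original point ids (defaults to row numbers).
#' @param stage one of `"P"`, `"P_prime"`, `"P_hat"`, `"P_tilde"`.
#' @return An object of class `point_cloud_stage`.
#' @export
point_cloud_stage <- function(points, ids = seq_len(nrow(points)),
                              stage = "P") {
  points <- as_points3(points)
  stage <- match.arg(stage, c("P", "P_prime", "P_hat", "P_tilde"))
  structure(list(points = points, ids = as.integer(ids), stage = stage,
                 r = if (nrow(points)) bbox_diagonal(points) else 0),
            class = "point_cloud_stage")
}

#' @export
print.point_cloud_stage <- function(x, ...) {
  cat("<point_cloud_stage>", x$stage, ":", nrow(x$points),
      "points, r =", format(x$r, digits = 6), "\n")
  invisible(x)
}
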