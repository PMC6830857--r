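# Normal estimation / orientation / smoothing, implicit surface
# reconstruction from oriented points, and camera scoring for color
# transfer.  The surface is extracted as the zero level set of a smoothed
# signed-distance field (Gaussian-blended tangent planes of the k nearest
# oriented points) polygonized by marching tetrahedra; `depth` plays the
# role of an octree depth, the grid has 2^depth cells along the longest
# axis, so low depths yield deliberately smooth, low-detail surfaces.

#' Estimate unoriented per-point normals by local PCA
#'
#' Each point's normal is the eigenvector of the smallest eigenvalue of the
#' covariance of its neighbourhood (the point plus its `k` nearest
#' neighbours).  Signs are arbitrary at this stage.
#'
#' @param points N x 3 matrix (N >= 3).
#' @param k neighbourhood size (default 100, clamped to N - 1).
#' @return N x 3 matrix of unit normals.
#' @export
estimate_normals <- function(points, k = 100L) {
  points <- as_points3(points)
  if (nrow(points) < 3L)
    stop("normal estimation needs >= 3 points", call. = FALSE)
  k <- min(as.integer(k), nrow(points) - 1L)
  knn <- cpp_knn_self(points, k)
  cpp_pca_normals(points, knn$idx)
}

#' Orient normals using camera poses
#'
#' Each normal is flipped so it points toward the mean center of the cameras
#' observing the point (`dot(n, c_bar - p) >= 0`); a zero dot product keeps
#' the normal unflipped.  Points without a track use the globally nearest
#' camera center.  Without a reconstruction, normals are oriented toward the
#' cloud centroid (the interior of a cavity, where the endoscope sits).
#'
#' @param points N x 3 matrix.
#' @param normals N x 3 unit normals (e.g. from [estimate_normals()]).
#' @param recon optional [sparse_reconstruction()] whose frames observe the
#'   points.
#' @param point_ids point ids aligning rows of `points` with `recon` point
#'   ids (default: the reconstruction's own ids when `recon` is given).
#' @return N x 3 matrix of oriented unit normals.
#' @export
orient_normals <- function(points, normals, recon = NULL, point_ids = NULL) {
  points <- as_points3(points)
  n <- nrow(points)
  if (is.null(recon)) {
    centroid <- colMeans(points)
    towards <- matrix(centroid, n, 3, byrow = TRUE) - points
  } else {
    if (length(recon$frames) == 0L)
      stop("reconstruction has no registered frames", call. = FALSE)
    if (is.null(point_ids)) point_ids <- recon$points$ids
    stopifnot(length(point_ids) == n)
    centers <- t(vapply(recon$frames, camera_center, numeric(3)))
    mean_center <- matrix(NA_real_, n, 3)
    idx_in_recon <- match(point_ids, recon$points$ids)
    frame_ids <- vapply(recon$frames, function(f) f$frame_id, integer(1))
    for (i in seq_len(n)) {
      j <- idx_in_recon[i]
      tr <- if (!is.na(j)) recon$points$track[[j]] else NULL
      if (!is.null(tr) && nrow(tr) > 0) {
        rows <- match(tr[, 1], frame_ids)
        mean_center[i, ] <- colMeans(centers[rows, , drop = FALSE])
      }
    }
    missing <- which(is.na(mean_center[, 1]))
    if (length(missing)) {
      nearest <- cpp_knn_query(centers, points[missing, , drop = FALSE], 1L)
      mean_center[missing, ] <- centers[nearest$idx[, 1], , drop = FALSE]
    }
    towards <- mean_center - points
  }
  flip <- rowSums(normals * towards) < 0
  normals[flip, ] <- -normals[flip, ]
  normals
}

#' Smooth oriented normals
#'
#' Each normal is replaced by the renormalized mean of the normals of its
#' `k_smooth` nearest points (the point itself included); `k_smooth = 1` is
#' the identity.  Zero-length means keep the original normal.
#'
#' @param points N x 3 matrix.
#' @param normals N x 3 oriented unit normals.
#' @param k_smooth neighbourhood size including self (default 10).
#' @return N x 3 matrix of smoothed unit normals.
#' @export
smooth_normals <- function(points, normals, k_smooth = 10L) {
  points <- as_points3(points)
  k_smooth <- min(as.integer(k_smooth), nrow(points))
  if (k_smooth <= 1L) return(normals)
  knn <- cpp_knn_self(points, k_smooth - 1L)
  out <- normals
  for (i in seq_len(nrow(points))) {
    nb <- c(i, knn$idx[i, ])
    m <- colSums(normals[nb, , drop = FALSE])
    len <- sqrt(sum(m^2))
    if (len > 1e-12) out[i, ] <- m / len
  }
  out
}

#' Reconstruct a triangle mesh from oriented points
#'
#' Implicit surface reconstruction: a signed-distance field is evaluated on
#' a regular grid as the Gaussian-weighted average of signed distances to
#' the tangent planes of the `k` nearest oriented points, and its zero level
#' set is extracted with marching tetrahedra.  `depth` controls resolution
#' (2^depth cells along the longest bounding-box axis), so small depths give
#' very smooth surfaces and larger depths recover detail.
#'
#' @param points N x 3 matrix of surface samples (N >= 4).
#' @param normals N x 3 consistently oriented unit normals.
#' @param depth resolution exponent (default 7).
#' @param k tangent-plane blending neighbours (default 12).
#' @param padding bounding-box padding as a fraction of the diagonal
#'   (default 0.05).
#' @param keep_largest keep only the largest connected component, discarding
#'   spurious blobs from far-field sign noise (default TRUE).
#' @return A [triangle_mesh()].
#' @export
reconstruct_mesh <- function(points, normals, depth = 7L, k = 12L,
                             padding = 0.05, keep_largest = TRUE) {
  points <- as_points3(points)
  if (nrow(points) < 4L)
    stop("surface reconstruction needs >= 4 points", call. = FALSE)
  stopifnot(nrow(normals) == nrow(points))
  lo <- apply(points, 2, min)
  hi <- apply(points, 2, max)
  diag_len <- sqrt(sum((hi - lo)^2))
  if (diag_len <= 0) stop("degenerate input: zero-extent cloud", call. = FALSE)
  pad <- padding * diag_len
  lo <- lo - pad
  hi <- hi + pad
  spacing <- max(hi - lo) / 2^depth
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  field <- cpp_sdf_grid(points, normals, lo, spacing, dims,
                        as.integer(min(k, nrow(points))))
  mt <- cpp_marching_tetra(field, dims, lo, spacing)
  if (nrow(mt$faces) == 0L)
    stop("degenerate input: surface reconstruction produced no triangles",
         call. = FALSE)
  mesh <- triangle_mesh(mt$vertices, mt$faces)
  if (keep_largest) mesh <- largest_component(mesh)
  mesh
}

# largest connected component of a mesh (vertex-connectivity union-find)
largest_component <- function(mesh) {
  nv <- nrow(mesh$vertices)
  parent <- seq_len(nv)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    a <- find(f[i, 1]); b <- find(f[i, 2]); c <- find(f[i, 3])
    parent[b] <- a
    parent[c] <- a
  }
  roots <- vapply(seq_len(nv), find, integer(1))
  main <- as.integer(names(which.max(table(roots))))
  keep_v <- roots == main
  remap <- cumsum(keep_v)
  keep_f <- keep_v[f[, 1]]
  triangle_mesh(mesh$vertices[keep_v, , drop = FALSE],
                cbind(remap[f[keep_f, 1]], remap[f[keep_f, 2]],
                      remap[f[keep_f, 3]]))
}

#' Face centroids and normals of a mesh
#'
#' @param mesh a [triangle_mesh()].
#' @return `face_centroids`: F x 3 matrix.
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname face_centroids
#' @return `face_normals`: F x 3 matrix of unit normals (right-hand rule on
#'   the stored vertex order).
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# score a set of target points with given outward directions against all
# registered cameras; returns best frame id per point plus full per-frame
# scores when requested.  s = angle_cos / (1 + distance / r_scale).
score_cameras_points <- function(targets, dirs, recon, r_scale,
                                 full = FALSE) {
  n <- nrow(targets)
  best_score <- rep(-Inf, n)
  best_frame <- rep(NA_integer_, n)
  rows <- list()
  for (f in recon$frames) {
    cam <- recon$cameras[[as.character(f$camera_id)]]
    pin <- pinhole_params(cam)
    R <- quat_to_rotmat(f$qvec)
    C <- camera_center(f)
    xc <- t(R %*% t(targets) + f$tvec)
    u <- pin["fx"] * xc[, 1] / xc[, 3] + pin["cx"]
    v <- pin["fy"] * xc[, 2] / xc[, 3] + pin["cy"]
    visible <- xc[, 3] > 0 & u >= 0 & u < cam$width & v >= 0 & v < cam$height
    to_cam <- matrix(C, n, 3, byrow = TRUE) - targets
    dist <- sqrt(rowSums(to_cam^2))
    cosang <- rowSums(dirs * to_cam) / pmax(dist, 1e-300)
    score <- cosang / (1 + dist / r_scale)
    ok <- visible & cosang > 0
    improve <- ok & (score > best_score |
                       (score == best_score & f$frame_id < best_frame))
    improve[is.na(improve)] <- FALSE
    best_score[improve] <- score[improve]
    best_frame[improve] <- f$frame_id
    if (full)
      rows[[length(rows) + 1L]] <- data.frame(
        frame_id = f$frame_id, angle_cos = cosang, distance = dist,
        score = score, visible = ok)
  }
  out <- list(best_frame = best_frame, best_score = best_score)
  if (full) out$all <- do.call(rbind, rows)
  out
}

#' Rank cameras for texturing one mesh face
#'
#' Candidate frames must see the face centroid (in front of the camera,
#' projecting inside the image) from the front side of the face.  They are
#' ranked by `s = angle_cos / (1 + distance / r_mesh)`, a dimensionless
#' score increasing with orthogonality and proximity (`r_mesh` is the mesh
#' bounding-box diagonal).  Occlusion is not tested: a single cavity has
#' little self-occlusion.
#'
#' @param face face index into `mesh$faces`.
#' @param mesh a [triangle_mesh()].
#' @param recon a [sparse_reconstruction()].
#' @return A data frame (`frame_id`, `angle_cos`, `distance`, `score`),
#'   best candidate first; zero rows when no camera sees the face.
#' @export
score_cameras_for_face <- function(face, mesh, recon) {
  centroid <- face_centroids(mesh)[face, , drop = FALSE]
  normal <- face_normals(mesh)[face, , drop = FALSE]
  r_mesh <- bbox_diagonal(mesh$vertices)
  sc <- score_cameras_points(centroid, normal, recon, r_mesh, full = TRUE)
  cand <- sc$all[sc$all$visible, c("frame_id", "angle_cos", "distance",
                                   "score")]
  cand <- cand[order(-cand$score, cand$frame_id), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Transfer per-vertex colors from registered frames
#'
#' Every vertex is colored by its best-ranked camera (the ranking of
#' [score_cameras_for_face()] applied at the vertex with its oriented
#' normal), sampling the frame image at the projected pixel with
#' nearest-pixel lookup.  Vertices visible to no camera get sentinel gray
#' (128, 128, 128).
#'
#' @param mesh a [triangle_mesh()]; vertex normals are used when present,
#'   otherwise computed and oriented toward the cameras.
#' @param recon a [sparse_reconstruction()] with registered frames.
#' @param frames an RGB [frame_sequence()] whose names or indices match the
#'   reconstruction's frame names/ids.
#' @return The mesh with a `colors` matrix attached.
#' @export
transfer_vertex_colors <- function(mesh, recon, frames) {
  v <- mesh$vertices
  nv <- nrow(v)
  normals <- mesh$normals
  if (is.null(normals)) {
    normals <- estimate_normals(v, k = min(30L, nv - 1L))
    normals <- orient_normals(v, normals, recon = recon,
                              point_ids = rep(NA_integer_, nv))
  }
  r_mesh <- bbox_diagonal(v)
  sc <- score_cameras_points(v, normals, recon, r_mesh)
  colors <- matrix(128L, nv, 3)
  for (fid in unique(sc$best_frame[!is.na(sc$best_frame)])) {
    pose <- recon$frames[[as.character(fid)]]
    img <- frame_image_for(frames, pose)
    if (is.null(img))
      stop("no image available for registered frame ", fid, call. = FALSE)
    cam <- recon$cameras[[as.character(pose$camera_id)]]
    pin <- pinhole_params(cam)
    R <- quat_to_rotmat(pose$qvec)
    sel <- which(sc$best_frame == fid)
    xc <- t(R %*% t(v[sel, , drop = FALSE]) + pose$tvec)
    u <- pin["fx"] * xc[, 1] / xc[, 3] + pin["cx"]
    vv <- pin["fy"] * xc[, 2] / xc[, 3] + pin["cy"]
    col <- pmin(pmax(floor(u) + 1L, 1L), dim(img)[2])
    row <- pmin(pmax(floor(vv) + 1L, 1L), dim(img)[1])
    for (j in seq_along(sel)) {
      colors[sel[j], ] <- as.integer(img[row[j], col[j], ])
    }
  }
  mesh$colors <- colors
  mesh$normals <- normals
  mesh
}

# match a frame image to a registered pose: by file name first, then by
# sequence index equal to the frame id
frame_image_for <- function(frames, pose) {
  i <- NA_integer_
  if (!is.null(frames$names) && nzchar(pose$name))
    i <- match(pose$name, frames$names)
  if (is.na(i)) i <- match(pose$frame_id, frames$index)
  if (is.na(i)) return(NULL)
  frames$frames[[i]]
}
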