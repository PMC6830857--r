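# Frame retrieval and localization.  Retrieval ranks frames by Euclidean
# distance between global image descriptors, d = ||f(I_r) - f(I_t)||.  The
# descriptor interface is pluggable: the default is a deterministic,
# dependency-free downsampled-intensity vector; externally computed
# descriptors (e.g. CNN features) can be supplied as a matrix.

#' Compute a global image descriptor
#'
#' The default `"downsample"` method converts the frame to grayscale,
#' average-pools it to `size x size`, subtracts the mean and L2-normalizes,
#' yielding a brightness-scale-invariant `size^2` vector.  A constant frame
#' has zero variance and maps to the zero vector.
#'
#' @param frame an integer frame array (`H x W` or `H x W x 3`).
#' @param method descriptor method token (only `"downsample"` is built in).
#' @param size pooled grid side length (default 16).
#' @return List with `vector` and `method`.
#' @export
compute_descriptor <- function(frame, method = "downsample", size = 16L) {
  if (!identical(method, "downsample"))
    stop("unsupported descriptor method: ", method, call. = FALSE)
  g <- if (length(dim(frame)) == 3L) {
    (frame[, , 1] + frame[, , 2] + frame[, , 3]) / 3
  } else {
    frame
  }
  h <- nrow(g); w <- ncol(g)
  size <- min(size, h, w)
  gr <- floor((seq_len(h) - 1L) * size / h) + 1L
  gc <- floor((seq_len(w) - 1L) * size / w) + 1L
  pooled <- rowsum(g, gr)                       # pool rows
  pooled <- t(rowsum(t(pooled), gc))            # pool cols
  counts <- outer(tabulate(gr, size), tabulate(gc, size))
  vec <- as.numeric(pooled / counts)
  vec <- vec - mean(vec)
  nrm <- sqrt(sum(vec^2))
  if (nrm > 1e-12) vec <- vec / nrm else vec <- rep(0, length(vec))
  list(vector = vec, method = method)
}

descriptor_matrix <- function(seq, method = "downsample", size = 16L) {
  t(vapply(seq$frames,
           function(f) compute_descriptor(f, method, size)$vector,
           numeric(min(size, dim(seq$frames[[1]])[1],
                       dim(seq$frames[[1]])[2])^2)))
}

#' Retrieve the frames most similar to a reference frame
#'
#' Frames are ranked by ascending Euclidean distance between descriptors;
#' the reference itself appears at rank 1 with distance 0.  Distance ties
#' are broken by frame index.
#'
#' @param reference_id frame index (a value of `seq$index`).
#' @param seq a [frame_sequence()].
#' @param n how many frames to return (published default 100); clamped with
#'   a warning when larger than the sequence.
#' @param method descriptor method (see [compute_descriptor()]).
#' @param descriptors optional precomputed descriptor matrix (one row per
#'   frame, aligned with `seq`), the plug-in point for external CNN
#'   features.
#' @return List with `ranked` (data frame `frame_id`, `distance`) and
#'   `reference_id`.
#' @export
retrieve_similar <- function(reference_id, seq, n = 100L,
                             method = "downsample", descriptors = NULL) {
  pos <- match(reference_id, seq$index)
  if (is.na(pos)) stop("reference frame ", reference_id,
                       " not in sequence", call. = FALSE)
  if (n > length(seq$frames)) {
    warning("n = ", n, " clamped to sequence length ", length(seq$frames))
    n <- length(seq$frames)
  }
  D <- if (is.null(descriptors)) descriptor_matrix(seq, method)
       else as.matrix(descriptors)
  ref <- D[pos, ]
  d <- sqrt(rowSums((D - matrix(ref, nrow(D), ncol(D), byrow = TRUE))^2))
  # the reference wins its zero-distance tie with exact duplicates;
  # remaining ties break by frame index
  ord <- order(d, seq$index != reference_id, seq$index)
  top <- ord[seq_len(n)]
  list(ranked = data.frame(frame_id = seq$index[top], distance = d[top]),
       reference_id = reference_id)
}

#' Localize a registered frame on the mesh
#'
#' Casts a `ray_grid x ray_grid` grid of pixel rays from the frame's camera
#' through the image plane and records the first mesh intersection of each
#' ray (rays starting inside the mesh are valid — the endoscope films from
#' inside the cavity).
#'
#' @param frame_id a registered frame id.
#' @param recon a [sparse_reconstruction()].
#' @param mesh a [triangle_mesh()].
#' @param ray_grid rays per image side (default 32).
#' @return List with `frame_id`, `hit_points` (H x 3), `hit_faces`
#'   (H face indices), `hit_pixels` (H x 2), and `coverage_fraction`.
#' @export
localize_frame <- function(frame_id, recon, mesh, ray_grid = 32L) {
  pose <- recon$frames[[as.character(frame_id)]]
  if (is.null(pose))
    stop("frame ", frame_id, " is not registered", call. = FALSE)
  cam <- recon$cameras[[as.character(pose$camera_id)]]
  pin <- pinhole_params(cam)
  g <- seq_len(ray_grid)
  u <- (g - 0.5) / ray_grid * cam$width
  v <- (g - 0.5) / ray_grid * cam$height
  uv <- cbind(rep(u, times = ray_grid), rep(v, each = ray_grid))
  dir_cam <- cbind((uv[, 1] - pin["cx"]) / pin["fx"],
                   (uv[, 2] - pin["cy"]) / pin["fy"], 1)
  dir_cam <- dir_cam / sqrt(rowSums(dir_cam^2))
  R <- quat_to_rotmat(pose$qvec)
  dirs <- dir_cam %*% R              # R^T d, row-wise
  C <- camera_center(pose)
  origins <- matrix(C, nrow(dirs), 3, byrow = TRUE)
  hit <- cpp_ray_mesh_first_hit(origins, dirs, mesh$vertices, mesh$faces)
  ok <- !is.na(hit$face)
  list(frame_id = frame_id,
       hit_points = hit$points[ok, , drop = FALSE],
       hit_faces = hit$face[ok],
       hit_pixels = uv[ok, , drop = FALSE],
       coverage_fraction = mean(ok))
}

#' Select frames for a local reconstruction
#'
#' Returns the ids of the `n` frames most similar to the reference, i.e. the
#' prefix of the [retrieve_similar()] ranking, ready to be exported (as
#' single-channel images) to an external structure-from-motion run.
#'
#' @inheritParams retrieve_similar
#' @return Integer vector of `n` frame ids.
#' @export
select_local_frames <- function(reference_id, seq, n = 100L,
                                method = "downsample") {
  retrieve_similar(reference_id, seq, n, method)$ranked$frame_id
}
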