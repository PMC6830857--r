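# Shared fixtures and independent oracles.  Expensive fixtures are built
# lazily once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_cache)) assign(name, expr, .fixture_cache)
  get(name, .fixture_cache)
}

# a hand-built 2-camera, 5-point reconstruction with full cross-links
tiny_recon <- function() {
  cam <- camera_intrinsics(1L, "PINHOLE", 64L, 64L, c(50, 50, 32, 32))
  q <- c(1, 0, 0, 0)
  xys <- cbind(10 + seq_len(5), 20 + seq_len(5)) + 0.123456789012
  f1 <- frame_pose(1L, q, c(0, 0, 0), 1L, "a.png", xys, 1:5)
  f2 <- frame_pose(2L, q / sqrt(sum(q^2)), c(0.25, 0, 0), 1L, "b.png",
                   xys + 1, 1:5)
  pts <- list(
    ids = 1:5,
    xyz = matrix(rnorm(15), 5, 3),
    rgb = matrix(rep(c(10L, 20L, 30L), each = 5), 5, 3),
    error = runif(5),
    track = lapply(1:5, function(i) rbind(c(1L, i), c(2L, i)))
  )
  sparse_reconstruction(list(cam), list(f1, f2), pts)
}

# exhaustive O(N^2) nearest-neighbour oracle for the isolated filter
isolated_oracle_keep <- function(points, A) {
  dm <- as.matrix(dist(points))
  diag(dm) <- Inf
  unname(apply(dm, 1, min)) <= A * bbox_diagonal(points)
}

# brute-force enumeration of all point triples: the inlier-count-maximising
# plane, ties by smaller inlier-distance sum
plane_oracle <- function(pts, eps) {
  n <- nrow(pts)
  best <- NULL
  for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
    u <- pts[b, ] - pts[a, ]
    v <- pts[cc, ] - pts[a, ]
    nr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nr^2))
    if (nn < 1e-12) next
    nr <- nr / nn
    off <- -sum(nr * pts[a, ])
    d <- abs(as.numeric(pts %*% nr) + off)
    cnt <- sum(d <= eps)
    sdist <- sum(d[d <= eps])
    if (is.null(best) || cnt > best$count ||
        (cnt == best$count && sdist < best$sumdist))
      best <- list(count = cnt, sumdist = sdist, normal = nr, offset = off)
  }
  best
}

# noiseless unit-sphere cloud with an interior camera trajectory
sphere_fixture <- function() {
  cached("sphere", {
    surf <- make_surface(semi_axes = c(1, 1, 1), bump_amplitude = 0,
                         bump_count = 0L)
    scene <- sample_cloud(surf, n_inliers = 2000L, noise_sigma = 0,
                          n_isolated = 0L, n_near = 0L, seed = 5L)
    recon <- suppressWarnings(
      make_trajectory_and_tracks(surf, scene, n_cameras = 30L,
                                 points_per_view = 300L))
    normals <- estimate_normals(scene$points, k = 100L)
    oriented <- orient_normals(scene$points, normals, recon = recon,
                               point_ids = seq_len(nrow(scene$points)))
    list(surface = surf, scene = scene, recon = recon, normals = normals,
         oriented = oriented)
  })
}

sphere_mesh_d5 <- function() {
  cached("sphere_mesh_d5", {
    fx <- sphere_fixture()
    reconstruct_mesh(fx$scene$points, fx$oriented, depth = 5L)
  })
}

# default-parameter synthetic study scene (shared by cascade tests)
study_scene <- function() {
  cached("study_scene", {
    surf <- make_surface(seed = 2L)
    sample_cloud(surf, seed = 3L)
  })
}

# axis-aligned unit cube mesh centred at the origin (12 triangles)
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = c(-0.5, 0.5), y = c(-0.5, 0.5),
                             z = c(-0.5, 0.5)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = -0.5
    c(5, 6, 7), c(6, 8, 7),   # z = +0.5
    c(1, 2, 5), c(2, 6, 5),   # y = -0.5
    c(3, 7, 4), c(4, 7, 8),   # y = +0.5
    c(1, 5, 3), c(3, 5, 7),   # x = -0.5
    c(2, 4, 6), c(4, 8, 6)    # x = +0.5
  )
  triangle_mesh(v, f)
}

# world-to-camera pose looking from centre C along unit direction z_dir
pose_looking <- function(frame_id, C, z_dir, camera_id = 1L, name = "") {
  z <- z_dir / sqrt(sum(z_dir^2))
  up <- if (abs(z[3]) > 0.98) c(1, 0, 0) else c(0, 0, 1)
  x <- up - sum(up * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  frame_pose(frame_id, rotmat_to_quat(R), as.numeric(-R %*% C), camera_id,
             name = name)
}

# change exactly k pixels of a frame (values guaranteed to differ)
perturb_pixels <- function(frame, k, seed = 1L) {
  set.seed(seed)
  pos <- sample.int(length(frame), k)
  frame[pos] <- (frame[pos] + sample.int(255L, k, replace = TRUE)) %% 256L
  frame
}

noise_frame <- function(h = 100L, w = 100L, seed = 1L) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
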