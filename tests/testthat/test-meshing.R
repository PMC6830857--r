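test_that("PCA normals recover planar and spherical orientations", {
  set.seed(1)
  flat <- cbind(matrix(runif(600), 300, 2), 0)
  n <- estimate_normals(flat, k = 50L)
  expect_equal(abs(n[, 3]), rep(1, 300), tolerance = 1e-9)
  expect_equal(sqrt(rowSums(n^2)), rep(1, 300), tolerance = 1e-9)

  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  n3 <- estimate_normals(tri, k = 100L)   # k clamped to N - 1
  expect_equal(abs(n3[, 3]), rep(1, 3), tolerance = 1e-9)

  fx <- sphere_fixture()
  rad <- fx$scene$points / sqrt(rowSums(fx$scene$points^2))
  cosang <- abs(rowSums(fx$normals * rad))
  ang <- acos(pmin(cosang, 1)) * 180 / pi
  expect_gte(mean(ang <= 5), 0.99)
  expect_error(estimate_normals(tri[1:2, ]), ">= 3")
})

test_that("orientation flips normals toward observing cameras", {
  cam <- camera_intrinsics(1L, "PINHOLE", 64L, 64L, c(50, 50, 32, 32))
  pose <- frame_pose(1L, c(1, 0, 0, 0), c(0, 0, 0), 1L)  # centre at origin
  pose$xys <- matrix(c(32, 32), 1, 2)
  pose$point3d_ids <- 1L
  recon <- sparse_reconstruction(
    list(cam), list(pose),
    list(ids = 1L, xyz = matrix(c(0, 0, 1), 1, 3),
         rgb = matrix(0L, 1, 3), error = 0,
         track = list(matrix(c(1L, 1L), 1, 2))))
  p <- matrix(c(0, 0, 1), 1, 3)
  flipped <- orient_normals(p, matrix(c(0, 0, 1), 1, 3), recon = recon,
                            point_ids = 1L)
  expect_equal(flipped[1, ], c(0, 0, -1))
  # orthogonal normal (dot = 0) stays unflipped
  ortho <- orient_normals(p, matrix(c(1, 0, 0), 1, 3), recon = recon,
                          point_ids = 1L)
  expect_equal(ortho[1, ], c(1, 0, 0))
  # a point without a track uses the nearest camera centre
  noid <- orient_normals(p, matrix(c(0, 0, 1), 1, 3), recon = recon,
                         point_ids = NA_integer_)
  expect_equal(noid[1, ], c(0, 0, -1))
  expect_error(orient_normals(p, matrix(c(0, 0, 1), 1, 3),
                              recon = sparse_reconstruction(list(cam))),
               "no registered frames")

  # interior cameras orient a whole sphere inward
  fx <- sphere_fixture()
  rad <- fx$scene$points / sqrt(rowSums(fx$scene$points^2))
  expect_true(all(rowSums(fx$oriented * rad) < 0))
})

test_that("normal smoothing is a fixed point on uniform fields", {
  set.seed(2)
  pts <- matrix(runif(300), 100, 3)
  uni <- matrix(rep(c(0, 0, 1), each = 100), 100, 3)
  expect_equal(smooth_normals(pts, uni, k_smooth = 10L), uni,
               tolerance = 1e-12)
  expect_identical(smooth_normals(pts, uni, k_smooth = 1L), uni)

  # one flipped normal among aligned neighbours is restored
  flip <- uni
  flip[17, ] <- c(0, 0, -1)
  fixed <- smooth_normals(pts, flip, k_smooth = 10L)
  expect_equal(fixed[17, ], c(0, 0, 1), tolerance = 1e-12)
})

test_that("implicit reconstruction recovers the analytic sphere", {
  mesh <- sphere_mesh_d5()
  rad <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(sqrt(mean((rad - 1)^2)), 0.02)

  fx <- sphere_fixture()
  mesh4 <- reconstruct_mesh(fx$scene$points, fx$oriented, depth = 4L)
  expect_lt(nrow(mesh4$vertices), nrow(mesh$vertices))
  expect_error(reconstruct_mesh(matrix(numeric(), 0, 3),
                                matrix(numeric(), 0, 3)), ">= 4")
})

test_that("camera scoring ranks orthogonal and near cameras first", {
  mesh <- triangle_mesh(rbind(c(-0.5, -0.5, 0), c(0.5, -0.5, 0),
                              c(0, 1, 0)),   # centroid at the origin
                        matrix(c(1L, 2L, 3L), 1, 3))
  # the stored face normal points along +z for this vertex order
  cam <- camera_intrinsics(1L, "PINHOLE", 64L, 64L, c(50, 50, 32, 32))
  faceon <- pose_looking(1L, c(0, 0, 1), c(0, 0, -1))
  oblique <- pose_looking(2L, c(sin(pi / 3), 0, cos(pi / 3)),
                          -c(sin(pi / 3), 0, cos(pi / 3)))
  recon <- sparse_reconstruction(list(cam), list(faceon, oblique))
  sc <- score_cameras_for_face(1L, mesh, recon)
  expect_identical(sc$frame_id, c(1L, 2L))
  expect_equal(sc$angle_cos[1], 1, tolerance = 1e-9)
  expect_equal(sc$angle_cos[2], 0.5, tolerance = 1e-9)

  # two face-on cameras at distance d and 2d: nearer first
  far <- pose_looking(3L, c(0, 0, 2), c(0, 0, -1))
  recon2 <- sparse_reconstruction(list(cam), list(far, faceon))
  sc2 <- score_cameras_for_face(1L, mesh, recon2)
  expect_identical(sc2$frame_id, c(1L, 3L))

  # a camera behind the face is excluded
  behind <- pose_looking(4L, c(0, 0, -1), c(0, 0, 1))
  recon3 <- sparse_reconstruction(list(cam), list(behind))
  expect_identical(nrow(score_cameras_for_face(1L, mesh, recon3)), 0L)
})

test_that("vertex colors come from the top-ranked camera", {
  mesh <- triangle_mesh(rbind(c(-0.5, -0.5, 0), c(0.5, -0.5, 0),
                              c(0, 1, 0)),
                        matrix(c(1L, 2L, 3L), 1, 3),
                        normals = matrix(rep(c(0, 0, 1), each = 3), 3, 3))
  cam <- camera_intrinsics(1L, "PINHOLE", 64L, 64L, c(50, 50, 32, 32))
  p1 <- pose_looking(1L, c(0, 0, 2), c(0, 0, -1), name = "im1")
  p2 <- pose_looking(2L, c(0, 0, 4), c(0, 0, -1), name = "im2")
  recon <- sparse_reconstruction(list(cam), list(p1, p2))
  img <- function(rgb) {
    a <- array(0L, c(64, 64, 3))
    for (ch in 1:3) a[, , ch] <- rgb[ch]
    a
  }
  frames <- frame_sequence(list(img(c(200, 0, 0)), img(c(0, 200, 0))),
                           channel = "RGB", names = c("im1", "im2"))
  colored <- transfer_vertex_colors(mesh, recon, frames)
  best <- score_cameras_for_face(1L, mesh, recon)$frame_id[1]
  expect_identical(best, 1L)
  for (i in 1:3) expect_identical(colored$colors[i, ], c(200L, 0L, 0L))

  # a vertex no camera sees keeps sentinel gray
  mesh2 <- triangle_mesh(rbind(c(-0.5, -0.5, 0), c(0.5, -0.5, 0),
                               c(0, 0.5, 10)),
                         matrix(c(1L, 2L, 3L), 1, 3),
                         normals = matrix(rep(c(0, 0, 1), each = 3), 3, 3))
  colored2 <- transfer_vertex_colors(mesh2, recon, frames)
  expect_identical(colored2$colors[3, ], c(128L, 128L, 128L))
})
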