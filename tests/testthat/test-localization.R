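test_that("the downsample descriptor is deterministic and scale invariant", {
  const <- matrix(37L, 40, 40)
  d <- compute_descriptor(const)
  expect_identical(d$vector, rep(0, 256))

  fr <- noise_frame(48, 40, seed = 1)
  expect_identical(compute_descriptor(fr)$vector,
                   compute_descriptor(fr)$vector)

  # halving brightness leaves the mean-subtracted, L2-normalized vector
  even <- (noise_frame(48, 40, seed = 2) %/% 2L) * 2L
  half <- even %/% 2L
  expect_equal(compute_descriptor(even)$vector,
               compute_descriptor(half)$vector, tolerance = 1e-12)

  expect_error(compute_descriptor(fr, method = "cnn"), "unsupported")
})

test_that("retrieval equals brute-force distance sorting", {
  fs <- make_frame_sequence(80L, list(c(5L, 3L)), seed = 3L)
  seq <- fs$sequence
  rr <- retrieve_similar(7L, seq, n = 80L)
  D <- t(vapply(seq$frames, function(f) compute_descriptor(f)$vector,
                numeric(256)))
  d <- sqrt(colSums((t(D) - D[7, ])^2))
  expect_identical(rr$ranked$frame_id, order(d, seq_len(80) != 7, seq_len(80)))
  expect_identical(rr$ranked$frame_id[1], 7L)
  expect_identical(rr$ranked$distance[1], 0)
  expect_true(all(diff(rr$ranked$distance) >= 0))

  # duplicates of the reference land at distance zero
  dup_of_7 <- which(vapply(seq$frames, identical, TRUE, seq$frames[[7]]))
  expect_setequal(rr$ranked$frame_id[seq_along(dup_of_7)], dup_of_7)

  expect_warning(retrieve_similar(1L, seq, n = 200L), "clamped")
  expect_error(retrieve_similar(999L, seq), "not in sequence")
})

test_that("externally supplied descriptors drive the ranking", {
  frames <- rep(list(matrix(0L, 8, 8)), 4)
  seq <- frame_sequence(frames, channel = "R")
  D <- rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0))
  rr <- retrieve_similar(1L, seq, n = 4L, descriptors = D)
  expect_identical(rr$ranked$frame_id, 1:4)
  expect_equal(rr$ranked$distance, c(0, 1, 2, 3))
})

test_that("descriptor distance behaves like a metric", {
  fs <- make_frame_sequence(12L, list(), seed = 4L)
  D <- t(vapply(fs$sequence$frames,
                function(f) compute_descriptor(f)$vector, numeric(256)))
  d <- function(i, j) sqrt(sum((D[i, ] - D[j, ])^2))
  for (i in 1:6) expect_identical(d(i, i), 0)
  for (i in 1:5) expect_equal(d(i, i + 1), d(i + 1, i))
  set.seed(5)
  for (rep in 1:25) {
    ijk <- sample(12L, 3)
    expect_lte(d(ijk[1], ijk[3]),
               d(ijk[1], ijk[2]) + d(ijk[2], ijk[3]) + 1e-12)
  }
})

test_that("frame localization casts pixel rays onto the mesh", {
  fx <- sphere_fixture()
  mesh <- sphere_mesh_d5()
  fp <- localize_frame(1L, fx$recon, mesh, ray_grid = 16L)
  expect_equal(fp$coverage_fraction, 1)   # closed surface around the camera
  # hits lie on their faces' planes
  fn <- face_normals(mesh)
  fc <- face_centroids(mesh)
  res <- abs(rowSums((fp$hit_points - fc[fp$hit_faces, ]) *
                       fn[fp$hit_faces, ]))
  expect_lt(max(res), 1e-6 * bbox_diagonal(mesh$vertices))
  expect_error(localize_frame(999L, fx$recon, mesh), "not registered")

  # a camera looking away from an open surface hits nothing
  cam <- camera_intrinsics(1L, "PINHOLE", 64L, 64L, c(50, 50, 32, 32))
  away <- pose_looking(1L, c(0, 0, 0), c(0, 0, -1))
  recon <- sparse_reconstruction(list(cam), list(away))
  wall <- triangle_mesh(rbind(c(-5, -5, 3), c(5, -5, 3), c(0, 5, 3)),
                        matrix(c(1L, 2L, 3L), 1, 3))
  fp0 <- localize_frame(1L, recon, wall, ray_grid = 8L)
  expect_identical(fp0$coverage_fraction, 0)
})

test_that("axis-aligned cube hits match analytic ray-plane intersections", {
  cube <- unit_cube_mesh()
  cam <- camera_intrinsics(1L, "PINHOLE", 64L, 64L, c(100, 100, 32, 32))
  pose <- pose_looking(1L, c(0, 0, 0), c(0, 0, 1))
  recon <- sparse_reconstruction(list(cam), list(pose))
  fp <- localize_frame(1L, recon, cube, ray_grid = 8L)
  expect_equal(fp$coverage_fraction, 1)
  # with f = 100 all rays of the 8x8 grid hit the z = +0.5 face first
  dirs <- cbind((fp$hit_pixels[, 1] - 32) / 100,
                (fp$hit_pixels[, 2] - 32) / 100, 1)
  analytic <- dirs * (0.5 / dirs[, 3])
  expect_equal(fp$hit_points, unname(analytic), tolerance = 1e-9)
})

test_that("local-frame selection is the deterministic ranking prefix", {
  fs <- make_frame_sequence(30L, list(c(4L, 2L)), seed = 6L)
  ids <- select_local_frames(3L, fs$sequence, n = 5L)
  expect_length(ids, 5L)
  expect_true(all(ids %in% fs$sequence$index))
  expect_identical(ids, select_local_frames(3L, fs$sequence, n = 5L))
  rr <- retrieve_similar(3L, fs$sequence, n = 10L)
  expect_identical(ids, rr$ranked$frame_id[1:5])
})
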