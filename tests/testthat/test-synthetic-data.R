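test_that("the cavity surface has exact radial geometry", {
  ell <- make_surface(semi_axes = c(3, 2, 1.5), bump_amplitude = 0,
                      bump_count = 0L)
  expect_equal(surface_radius(ell, matrix(c(1, 0, 0), 1, 3)), 3)
  expect_equal(surface_radius(ell, matrix(c(0, 0, -2), 1, 3)), 1.5)
  # a point on the surface has zero signed distance; the centre is inside
  p <- matrix(c(3, 0, 0), 1, 3)
  expect_equal(surface_signed_distance(ell, p), 0)
  expect_lt(surface_signed_distance(ell, matrix(0, 1, 3)), 0)
  expect_error(make_surface(bump_amplitude = 1.2), "self-intersection")

  # dense triangulated area vs the Thomsen closed-form approximation
  a <- 3; b <- 2; cc <- 1.5; pp <- 1.6075
  thomsen <- 4 * pi * (((a * b)^pp + (a * cc)^pp + (b * cc)^pp) / 3)^(1 / pp)
  expect_lt(abs(surface_area(ell, n = 200L) - thomsen) / thomsen, 0.02)
})

test_that("sampled clouds honor their label contracts", {
  surf <- make_surface(seed = 1L)
  clean <- sample_cloud(surf, n_inliers = 300L, n_isolated = 0L,
                        n_near = 0L, seed = 2L)
  expect_true(all(clean$labels == "INLIER"))
  # inliers lie within 3 sigma of the surface (radial noise is truncated)
  sd3 <- abs(surface_signed_distance(surf, clean$points))
  expect_true(all(sd3 <= 3 * clean$noise_sigma + 1e-12))

  scene <- sample_cloud(surf, n_inliers = 800L, n_isolated = 80L,
                        n_near = 80L, seed = 3L)
  expect_identical(as.vector(table(scene$labels)), c(800L, 80L, 80L))
  r <- bbox_diagonal(scene$points)
  iso <- scene$points[scene$labels == "ISOLATED_OUTLIER", ]
  rest <- scene$points[scene$labels != "ISOLATED_OUTLIER", ]
  # exhaustive check: every isolated outlier is beyond A * r of every point
  dm <- as.matrix(dist(rbind(iso, rest)))[seq_len(80), ]
  diag(dm[, seq_len(80)]) <- Inf
  expect_true(all(apply(dm, 1, min) > scene$A * r))
  # near outliers sit 5-15 sigma off the surface
  off <- abs(surface_signed_distance(surf,
                                     scene$points[scene$labels ==
                                                    "NEAR_OUTLIER", ]))
  expect_true(all(off >= 5 * scene$noise_sigma - 1e-9))
  expect_true(all(off <= 15 * scene$noise_sigma + 1e-9))

  # fixed seed reproduces the cloud bit for bit
  again <- sample_cloud(surf, n_inliers = 800L, n_isolated = 80L,
                        n_near = 80L, seed = 3L)
  expect_identical(again$points, scene$points)
})

test_that("camera trajectories stay inside and export valid models", {
  surf <- make_surface(seed = 4L)
  scene <- sample_cloud(surf, n_inliers = 500L, n_isolated = 0L,
                        n_near = 0L, seed = 5L)
  recon <- make_trajectory_and_tracks(surf, scene, n_cameras = 30L,
                                      points_per_view = 150L)
  centers <- t(vapply(recon$frames, camera_center, numeric(3)))
  expect_true(all(surface_signed_distance(surf, centers) < 0))
  expect_true(all(vapply(recon$points$track, nrow, 0L) >= 1L))
  expect_silent(validate_reconstruction(recon))
  expect_error(make_trajectory_and_tracks(surf, scene, n_cameras = 1L),
               "at least 2")

  dir <- withr::local_tempdir()
  write_colmap_sparse(recon, dir)
  back <- read_colmap_sparse(dir)
  expect_identical(back$points$track, recon$points$track)
  expect_equal(back$points$xyz, recon$points$xyz, tolerance = 1e-12)
})

test_that("duplicate-frame fixtures know their ground truth", {
  # runs starting at 1 and 6 over 8 frames
  fs <- make_frame_sequence(8L, list(c(1L, 3L), c(6L, 2L)), seed = 6L)
  expect_identical(fs$kept_truth, c(1L, 4L, 5L, 6L, 8L))
  dd <- remove_duplicates(fs$sequence, phi = 0.6)
  expect_identical(dd$report$kept_indices, fs$kept_truth)

  # unit-length runs: nothing is a duplicate
  fs1 <- make_frame_sequence(6L, list(c(2L, 1L), c(4L, 1L)), seed = 7L)
  expect_identical(fs1$kept_truth, 1:6)
  dd1 <- remove_duplicates(fs1$sequence, phi = 0.6)
  expect_identical(dd1$report$removed_indices, integer(0))

  # frames are bit-identical within a run
  expect_identical(fs$sequence$frames[[1]], fs$sequence$frames[[3]])
  expect_false(identical(fs$sequence$frames[[3]], fs$sequence$frames[[4]]))

  # an ambiguous fixture is a spec error
  expect_error(make_frame_sequence(8L, list(), perturbation_fraction = 0.5,
                                   phi = 0.6), "spec error")
  expect_error(make_frame_sequence(8L, list(c(1L, 3L), c(3L, 2L))),
               "overlap")

  # determinism
  fs2 <- make_frame_sequence(8L, list(c(1L, 3L), c(6L, 2L)), seed = 6L)
  expect_identical(fs2$sequence$frames, fs$sequence$frames)
})
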