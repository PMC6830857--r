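test_that("bounding-box diagonal matches the direct formula", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(bbox_diagonal(cube), sqrt(3))
  expect_equal(bbox_diagonal(matrix(c(2, 5, -1), 1, 3)), 0)
  set.seed(1)
  pts <- matrix(runif(3000, 0, 2), 1000, 3)
  ext <- apply(pts, 2, max) - apply(pts, 2, min)
  expect_equal(bbox_diagonal(pts), sqrt(sum(ext^2)))
  expect_error(bbox_diagonal(matrix(numeric(), 0, 3)), "empty")
})

test_that("isolated-point filter equals the exhaustive oracle", {
  set.seed(2)
  pts <- rbind(matrix(runif(3000), 1000, 3), c(3, 3, 3))
  st <- remove_isolated(pts, A = 0.05)
  expect_false(1001L %in% st$ids)
  expect_identical(st$ids, which(isolated_oracle_keep(pts, 0.05)))
  # stage r is recomputed on survivors
  expect_equal(st$r, bbox_diagonal(pts[st$ids, ]))

  # regular grid, and a handful of random labeled clouds
  grid <- as.matrix(expand.grid(0:9, 0:9, 0:9)) * 0.01
  dimnames(grid) <- NULL
  stg <- remove_isolated(grid, A = 0.05)
  expect_identical(stg$ids, which(isolated_oracle_keep(grid, 0.05)))
  for (seed in 3:6) {
    set.seed(seed)
    n <- sample(100:500, 1)
    cl <- rbind(matrix(rnorm(3 * n), n, 3),
                matrix(runif(9, 4, 8), 3, 3))
    st2 <- remove_isolated(cl, A = 0.05)
    expect_identical(st2$ids, which(isolated_oracle_keep(cl, 0.05)))
  }

  # all-coincident cloud: r = 0 and NN distance 0 <= 0, everything kept
  co <- matrix(1, 10, 3)
  expect_identical(remove_isolated(co, A = 0.05)$ids, 1:10)
  expect_error(remove_isolated(matrix(0, 1, 3)), "at least 2")
})

test_that("neighbourhood gathering applies cap, census and tie rules", {
  set.seed(7)
  pts <- matrix(rnorm(450), 150, 3)
  st <- point_cloud_stage(pts, stage = "P_prime")
  cfg <- cleaning_config(M = 80L, neighbor_cap = 100L)
  nb <- gather_neighborhood(1L, st, cfg)
  expect_length(nb, 100L)   # 149 in-radius candidates, capped at the 100 nearest
  d <- sqrt(colSums((t(pts) - pts[1, ])^2))
  expect_identical(sort(d[nb]), sort(sort(d[-1])[1:100]))

  # fewer than M in-radius neighbours -> outlier mark
  tight <- point_cloud_stage(matrix(rnorm(150), 50, 3), stage = "P_prime")
  expect_null(gather_neighborhood(1L, tight, cfg))

  # tie at the cap boundary: lowest index wins
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0),
                c(0, -1, 0), c(0, 0, 1))  # two tied candidates at distance 1
  st3 <- point_cloud_stage(base, stage = "P_prime")
  cfg3 <- cleaning_config(M = 3L, neighbor_cap = 3L)
  nb3 <- gather_neighborhood(1L, st3, cfg3)
  expect_length(nb3, 3L)
  expect_identical(nb3, c(2L, 3L, 4L))  # 5 and 6 tie with 4; lowest index
})

test_that("RANSAC plane fitting matches brute-force triple enumeration", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  fit <- ransac_plane(tri, iters = 10L, seed = 1L)
  expect_equal(abs(fit$normal[3]), 1, tolerance = 1e-12)
  expect_equal(max(fit$dists), 0, tolerance = 1e-12)

  set.seed(8)
  flat <- cbind(matrix(runif(200), 100, 2), 0)
  spike <- cbind(matrix(runif(10), 5, 2), 5)
  pts <- rbind(flat, spike)
  fit2 <- ransac_plane(pts, iters = choose(105, 3), seed = 1L)
  expect_equal(abs(fit2$normal[3]), 1, tolerance = 1e-9)
  expect_equal(fit2$offset, 0, tolerance = 1e-9)
  expect_identical(fit2$inlier_count, 100L)

  # coplanar cloud: every residual is zero
  fit3 <- ransac_plane(flat, iters = 50L, seed = 2L)
  expect_equal(max(fit3$dists), 0, tolerance = 1e-12)

  # all-collinear input is degenerate
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(ransac_plane(line, iters = 20L, seed = 1L), "degenerate")

  # deterministic under a fixed seed, exhaustive agrees with the R oracle
  set.seed(9)
  for (rep in 1:12) {
    npl <- sample(6:12, 1)
    noff <- sample(0:3, 1)
    u <- matrix(rnorm(6), 2, 3)
    pl <- matrix(rnorm(npl * 2), npl, 2) %*% u
    pts <- rbind(pl, matrix(rnorm(noff * 3), noff, 3) * 2 + 5)
    eps <- 0.01 * bbox_diagonal(pts)
    a <- ransac_plane(pts, iters = choose(nrow(pts), 3), seed = 3L, eps = eps)
    b <- ransac_plane(pts, iters = choose(nrow(pts), 3), seed = 99L, eps = eps)
    expect_identical(a$normal, b$normal)
    orc <- plane_oracle(pts, eps)
    expect_identical(a$inlier_count, orc$count)
    expect_equal(abs(sum(a$normal * orc$normal)), 1, tolerance = 1e-9)
  }
})

test_that("plane-fit filter removes exactly the above-average points", {
  set.seed(4)
  base <- cbind(runif(200), runif(200), 0)
  off <- cbind(runif(10), runif(10), 1)
  st <- point_cloud_stage(rbind(base, off), stage = "P_prime")
  pf <- plane_fit_filter(st, cleaning_config(ransac_seed = 1L))
  expect_identical(sort(pf$report$removed_plane), 201:210)
  expect_equal(pf$report$avg_D, 10 / 210, tolerance = 1e-9)
  expect_identical(pf$stage$ids, 1:200)
  expect_identical(pf$stage$stage, "P_hat")

  # perfectly planar cloud: all D = 0, strict comparison keeps everything
  stp <- point_cloud_stage(cbind(matrix(runif(400), 200, 2), 0),
                           stage = "P_prime")
  pf2 <- plane_fit_filter(stp, cleaning_config(ransac_seed = 1L))
  expect_identical(nrow(pf2$stage$points), 200L)
  expect_equal(pf2$report$avg_D, 0)

  # every point sparse -> empty stage with a warning
  sp <- point_cloud_stage(matrix(rnorm(60), 20, 3), stage = "P_prime")
  expect_warning(pf3 <- plane_fit_filter(sp, cleaning_config()), "census")
  expect_identical(nrow(pf3$stage$points), 0L)
})

test_that("smooth-mesh filter removes far points and respects the B limit", {
  surf <- make_surface(semi_axes = c(1, 1, 1), bump_amplitude = 0,
                       bump_count = 0L)
  scene <- sample_cloud(surf, n_inliers = 2000L, noise_sigma = 0.01,
                        n_isolated = 0L, n_near = 0L, seed = 10L)
  pts <- scene$points
  set.seed(11)
  dirs <- matrix(rnorm(90), 30, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  planted <- dirs * (1 + 10 * 0.01)   # radial offset 10 sigma
  all_pts <- rbind(pts, planted)
  st <- point_cloud_stage(all_pts, stage = "P_hat")
  sm <- smooth_mesh_filter(st, cleaning_config(B = 5))
  planted_ids <- 2000L + seq_len(30L)
  expect_true(all(planted_ids %in% sm$report$removed_mesh))
  kept_inliers <- sum(sm$stage$ids <= 2000L)
  expect_gte(kept_inliers / 2000, 0.99)

  # B large enough keeps everything
  sm2 <- smooth_mesh_filter(st, cleaning_config(B = 1e6))
  expect_identical(nrow(sm2$stage$points), nrow(all_pts))
  expect_error(smooth_mesh_filter(point_cloud_stage(matrix(numeric(), 0, 3),
                                                    ids = integer(),
                                                    stage = "P_hat")),
               "empty")
})

test_that("the cascade is monotone, deterministic and parameter-consistent", {
  surf <- make_surface(seed = 12L)
  scene <- sample_cloud(surf, n_inliers = 1200L, n_isolated = 60L,
                        n_near = 60L, seed = 13L)
  cfg <- cleaning_config(ransac_seed = 5L)
  res <- run_outlier_removal(scene$points, cfg)
  sz <- res$report$stage_sizes
  expect_true(all(diff(sz) <= 0))
  expect_identical(sum(lengths(res$report$removed_per_stage)) +
                     nrow(res$stage$points), nrow(scene$points))

  res2 <- run_outlier_removal(scene$points, cfg)
  expect_identical(res$stage$ids, res2$stage$ids)
  expect_identical(res$report$removed_per_stage,
                   res2$report$removed_per_stage)

  # recall of planted isolated outliers is non-increasing in A
  iso_ids <- which(scene$labels == "ISOLATED_OUTLIER")
  recall_iso <- vapply(c(0.02, 0.05, 0.12), function(A) {
    st <- remove_isolated(scene$points, A = A)
    mean(!(iso_ids %in% st$ids))
  }, 0)
  expect_true(all(diff(recall_iso) <= 0))
  expect_equal(recall_iso[2], 1)   # planted against the default A

  # shrinking B removes more points
  p_hat <- plane_fit_filter(remove_isolated(scene$points, cfg$A), cfg)$stage
  survivors <- vapply(c(2, 5, 10), function(B) {
    nrow(smooth_mesh_filter(p_hat, cleaning_config(B = B,
                                                   ransac_seed = 5L))$stage$points)
  }, 0L)
  expect_true(all(diff(survivors) >= 0))
})

test_that("the cascade accepts a sparse reconstruction as input", {
  surf <- make_surface(seed = 14L)
  scene <- sample_cloud(surf, n_inliers = 600L, n_isolated = 30L,
                        n_near = 0L, seed = 15L)
  recon <- make_trajectory_and_tracks(surf, scene, n_cameras = 30L,
                                      points_per_view = 150L)
  # reconstruction only carries inliers; isolated outliers never had tracks
  res <- run_outlier_removal(recon, cleaning_config(M = 50L,
                                                    neighbor_cap = 80L))
  expect_true(all(res$stage$ids %in% recon$points$ids))
  expect_error(run_outlier_removal(matrix(rnorm(30), 10, 3),
                                   cleaning_config()), "M \\+ 1")
})
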