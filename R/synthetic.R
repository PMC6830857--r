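# Fully labeled synthetic scenes: a closed, bumpy, star-shaped cavity
# surface (radial function over directions, so an exact signed distance is
# available for oracles), a noisy point cloud with planted isolated and
# near-surface outliers, an interior camera trajectory with feature tracks,
# and frame sequences with planted duplicate runs.  Anatomical realism is a
# non-goal; the generator exists so that every downstream precision/recall
# number is well defined.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Define a closed bumpy cavity surface
#'
#' A star-shaped radial surface `R(u) = r_ellipsoid(u) * (1 + amplitude *
#' sum of smooth angular Gaussian bumps)` over unit directions `u`.  The
#' bumps emulate local relief such as mucosal folds; amplitude must stay
#' below 1 to rule out self-intersection.
#'
#' @param semi_axes ellipsoid semi-axes (default `c(3, 2, 1.5)` scene units,
#'   stomach-like proportions in arbitrary reconstruction units).
#' @param bump_amplitude relative bump height (default 0.06).
#' @param bump_count number of bumps (default 12).
#' @param bump_width angular bump width in radians (default 0.35).
#' @param seed RNG seed for bump placement.
#' @return An object of class `cavity_surface`.
#' @export
make_surface <- function(semi_axes = c(3, 2, 1.5), bump_amplitude = 0.06,
                         bump_count = 12L, bump_width = 0.35, seed = 1L) {
  stopifnot(all(semi_axes > 0), bump_count >= 0)
  if (bump_amplitude >= 1)
    stop("bump_amplitude must be < 1 (self-intersection risk)", call. = FALSE)
  centers <- matrix(numeric(), 0, 3)
  widths <- numeric()
  if (bump_count > 0) {
    centers <- with_seed(seed, {
      m <- matrix(rnorm(3 * bump_count), bump_count, 3)
      m / sqrt(rowSums(m^2))
    })
    widths <- rep(bump_width, bump_count)
  }
  structure(list(semi_axes = as.numeric(semi_axes),
                 bump_amplitude = bump_amplitude, centers = centers,
                 widths = widths, seed = as.integer(seed)),
            class = "cavity_surface")
}

#' Radial extent of a cavity surface along directions
#'
#' @param surface a [make_surface()] object.
#' @param dirs N x 3 matrix of directions (normalized internally).
#' @return Numeric vector of radii `R(u)`.
#' @export
surface_radius <- function(surface, dirs) {
  dirs <- as_points3(dirs, "dirs")
  u <- dirs / sqrt(rowSums(dirs^2))
  a <- surface$semi_axes
  r_ell <- 1 / sqrt((u[, 1] / a[1])^2 + (u[, 2] / a[2])^2 +
                      (u[, 3] / a[3])^2)
  bump <- rep(0, nrow(u))
  for (j in seq_len(nrow(surface$centers))) {
    cosang <- pmin(pmax(as.numeric(u %*% surface$centers[j, ]), -1), 1)
    theta <- acos(cosang)
    bump <- bump + exp(-theta^2 / (2 * surface$widths[j]^2))
  }
  as.numeric(r_ell * (1 + surface$bump_amplitude * bump))
}

#' Radial signed distance to a cavity surface
#'
#' `||x|| - R(x/||x||)`: negative inside the cavity, zero on the surface.
#' Exact for spheres; for general shapes it is the radial (not Euclidean)
#' distance, which is what the generator's label contracts use.
#'
#' @param surface a [make_surface()] object.
#' @param points N x 3 matrix.
#' @return Numeric vector of signed radial distances.
#' @export
surface_signed_distance <- function(surface, points) {
  points <- as_points3(points)
  len <- sqrt(rowSums(points^2))
  out <- numeric(nrow(points))
  zero <- len < 1e-300
  if (any(!zero))
    out[!zero] <- len[!zero] - surface_radius(surface,
                                              points[!zero, , drop = FALSE])
  # the center is inside by the full local radius
  if (any(zero)) out[zero] <- -min(surface$semi_axes)
  out
}

#' Numeric surface area of a cavity surface
#'
#' Triangulates the radial parametrization on an `n x 2n` angular grid and
#' sums triangle areas.
#'
#' @param surface a [make_surface()] object.
#' @param n polar grid resolution (default 256).
#' @return Scalar area.
#' @export
surface_area <- function(surface, n = 256L) {
  theta <- seq(0, pi, length.out = n + 1L)
  phi <- seq(0, 2 * pi, length.out = 2L * n + 1L)
  grid <- expand.grid(theta = theta, phi = phi)
  u <- cbind(sin(grid$theta) * cos(grid$phi),
             sin(grid$theta) * sin(grid$phi), cos(grid$theta))
  p <- u * surface_radius(surface, u)
  nt <- n + 1L
  idx <- function(i, j) (j - 1L) * nt + i
  i <- rep(seq_len(n), times = 2L * n)
  j <- rep(seq_len(2L * n), each = n)
  a <- p[idx(i, j), , drop = FALSE]
  b <- p[idx(i + 1L, j), , drop = FALSE]
  cc <- p[idx(i + 1L, j + 1L), , drop = FALSE]
  d <- p[idx(i, j + 1L), , drop = FALSE]
  tri_area <- function(x, y, z) {
    e1 <- y - x; e2 <- z - x
    0.5 * sqrt(pmax(rowSums(e1^2) * rowSums(e2^2) - rowSums(e1 * e2)^2, 0))
  }
  sum(tri_area(a, b, cc)) + sum(tri_area(a, cc, d))
}

#' Sample a labeled synthetic point cloud from a cavity surface
#'
#' Inliers are surface samples with radial Gaussian noise; near outliers sit
#' at radial offsets uniform in `[5, 15] * noise_sigma * near_scale` (random
#' sign); isolated outliers are rejection-sampled in a padded box so that,
#' by construction, each lies farther than `A * r` (r = bounding-box
#' diagonal of the final cloud) from every other point.  Label contracts are
#' verified exhaustively before returning.
#'
#' @param surface a [make_surface()] object.
#' @param n_inliers,n_isolated,n_near point counts (defaults 5000/500/500).
#' @param noise_sigma radial noise standard deviation in scene units
#'   (default 0.03, about 0.4% of the default surface's bounding box).
#' @param near_scale multiplier on the near-outlier offset band (default 1).
#' @param A isolation scale the planted isolated outliers are defined
#'   against (default 0.05, the cascade default).
#' @param box_scale padded-box half-width as a multiple of the maximum
#'   surface radius (default 2.5).
#' @param seed RNG seed; fixed seed gives a bit-identical cloud.
#' @return An object of class `synthetic_scene` with `points` (N x 3),
#'   `labels` (factor: `INLIER`, `NEAR_OUTLIER`, `ISOLATED_OUTLIER`),
#'   `surface`, `noise_sigma`, `seed`.
#' @export
sample_cloud <- function(surface, n_inliers = 5000L, noise_sigma = 0.03,
                         n_isolated = 500L, n_near = 500L, near_scale = 1,
                         A = 0.05, box_scale = 2.5, seed = 1L) {
  stopifnot(n_inliers >= 0, n_isolated >= 0, n_near >= 0, noise_sigma >= 0)
  res <- with_seed(seed, {
    rand_dirs <- function(n) {
      m <- matrix(rnorm(3 * n), n, 3)
      m / sqrt(rowSums(m^2))
    }
    u_in <- rand_dirs(max(n_inliers, 1L))[seq_len(n_inliers), , drop = FALSE]
    noise <- rnorm(n_inliers, 0, noise_sigma)
    # truncate at 3 sigma so the inlier label contract (within 3 sigma of
    # the surface) holds exactly, keeping them separated from near outliers
    while (any(bad <- abs(noise) > 3 * noise_sigma))
      noise[bad] <- rnorm(sum(bad), 0, noise_sigma)
    r_in <- surface_radius(surface, u_in) + noise
    inliers <- u_in * r_in

    u_nr <- rand_dirs(max(n_near, 1L))[seq_len(n_near), , drop = FALSE]
    off <- runif(n_near, 5, 15) * noise_sigma * near_scale *
      sample(c(-1, 1), n_near, replace = TRUE)
    near <- u_nr * (surface_radius(surface, u_nr) + off)

    r_max <- max(surface$semi_axes) * (1 + surface$bump_amplitude *
                                         max(1L, nrow(surface$centers)))
    outer <- box_scale * r_max
    s_min <- A * 2 * sqrt(3) * outer   # upper bound on A * r of the cloud
    base <- rbind(inliers, near)
    isolated <- matrix(numeric(), 0, 3)
    tries <- 0L
    budget <- 400L * max(n_isolated, 1L)
    while (nrow(isolated) < n_isolated) {
      if (tries >= budget)
        stop("isolated-outlier rejection sampling exceeded its retry budget",
             call. = FALSE)
      tries <- tries + 1L
      cand <- matrix(runif(3, -outer, outer), 1, 3)
      ok <- TRUE
      if (nrow(base) && min(cpp_min_dists(cand, base)) < s_min) ok <- FALSE
      if (ok && nrow(isolated) &&
          min(cpp_min_dists(cand, isolated)) < s_min) ok <- FALSE
      if (ok) isolated <- rbind(isolated, cand)
    }
    list(inliers = inliers, near = near, isolated = isolated)
  })
  points <- rbind(res$inliers, res$near, res$isolated)
  labels <- factor(rep(c("INLIER", "NEAR_OUTLIER", "ISOLATED_OUTLIER"),
                       c(n_inliers, n_near, n_isolated)),
                   levels = c("INLIER", "NEAR_OUTLIER", "ISOLATED_OUTLIER"))
  # exhaustive verification of the planted-label contracts
  if (n_isolated > 0 && nrow(points) > n_isolated) {
    r_final <- bbox_diagonal(points)
    iso <- points[labels == "ISOLATED_OUTLIER", , drop = FALSE]
    rest <- points[labels != "ISOLATED_OUTLIER", , drop = FALSE]
    d_rest <- cpp_min_dists(iso, rest)
    d_iso <- if (nrow(iso) > 1) cpp_nn_dists(iso) else Inf
    if (any(pmin(d_rest, d_iso) <= A * r_final))
      stop("internal error: isolated-outlier contract violated",
           call. = FALSE)
  }
  structure(list(surface = surface, points = points, labels = labels,
                 noise_sigma = noise_sigma, near_scale = near_scale,
                 A = A, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("<synthetic_scene>", nrow(x$points), "points (",
      paste(levels(x$labels), table(x$labels), sep = "=", collapse = ", "),
      "), noise_sigma =", x$noise_sigma, "\n")
  invisible(x)
}

#' Build an interior camera trajectory with feature tracks
#'
#' Places `n_cameras` on a smooth spiral strictly inside the surface, each
#' looking radially outward, and lets every camera observe its
#' `points_per_view` nearest visible inlier points.  Points seen by fewer
#' than `min_track` cameras after that pass get additional observations from
#' the nearest cameras that see them; points visible to fewer than
#' `min_track` cameras at all are left out of the reconstruction (with a
#' warning).  Observations and tracks are fully cross-linked.
#'
#' @param surface a [make_surface()] object.
#' @param scene a [sample_cloud()] scene on that surface.
#' @param n_cameras number of poses (>= 2; default 40).
#' @param points_per_view observations per camera (default 400).
#' @param image_size pixel dimensions (default 256 x 256).
#' @param focal focal length in pixels (default 70, a wide interior field of view).
#' @param center_scale camera distance from the origin as a fraction of the
#'   local surface radius (default 0.35).
#' @param min_track minimum track length for exported points (default 2).
#' @return A [sparse_reconstruction()] whose point ids are row indices into
#'   `scene$points`.
#' @export
make_trajectory_and_tracks <- function(surface, scene, n_cameras = 40L,
                                       points_per_view = 400L,
                                       image_size = c(256L, 256L),
                                       focal = 70, center_scale = 0.35,
                                       min_track = 2L) {
  if (n_cameras < 2L) stop("need at least 2 cameras", call. = FALSE)
  w <- image_size[1]; h <- image_size[2]
  cam <- camera_intrinsics(1L, "PINHOLE", w, h,
                           c(focal, focal, w / 2, h / 2))
  tt <- (seq_len(n_cameras) - 1L) / n_cameras
  theta <- (12 + 156 * tt) * pi / 180
  phi <- 6 * pi * tt
  u <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  centers <- u * (center_scale * surface_radius(surface, u))
  stopifnot(all(surface_signed_distance(surface, centers) < 0))

  inlier_rows <- which(scene$labels == "INLIER")
  pts <- scene$points[inlier_rows, , drop = FALSE]
  np <- nrow(pts)

  poses <- vector("list", n_cameras)
  obs_point <- vector("list", n_cameras)   # scene rows observed per camera
  obs_xy <- vector("list", n_cameras)
  proj_all <- vector("list", n_cameras)
  vis_all <- matrix(FALSE, np, n_cameras)
  for (ci in seq_len(n_cameras)) {
    z <- u[ci, ]
    up <- if (abs(z[3]) > 0.98) c(1, 0, 0) else c(0, 0, 1)
    x <- up - sum(up * z) * z
    x <- x / sqrt(sum(x^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])
    R <- rbind(x, y, z)
    dimnames(R) <- NULL
    tvec <- as.numeric(-R %*% centers[ci, ])
    pc <- t(R %*% t(pts) + tvec)
    uu <- focal * pc[, 1] / pc[, 3] + w / 2
    vv <- focal * pc[, 2] / pc[, 3] + h / 2
    vis <- pc[, 3] > 0 & uu >= 0 & uu < w & vv >= 0 & vv < h
    vis_all[, ci] <- vis
    proj_all[[ci]] <- cbind(uu, vv)
    dist <- sqrt(rowSums((pts - matrix(centers[ci, ], np, 3,
                                       byrow = TRUE))^2))
    cand <- which(vis)
    sel <- cand[order(dist[cand], cand)]
    sel <- head(sel, points_per_view)
    obs_point[[ci]] <- sel
    poses[[ci]] <- list(R = R, tvec = tvec)
  }

  # coverage pass: guarantee min_track observations where visibility allows
  n_seen <- tabulate(unlist(lapply(obs_point, identity)), nbins = np)
  camdist <- t(vapply(seq_len(n_cameras), function(ci) {
    sqrt(rowSums((pts - matrix(centers[ci, ], np, 3, byrow = TRUE))^2))
  }, numeric(np)))          # n_cameras x np
  dropped <- integer()
  for (pi in which(n_seen < min_track)) {
    seeing <- which(vis_all[pi, ])
    have <- which(vapply(obs_point, function(s) pi %in% s, TRUE))
    add <- setdiff(seeing, have)
    add <- add[order(camdist[add, pi], add)]
    need <- min_track - length(have)
    if (length(add) < need) {
      dropped <- c(dropped, pi)
      next
    }
    for (ci in head(add, need)) obs_point[[ci]] <- c(obs_point[[ci]], pi)
  }
  if (length(dropped)) {
    warning(length(dropped), " points visible to fewer than ", min_track,
            " cameras were left out of the reconstruction")
    for (ci in seq_len(n_cameras))
      obs_point[[ci]] <- setdiff(obs_point[[ci]], dropped)
  }
  exported <- sort(unique(unlist(obs_point)))

  frames <- vector("list", n_cameras)
  track <- rep(list(matrix(integer(), 0, 2)), length(exported))
  names(track) <- NULL
  exp_index <- match(seq_len(np), exported)   # scene inlier row -> export row
  for (ci in seq_len(n_cameras)) {
    sel <- obs_point[[ci]]
    xys <- proj_all[[ci]][sel, , drop = FALSE]
    ids3d <- inlier_rows[sel]
    q <- rotmat_to_quat(poses[[ci]]$R)
    frames[[ci]] <- frame_pose(ci, q, poses[[ci]]$tvec, 1L,
                               name = sprintf("frame_%06d.png", ci),
                               xys = xys, point3d_ids = ids3d)
    for (k in seq_along(sel)) {
      e <- exp_index[sel[k]]
      track[[e]] <- rbind(track[[e]], c(ci, k))
    }
  }
  points <- list(
    ids = inlier_rows[exported],
    xyz = pts[exported, , drop = FALSE],
    rgb = matrix(rep(c(180L, 130L, 120L), each = length(exported)),
                 ncol = 3),
    error = rep(0, length(exported)),
    track = track
  )
  sparse_reconstruction(list(cam), frames, points, validate = TRUE)
}

#' Generate a frame sequence with planted duplicate runs
#'
#' Base frames are procedural uint8 noise images.  Within a duplicate run
#' frames are bit-identical copies of the run's first frame; each new
#' distinct frame differs from the previous distinct frame in exactly
#' `round(perturbation_fraction * npixels)` pixels (values forced to
#' change), so every comparison the dedup loop makes has a known ratio.
#'
#' @param n_frames sequence length.
#' @param duplicate_runs list of `c(start, length)` pairs (1-based start
#'   positions, disjoint, length >= 1).
#' @param perturbation_fraction fraction of pixels redrawn between distinct
#'   frames; must exceed `phi` or the fixture would be ambiguous.
#' @param width,height frame size (default 64 x 64).
#' @param phi the dedup threshold the fixture is built for (default 0.6).
#' @param seed RNG seed.
#' @return List with `sequence` (single-channel [frame_sequence()]),
#'   `kept_truth` (1-based positions of the ground-truth kept set), and the
#'   generating parameters.
#' @export
make_frame_sequence <- function(n_frames, duplicate_runs = list(),
                                perturbation_fraction = 0.8, width = 64L,
                                height = 64L, phi = 0.6, seed = 1L) {
  if (perturbation_fraction <= phi)
    stop("spec error: perturbation_fraction must exceed phi, otherwise the ",
         "fixture is ambiguous", call. = FALSE)
  runs <- lapply(duplicate_runs, function(r) as.integer(r))
  starts <- vapply(runs, `[`, 0L, 1L)
  lens <- vapply(runs, `[`, 0L, 2L)
  stopifnot(all(lens >= 1L), all(starts >= 1L),
            all(starts + lens - 1L <= n_frames))
  covered <- unlist(mapply(function(s, l) seq(s, s + l - 1L), starts, lens,
                           SIMPLIFY = FALSE))
  if (anyDuplicated(covered)) stop("duplicate runs overlap", call. = FALSE)
  in_run_tail <- rep(FALSE, n_frames)
  for (r in runs)
    if (r[2] > 1L) in_run_tail[(r[1] + 1L):(r[1] + r[2] - 1L)] <- TRUE

  npix <- width * height
  k <- round(perturbation_fraction * npix)
  frames <- with_seed(seed, {
    out <- vector("list", n_frames)
    for (t in seq_len(n_frames)) {
      if (t == 1L) {
        f <- matrix(sample(0:255, npix, replace = TRUE), height, width)
      } else if (in_run_tail[t]) {
        f <- out[[t - 1L]]
      } else {
        f <- out[[t - 1L]]
        pos <- sample.int(npix, k)
        f[pos] <- (f[pos] + sample.int(255L, k, replace = TRUE)) %% 256L
      }
      out[[t]] <- f
    }
    out
  })
  kept_truth <- which(!in_run_tail)
  list(sequence = frame_sequence(frames, channel = "R"),
       kept_truth = kept_truth,
       spec = list(n_frames = n_frames, duplicate_runs = runs,
                   perturbation_fraction = perturbation_fraction,
                   phi = phi, width = width, height = height, seed = seed))
}
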