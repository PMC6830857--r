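# Four-stage point-cloud outlier removal:
#   P --(isolated-point filter, A*r)--> P'
#     --(neighborhood census, >= M in-radius neighbours)-->
#     --(local RANSAC plane fit, drop D > mean(D))--> P^
#     --(distance to a very smooth mesh, drop > B*sigma)--> P~
# All scale thresholds are relative to the bounding-box diagonal r of the
# current cloud, so the cascade is unit-free.

#' Cleaning-cascade configuration
#'
#' @param A isolated-point scale: a point whose nearest neighbour is farther
#'   than `A * r` is an isolated outlier (published default 0.05).
#' @param M minimum neighbourhood size for the census stage (default 80).
#' @param B smooth-mesh filter multiple: points farther than `B * sigma` from
#'   the smooth mesh are dropped (default 5).
#' @param neighbor_cap at most this many nearest neighbours form a local
#'   plane-fitting set (default 100).
#' @param ransac_iters random triples drawn per local fit (default 200).
#' @param ransac_seed integer seed making the whole cascade deterministic.
#' @param radius_scale multiplier on the neighbourhood-search radius `r`
#'   (the full recomputed bounding-box diagonal; default 1 keeps the radius
#'   literal — see Details).
#' @param plane_eps_scale RANSAC inlier band as a fraction of the local
#'   point set's bounding-box diagonal (default 0.01).
#' @param smooth_mesh_depth resolution exponent of the deliberately
#'   low-detail mesh used by the final stage (default 5).
#' @param smooth_mesh_k tangent-plane blending neighbours for that mesh
#'   (default 12).
#' @param sigma_floor_rel floor on sigma, relative to `r`, preventing total
#'   removal when all point-to-mesh distances are 0 (default 1e-12).
#'
#' @details A neighbourhood radius equal to the whole cloud's bounding-box
#' diagonal makes nearly every point an in-radius neighbour, so in practice
#' the `neighbor_cap` nearest points dominate the local sets; `radius_scale`
#' lets users shrink the radius if they want genuinely local censuses.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(A = 0.05, M = 80L, B = 5, neighbor_cap = 100L,
                            ransac_iters = 200L, ransac_seed = 0L,
                            radius_scale = 1, plane_eps_scale = 0.01,
                            smooth_mesh_depth = 5L, smooth_mesh_k = 12L,
                            sigma_floor_rel = 1e-12) {
  stopifnot(A > 0, M >= 3, B > 0, neighbor_cap >= M, ransac_iters >= 1,
            radius_scale > 0, plane_eps_scale > 0, smooth_mesh_depth >= 2,
            sigma_floor_rel >= 0)
  structure(list(A = A, M = as.integer(M), B = B,
                 neighbor_cap = as.integer(neighbor_cap),
                 ransac_iters = as.integer(ransac_iters),
                 ransac_seed = as.integer(ransac_seed),
                 radius_scale = radius_scale,
                 plane_eps_scale = plane_eps_scale,
                 smooth_mesh_depth = as.integer(smooth_mesh_depth),
                 smooth_mesh_k = as.integer(smooth_mesh_k),
                 sigma_floor_rel = sigma_floor_rel),
            class = "cleaning_config")
}

#' Bounding-box diagonal of a point cloud
#'
#' Euclidean length of the axis-aligned extent, the scale unit of the
#' cleaning cascade.
#'
#' @param points N x 3 matrix.
#' @return A non-negative real.
#' @export
bbox_diagonal <- function(points) {
  points <- as_points3(points)
  if (nrow(points) < 1L) stop("empty point cloud", call. = FALSE)
  ext <- apply(points, 2, function(v) max(v) - min(v))
  sqrt(sum(ext^2))
}

#' Remove isolated points
#'
#' Single pass: a point is removed when the distance to its nearest
#' neighbour (searched over the full input cloud) exceeds `A * r`, with `r`
#' the bounding-box diagonal of the input.  The returned stage carries the
#' recomputed diagonal of the survivors.
#'
#' @param points N x 3 matrix (N >= 2).
#' @param A isolation scale (default 0.05).
#' @param ids original point ids (default row numbers).
#' @return A [point_cloud_stage()] at stage `P_prime`.
#' @export
remove_isolated <- function(points, A = 0.05, ids = seq_len(nrow(points))) {
  points <- as_points3(points)
  if (nrow(points) < 2L)
    stop("isolated-point filter needs at least 2 points", call. = FALSE)
  r <- bbox_diagonal(points)
  nn <- cpp_nn_dists(points)
  keep <- nn <= A * r
  point_cloud_stage(points[keep, , drop = FALSE], ids = ids[keep],
                    stage = "P_prime")
}

#' Gather the local plane-fitting neighbourhood of one point
#'
#' Neighbours (excluding the centre) within radius `radius_scale * r` are
#' collected; if more than `neighbor_cap` qualify only the cap nearest are
#' returned (distance ties broken by lowest index); if fewer than `M`
#' qualify the point is marked as an outlier and `NULL` is returned.
#'
#' @param center_index row of the centre point in `stage$points`.
#' @param stage a [point_cloud_stage()] (carries the recomputed `r`).
#' @param cfg a [cleaning_config()].
#' @return Integer vector of neighbour row indices ordered by distance, or
#'   `NULL` (the outlier mark).
#' @export
gather_neighborhood <- function(center_index, stage, cfg = cleaning_config()) {
  pts <- stage$points
  radius <- stage$r * cfg$radius_scale
  d <- sqrt(colSums((t(pts) - pts[center_index, ])^2))
  d[center_index] <- Inf
  inside <- which(d <= radius)
  if (length(inside) < cfg$M) return(NULL)
  ord <- inside[order(d[inside], inside)]
  head(ord, cfg$neighbor_cap)
}

#' Fit a plane to a point set with RANSAC
#'
#' Candidate planes pass through three random points; the plane maximising
#' the inlier count at band `eps` wins, ties broken by the smaller sum of
#' inlier distances.  When `iters` is at least the number of distinct
#' triples, all triples are enumerated deterministically instead of sampled.
#'
#' @param points N x 3 matrix (N >= 3, not all collinear).
#' @param iters iteration budget (degenerate triples count against it when
#'   sampling).
#' @param seed RNG seed; a fixed seed gives a bit-identical result.
#' @param eps inlier distance band; default `0.01 *` the set's bounding-box
#'   diagonal.
#' @return List with `normal` (unit 3-vector), `offset` (plane is
#'   `normal . x + offset = 0`), `inlier_count`, `inliers` (row indices),
#'   and `dists` (all point-to-plane distances).
#' @export
ransac_plane <- function(points, iters = 200L, seed = 0L, eps = NULL) {
  points <- as_points3(points)
  if (nrow(points) < 3L) stop("plane fit needs >= 3 points", call. = FALSE)
  if (is.null(eps)) eps <- 0.01 * bbox_diagonal(points)
  res <- cpp_plane_ransac(points, as.integer(iters), eps, as.numeric(seed))
  if (!isTRUE(res$ok))
    stop("degenerate geometry: no non-collinear point triple found",
         call. = FALSE)
  list(normal = res$normal, offset = res$offset,
       inlier_count = as.integer(res$inlier_count),
       inliers = which(res$dists <= eps), dists = res$dists, eps = eps)
}

#' Census + local-plane-fit filter
#'
#' Every point of `P'` gets a local neighbourhood via the census rule of
#' [gather_neighborhood()]; marked points are removed outright.  For each
#' surviving point a local RANSAC plane is fitted to its neighbourhood and
#' the centre's point-to-plane distance `D` recorded.  The mean of all
#' recorded `D` is computed once, and points with `D` strictly above that
#' mean are removed.
#'
#' @param stage a `P_prime` [point_cloud_stage()].
#' @param cfg a [cleaning_config()].
#' @return List with `stage` (the `P_hat` [point_cloud_stage()]) and
#'   `report` (removed ids per sub-stage, per-point distances, `avg_D`).
#' @export
plane_fit_filter <- function(stage, cfg = cleaning_config()) {
  pts <- stage$points
  n <- nrow(pts)
  radius <- stage$r * cfg$radius_scale
  in_radius <- cpp_radius_counts(pts, radius)
  marked <- in_radius < cfg$M
  if (all(marked)) {
    warning("all points failed the neighbourhood census; P_hat is empty")
    empty <- point_cloud_stage(matrix(numeric(), 0, 3), ids = integer(),
                               stage = "P_hat")
    empty$r <- 0
    return(list(stage = empty, report = list(
      removed_census = stage$ids, removed_plane = integer(),
      distances = numeric(), avg_D = NA_real_)))
  }
  k <- min(cfg$neighbor_cap, n - 1L)
  knn <- cpp_knn_self(pts, k)
  counts <- pmin(in_radius, cfg$neighbor_cap)
  counts[marked] <- 0L
  D <- cpp_local_plane_dists(pts, knn$idx, as.integer(counts),
                             cfg$ransac_iters, cfg$plane_eps_scale,
                             as.numeric(cfg$ransac_seed))
  avg_D <- mean(D[!marked], na.rm = TRUE)
  # NA distances (all-collinear neighbourhoods) cannot be assessed: removed
  keep <- !marked & !is.na(D) & D <= avg_D
  out <- point_cloud_stage(pts[keep, , drop = FALSE], ids = stage$ids[keep],
                           stage = "P_hat")
  distances <- D[!marked]
  names(distances) <- stage$ids[!marked]
  list(stage = out, report = list(
    removed_census = stage$ids[marked],
    removed_plane = stage$ids[!marked & !keep],
    distances = distances, avg_D = avg_D))
}

#' Smooth-mesh distance filter
#'
#' Builds a deliberately low-detail surface from `P_hat` (implicit
#' signed-distance reconstruction at `smooth_mesh_depth`), measures every
#' point's unsigned distance to it, and removes points farther than
#' `B * sigma`, where `sigma` is the population standard deviation of the
#' distance distribution (floored at `sigma_floor_rel * r`).
#'
#' @param stage a `P_hat` [point_cloud_stage()].
#' @param cfg a [cleaning_config()].
#' @param normals optional pre-oriented unit normals for the stage's points;
#'   estimated and oriented internally when `NULL`.
#' @param recon optional [sparse_reconstruction()] used to orient internally
#'   estimated normals from camera poses.
#' @return List with `stage` (the `P_tilde` [point_cloud_stage()]) and
#'   `report` (`sigma`, removed ids, distances).
#' @export
smooth_mesh_filter <- function(stage, cfg = cleaning_config(), normals = NULL,
                               recon = NULL) {
  pts <- stage$points
  if (nrow(pts) == 0L) stop("P_hat is empty", call. = FALSE)
  if (is.null(normals)) {
    normals <- estimate_normals(pts, k = 100L)
    normals <- orient_normals(pts, normals, recon = recon,
                              point_ids = stage$ids)
    normals <- smooth_normals(pts, normals)
  }
  mesh <- reconstruct_mesh(pts, normals, depth = cfg$smooth_mesh_depth,
                           k = cfg$smooth_mesh_k)
  d <- cpp_point_mesh_dist(pts, mesh$vertices, mesh$faces)
  sigma <- sqrt(mean((d - mean(d))^2))
  cutoff <- cfg$B * max(sigma, cfg$sigma_floor_rel * stage$r)
  keep <- d <= cutoff
  out <- point_cloud_stage(pts[keep, , drop = FALSE], ids = stage$ids[keep],
                           stage = "P_tilde")
  dist_named <- d
  names(dist_named) <- stage$ids
  list(stage = out, report = list(
    sigma = sigma, cutoff = cutoff, removed_mesh = stage$ids[!keep],
    mesh_distances = dist_named, smooth_mesh = mesh))
}

#' Run the full outlier-removal cascade
#'
#' Composes the isolated-point filter, the neighbourhood census, the local
#' RANSAC plane-fit filter and the smooth-mesh filter, recording every
#' removal with its stage and statistic.
#'
#' @param x an N x 3 point matrix, a [point_cloud_stage()], or a
#'   [sparse_reconstruction()] (its 3D points are cleaned and its camera
#'   poses orient the normals of the smooth-mesh stage).
#' @param cfg a [cleaning_config()].
#' @return List with `stage` (the final `P_tilde` [point_cloud_stage()]) and
#'   `report` (class `cleaning_report`): `removed_per_stage` (ids removed by
#'   the `isolated`, `census`, `plane_fit` and `mesh` stages), `distances`
#'   (point-to-plane `D` by id), `avg_D`, `sigma`, `stage_sizes`, and the
#'   configuration used.
#' @export
run_outlier_removal <- function(x, cfg = cleaning_config()) {
  recon <- NULL
  if (inherits(x, "sparse_reconstruction")) {
    recon <- x
    pts <- x$points$xyz
    ids <- x$points$ids
  } else if (inherits(x, "point_cloud_stage")) {
    pts <- x$points
    ids <- x$ids
  } else {
    pts <- as_points3(x)
    ids <- seq_len(nrow(pts))
  }
  if (nrow(pts) < cfg$M + 1L)
    stop("need at least M + 1 = ", cfg$M + 1L,
         " points for a meaningful cascade", call. = FALSE)

  p_prime <- remove_isolated(pts, A = cfg$A, ids = ids)
  removed_isolated <- setdiff(ids, p_prime$ids)

  pf <- plane_fit_filter(p_prime, cfg)
  if (nrow(pf$stage$points) == 0L) {
    report <- structure(list(
      removed_per_stage = list(isolated = removed_isolated,
                               census = pf$report$removed_census,
                               plane_fit = pf$report$removed_plane,
                               mesh = integer()),
      distances = pf$report$distances, avg_D = pf$report$avg_D,
      sigma = NA_real_,
      stage_sizes = c(P = nrow(pts), P_prime = nrow(p_prime$points),
                      P_hat = 0L, P_tilde = 0L),
      config = cfg), class = "cleaning_report")
    return(list(stage = pf$stage, report = report))
  }

  sm <- smooth_mesh_filter(pf$stage, cfg, recon = recon)
  report <- structure(list(
    removed_per_stage = list(isolated = removed_isolated,
                             census = pf$report$removed_census,
                             plane_fit = pf$report$removed_plane,
                             mesh = sm$report$removed_mesh),
    distances = pf$report$distances, avg_D = pf$report$avg_D,
    sigma = sm$report$sigma,
    stage_sizes = c(P = nrow(pts), P_prime = nrow(p_prime$points),
                    P_hat = nrow(pf$stage$points),
                    P_tilde = nrow(sm$stage$points)),
    config = cfg), class = "cleaning_report")
  list(stage = sm$stage, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n  stage sizes:",
      paste(names(x$stage_sizes), x$stage_sizes, sep = "=", collapse = " "),
      "\n  removed:",
      paste(names(x$removed_per_stage),
            vapply(x$removed_per_stage, length, 0L), sep = "=",
            collapse = " "),
      "\n  avg_D =", format(x$avg_D, digits = 4),
      " sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}
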