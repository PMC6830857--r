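# End-to-end orchestration: preprocess -> [external SfM] -> clean -> mesh,
# plus evaluation against synthetic ground truth.  The external SfM tool is
# run by the user; the pipeline consumes its sparse-model directory.  On
# synthetic presets the whole chain runs from generated data.

#' Pipeline configuration
#'
#' Bundles all stage parameters with input paths and one seed.  The
#' configuration is serialized into every output directory so a run is fully
#' reproducible from its artifacts.
#'
#' @param frames_dir optional directory of RGB frames.
#' @param sparse_dir sparse-model text directory (required unless
#'   `synthetic` is set).
#' @param synthetic `NULL`, `"small"` or `"medium"`: generate the inputs
#'   instead of reading them.
#' @param channel channel used for deduplication (`"r"`, `"g"`, `"b"`, or
#'   `"rgb"`).
#' @param phi duplicate-removal threshold (published default 0.6).
#' @param zero_tolerance see [difference_ratio()].
#' @param cleaning a [cleaning_config()].
#' @param mesh_depth resolution exponent of the final mesh (default 7).
#' @param retrieval_n retrieval depth (published default 100).
#' @param descriptor descriptor method for retrieval.
#' @param seed master seed; all stage randomness derives from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(frames_dir = NULL, sparse_dir = NULL,
                            synthetic = NULL, channel = "r", phi = 0.6,
                            zero_tolerance = 0L,
                            cleaning = cleaning_config(), mesh_depth = 7L,
                            retrieval_n = 100L, descriptor = "downsample",
                            seed = 0L) {
  channel <- match.arg(tolower(channel), c("r", "g", "b", "rgb"))
  stopifnot(phi >= 0, phi <= 1, mesh_depth >= 2)
  if (!is.null(synthetic))
    synthetic <- match.arg(synthetic, c("small", "medium"))
  cleaning$ransac_seed <- as.integer(seed)
  structure(list(frames_dir = frames_dir, sparse_dir = sparse_dir,
                 synthetic = synthetic, channel = channel, phi = phi,
                 zero_tolerance = as.integer(zero_tolerance),
                 cleaning = cleaning, mesh_depth = as.integer(mesh_depth),
                 retrieval_n = as.integer(retrieval_n),
                 descriptor = descriptor, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_as_yaml <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Generate a synthetic scene preset
#'
#' `"small"` (fast, test-sized) and `"medium"` (the documented study
#' conditions: 5000 inliers with noise, 500 isolated and 500 near outliers,
#' 40 interior cameras) presets used by the pipeline and the CLI.
#'
#' @param preset `"small"` or `"medium"`.
#' @param seed RNG seed.
#' @return List with `scene`, `recon`, and a duplicate-frame fixture
#'   (`frames`, `kept_truth`).
#' @export
synthetic_preset <- function(preset = c("small", "medium"), seed = 0L) {
  preset <- match.arg(preset)
  surface <- make_surface(seed = seed + 1L)
  if (preset == "small") {
    scene <- sample_cloud(surface, n_inliers = 1200L, n_isolated = 60L,
                          n_near = 60L, seed = seed + 2L)
    recon <- make_trajectory_and_tracks(surface, scene, n_cameras = 30L,
                                        points_per_view = 200L)
    fs <- make_frame_sequence(24L, list(c(3L, 3L), c(10L, 4L)),
                              seed = seed + 3L)
  } else {
    scene <- sample_cloud(surface, seed = seed + 2L)
    recon <- make_trajectory_and_tracks(surface, scene)
    fs <- make_frame_sequence(200L, lapply(seq(0, 9), function(i)
      c(20L * i + 1L, 4L)), seed = seed + 3L)
  }
  list(scene = scene, recon = recon, frames = fs$sequence,
       kept_truth = fs$kept_truth)
}

#' Run the processing pipeline
#'
#' Executes deduplication (when frames are given), the outlier-removal
#' cascade, normal estimation/orientation and meshing, persisting every
#' intermediate stage (`P_prime`/`P_hat`/`P_tilde` PLYs), JSON reports, a
#' structured stage log and the configuration itself into `out_dir`.  With a
#' synthetic preset the run finishes with an evaluation against the planted
#' labels.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @return List with the main artifacts (`cleaned`, `report`, `mesh`,
#'   `eval`, paths), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "stages.jsonl")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE)
  }
  config_as_yaml(config, file.path(out_dir, "config.yaml"))

  scene <- NULL; kept_truth <- NULL; dedup <- NULL
  if (!is.null(config$synthetic)) {
    synth <- synthetic_preset(config$synthetic, config$seed)
    scene <- synth$scene
    recon <- synth$recon
    frames <- synth$frames
    kept_truth <- synth$kept_truth
    log_stage("synth", preset = config$synthetic,
              points = nrow(scene$points), cameras = length(recon$frames))
  } else {
    if (is.null(config$sparse_dir) || !dir.exists(config$sparse_dir))
      stop("sparse-model directory not found: ",
           if (is.null(config$sparse_dir)) "<unset>" else config$sparse_dir,
           call. = FALSE)
    recon <- read_colmap_sparse(config$sparse_dir)
    frames <- if (!is.null(config$frames_dir))
      read_frame_dir(config$frames_dir) else NULL
    log_stage("load", points = length(recon$points$ids),
              cameras = length(recon$frames))
  }

  if (!is.null(frames)) {
    seqs <- if (frames$channel == "RGB" && config$channel != "rgb") {
      split_channels(frames)[[toupper(config$channel)]]
    } else frames
    dd <- remove_duplicates(seqs, phi = config$phi,
                            zero_tolerance = config$zero_tolerance)
    dedup <- dd$report
    jsonlite::write_json(dedup, file.path(out_dir, "dedup_report.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("dedup", input = length(seqs),
              kept = length(dedup$kept_indices))
  }

  cl <- run_outlier_removal(recon, config$cleaning)
  rep <- cl$report
  pts <- recon$points$xyz
  ids <- recon$points$ids
  prime_ids <- setdiff(ids, rep$removed_per_stage$isolated)
  hat_ids <- setdiff(prime_ids, c(rep$removed_per_stage$census,
                                  rep$removed_per_stage$plane_fit))
  write_ply(file.path(out_dir, "P_prime.ply"),
            pts[ids %in% prime_ids, , drop = FALSE])
  write_ply(file.path(out_dir, "P_hat.ply"),
            pts[ids %in% hat_ids, , drop = FALSE])
  write_ply(file.path(out_dir, "P_tilde.ply"), cl$stage$points)
  jsonlite::write_json(
    list(stage_sizes = as.list(rep$stage_sizes),
         removed_per_stage = lapply(rep$removed_per_stage, as.integer),
         avg_D = rep$avg_D, sigma = rep$sigma,
         parameters = unclass(config$cleaning), seed = config$seed),
    file.path(out_dir, "cleaning_report.json"), auto_unbox = TRUE,
    digits = NA)
  log_stage("clean", sizes = as.list(rep$stage_sizes))

  normals <- estimate_normals(cl$stage$points, k = 100L)
  normals <- orient_normals(cl$stage$points, normals, recon = recon,
                            point_ids = cl$stage$ids)
  normals <- smooth_normals(cl$stage$points, normals)
  mesh <- reconstruct_mesh(cl$stage$points, normals,
                           depth = config$mesh_depth)
  if (!is.null(frames) && frames$channel == "RGB")
    mesh <- transfer_vertex_colors(mesh, recon, frames)
  write_ply_mesh(file.path(out_dir, "model.ply"), mesh)
  log_stage("mesh", vertices = nrow(mesh$vertices), faces = nrow(mesh$faces))

  ev <- NULL
  if (!is.null(scene)) {
    ev <- evaluate_cleaning(scene, cl$stage, dedup = dedup,
                            kept_truth = kept_truth)
    jsonlite::write_json(unclass(ev), file.path(out_dir, "eval.json"),
                         auto_unbox = TRUE, digits = NA)
    log_stage("eval", outlier_recall = ev$outlier_recall,
              inlier_precision = ev$inlier_precision)
  }
  invisible(list(cleaned = cl$stage, report = rep, mesh = mesh, eval = ev,
                 out_dir = out_dir))
}

#' Evaluate cleaning (and deduplication) against synthetic ground truth
#'
#' Removal decisions are scored against the planted labels with the planted
#' outliers as the positive class: `outlier_precision = TP / (TP + FP)`
#' and `outlier_recall = TP / (TP + FN)` over removals, plus
#' `inlier_precision` (fraction of kept points that are true inliers) and
#' `surface_rmse` (RMS radial surface distance of the kept points).
#'
#' @param scene a [sample_cloud()] scene.
#' @param cleaned the final [point_cloud_stage()] (ids are rows of
#'   `scene$points`).
#' @param dedup optional dedup report from [remove_duplicates()].
#' @param kept_truth ground-truth kept positions for the dedup fixture.
#' @return List of class `eval_report`.
#' @export
evaluate_cleaning <- function(scene, cleaned, dedup = NULL,
                              kept_truth = NULL) {
  n <- nrow(scene$points)
  kept <- seq_len(n) %in% cleaned$ids
  outlier <- scene$labels != "INLIER"
  tp <- sum(!kept & outlier)
  fp <- sum(!kept & !outlier)
  fn <- sum(kept & outlier)
  kept_pts <- scene$points[kept, , drop = FALSE]
  rmse <- sqrt(mean(surface_signed_distance(scene$surface, kept_pts)^2))
  dedup_exact <- if (!is.null(dedup) && !is.null(kept_truth)) {
    identical(sort(as.integer(dedup$kept_indices)),
              sort(as.integer(kept_truth)))
  } else NA
  structure(list(
    outlier_precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    outlier_recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    inlier_precision = if (sum(kept) > 0) sum(kept & !outlier) / sum(kept)
                       else NA_real_,
    surface_rmse = rmse,
    dedup_exact_match = dedup_exact,
    confusion = c(TP = tp, FP = fp, FN = fn,
                  TN = sum(kept & !outlier))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> outlier P/R =", format(x$outlier_precision, digits = 4),
      "/", format(x$outlier_recall, digits = 4),
      " inlier precision =", format(x$inlier_precision, digits = 4),
      " surface RMSE =", format(x$surface_rmse, digits = 4), "\n")
  invisible(x)
}
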