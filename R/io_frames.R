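# Frame-directory I/O.  Frames live in memory as integer arrays in 0-255
# (H x W for single-channel, H x W x 3 for RGB); PNG is the on-disk format.
# Video decoding is out of scope: an external frame extractor is expected to
# have dumped the video into an image directory.

frame_from_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3L) {
    img <- img[, , 1]
  }
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}

frame_to_png <- function(frame, path) {
  png::writePNG(frame / 255, path)
  invisible(path)
}

#' Read an image directory as a frame sequence
#'
#' Files matching `pattern` are taken in lexicographic order; all frames must
#' share dimensions.
#'
#' @param path directory of PNG frames.
#' @param pattern file-name regular expression (default: PNG files).
#' @param channel channel tag for the resulting sequence; single-channel
#'   tags require single-channel (grayscale) files.
#' @return A [frame_sequence()].
#' @export
read_frame_dir <- function(path, pattern = "\\.png$", channel = NULL) {
  if (!dir.exists(path)) stop("no such frame directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  frames <- lapply(files, frame_from_png)
  if (is.null(channel)) {
    channel <- if (!length(frames) || length(dim(frames[[1]])) == 3L) "RGB"
               else "R"
  }
  dims <- vapply(frames, function(f) paste(dim(f), collapse = "x"), "")
  if (length(unique(dims)) > 1L) {
    ref <- dims[1]
    off <- basename(files)[dims != ref]
    stop("frames have mixed dimensions: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  frame_sequence(frames, channel = channel, names = basename(files),
                 source_id = path)
}

#' Write a frame sequence as numbered PNG files
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_frame_dir <- function(seq, path, prefix = "frame") {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(path, sprintf("%s_%06d.png", prefix, seq$index))
  for (i in seq_along(seq$frames)) frame_to_png(seq$frames[[i]], paths[i])
  invisible(paths)
}
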