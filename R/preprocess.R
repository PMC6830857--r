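# Frame pre-processing: color-channel separation and duplicated-frame
# removal.  Endoscope capture hardware frequently emits runs of (nearly)
# identical frames; these are redundant for structure-from-motion and are
# dropped by comparing each frame against a running reference.

#' Split an RGB frame sequence into its three channel sequences
#'
#' Pixel values of each output plane are bit-identical to the corresponding
#' source plane.
#'
#' @param seq an RGB [frame_sequence()].
#' @return Named list of three single-channel sequences (`R`, `G`, `B`).
#' @export
split_channels <- function(seq) {
  if (seq$channel != "RGB")
    stop("split_channels expects an RGB sequence", call. = FALSE)
  one <- function(ch, tag) {
    frame_sequence(lapply(seq$frames, function(f) f[, , ch]),
                   channel = tag, index = seq$index, names = seq$names,
                   source_id = seq$source_id)
  }
  list(R = one(1L, "R"), G = one(2L, "G"), B = one(3L, "B"))
}

#' Fraction of differing pixels between two frames
#'
#' The absolute difference image is computed and the ratio of pixels whose
#' difference exceeds `zero_tolerance` (in any channel, for multi-channel
#' frames) to the total pixel count is returned.
#'
#' @param a,b frames of identical dimensions (integer arrays, 0-255).
#' @param zero_tolerance intensity difference regarded as "no change"
#'   (default 0: strictly non-zero differences count).
#' @return A real in \[0, 1\].
#' @export
difference_ratio <- function(a, b, zero_tolerance = 0L) {
  if (!identical(dim(a), dim(b)))
    stop("frames differ in dimensions", call. = FALSE)
  diff <- abs(a - b) > zero_tolerance
  if (length(dim(a)) == 3L) {
    npix <- dim(a)[1] * dim(a)[2]
    ndiff <- sum(diff[, , 1] | diff[, , 2] | diff[, , 3])
  } else {
    npix <- length(a)
    ndiff <- sum(diff)
  }
  ndiff / npix
}

#' Remove duplicated frames from a sequence
#'
#' Reference-advance loop: the first frame is the reference and is always
#' kept; each successive frame is compared to the reference via
#' [difference_ratio()].  While the ratio is below `phi` the frame is dropped
#' as a duplicate; the first frame reaching `phi` is kept and becomes the new
#' reference.
#'
#' @param seq a [frame_sequence()].
#' @param phi duplicate threshold in \[0, 1\] (published default 0.6).
#' @param zero_tolerance see [difference_ratio()].
#' @return List with `sequence` (the deduplicated [frame_sequence()]) and
#'   `report` (kept/removed positions — 1-based within the input — and the
#'   per-comparison ratios).
#' @export
remove_duplicates <- function(seq, phi = 0.6, zero_tolerance = 0L) {
  stopifnot(phi >= 0, phi <= 1)
  n <- length(seq$frames)
  if (n == 0L) {
    return(list(sequence = seq,
                report = dedup_report(integer(), integer(), numeric())))
  }
  kept <- 1L
  removed <- integer()
  ratios <- numeric()
  ref <- 1L
  for (t in seq_len(n)[-1]) {
    rho <- difference_ratio(seq$frames[[ref]], seq$frames[[t]],
                            zero_tolerance)
    ratios <- c(ratios, rho)
    if (rho < phi) {
      removed <- c(removed, t)
    } else {
      kept <- c(kept, t)
      ref <- t
    }
  }
  out <- frame_sequence(seq$frames[kept], channel = seq$channel,
                        index = seq$index[kept],
                        names = if (!is.null(seq$names)) seq$names[kept],
                        source_id = seq$source_id)
  list(sequence = out, report = dedup_report(kept, removed, ratios))
}

dedup_report <- function(kept, removed, ratios) {
  stopifnot(length(intersect(kept, removed)) == 0L)
  list(kept_indices = as.integer(kept), removed_indices = as.integer(removed),
       ratios = as.numeric(ratios))
}
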