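#' BODY_25 keypoint names
#'
#' Names of the 25 keypoints of the OpenPose BODY_25 model, in the order
#' they appear in `pose_keypoints_2d` arrays (index 0 = nose ... index
#' 24 = right heel). Suffixes `_l`/`_r` denote the person's left/right side.
#'
#' @return Character vector of length 25.
#' @export
#' @examples
#' body25_keypoints()[9]  # "midhip"
body25_keypoints <- function() {
  c("nose", "neck",
    "shoulder_r", "elbow_r", "wrist_r",
    "shoulder_l", "elbow_l", "wrist_l",
    "midhip",
    "hip_r", "knee_r", "ankle_r",
    "hip_l", "knee_l", "ankle_l",
    "eye_r", "eye_l", "ear_r", "ear_l",
    "bigtoe_l", "smalltoe_l", "heel_l",
    "bigtoe_r", "smalltoe_r", "heel_r")
}

#' Leg keypoints subject to left/right identity errors
#'
#' The six keypoints per leg whose left/right labels a pose estimator can
#' exchange: hip, knee, ankle, heel, big toe, small toe.
#'
#' @param side `"l"` or `"r"`.
#' @return Character vector of 6 keypoint names.
#' @export
leg_keypoints <- function(side = c("l", "r")) {
  side <- match.arg(side)
  paste0(c("hip_", "knee_", "ankle_", "heel_", "bigtoe_", "smalltoe_"), side)
}

#' Construct a pose sequence
#'
#' A pose sequence holds per-frame pixel keypoints with confidences for one
#' tracked person, the video frame rate, and which sagittal side the camera
#' viewed.
#'
#' @param xyc Numeric array `n_frames x 25 x 3`; the third dimension is
#'   `(x, y, confidence)` with pixel coordinates in the raw image convention
#'   (origin at the upper-left corner, y increasing downward). A confidence
#'   of exactly 0 marks a missing keypoint.
#' @param frame_rate Video frame rate in Hz (> 0).
#' @param camera_side `"left"` or `"right"`: which side of the person the
#'   camera viewed.
#' @param image_size Integer vector `c(width, height)` in pixels.
#' @param source_id Free-text identifier for the recording.
#' @return An object of class `pose_sequence`.
#' @export
pose_sequence <- function(xyc, frame_rate, camera_side = c("left", "right"),
                          image_size = c(960L, 540L), source_id = "pose") {
  camera_side <- match.arg(camera_side)
  stopifnot(is.array(xyc), length(dim(xyc)) == 3L, dim(xyc)[2] == 25L,
            dim(xyc)[3] == 3L, is.numeric(frame_rate), frame_rate > 0,
            length(image_size) == 2L, all(image_size > 0))
  dimnames(xyc) <- list(NULL, body25_keypoints(), c("x", "y", "c"))
  conf <- xyc[, , 3]
  bad <- conf > 0 & (!is.finite(xyc[, , 1]) | !is.finite(xyc[, , 2]))
  if (any(bad, na.rm = TRUE))
    stop("non-finite coordinates for keypoints with confidence > 0")
  structure(list(xyc = xyc, frame_rate = frame_rate,
                 camera_side = camera_side,
                 image_size = as.integer(image_size),
                 source_id = source_id),
            class = "pose_sequence")
}

#' @export
print.pose_sequence <- function(x, ...) {
  cat(sprintf("<pose_sequence> %d frames @ %g Hz, %s-side view, %dx%d px (%s)\n",
              n_frames(x), x$frame_rate, x$camera_side,
              x$image_size[1], x$image_size[2], x$source_id))
  invisible(x)
}

#' Number of frames in a pose sequence
#' @param x A `pose_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) dim(x$xyc)[1]
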