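#' Read a directory of per-frame OpenPose JSON files
#'
#' Each JSON file holds the detections for one video frame: a `people`
#' array whose elements carry a flat `pose_keypoints_2d` vector of 75
#' numbers (`x1, y1, c1, ..., x25, y25, c25`). Files are ordered by the
#' zero-padded numeric suffix of their filenames; non-contiguous frame
#' indices are an error rather than being silently resampled. Frames with
#' no detected people yield all-missing keypoints; frames with several
#' people are resolved by [select_person()] and logged.
#'
#' @param path Directory containing the per-frame `.json` files.
#' @param frame_rate Video frame rate in Hz.
#' @param camera_side `"left"` or `"right"` sagittal view.
#' @param image_size `c(width, height)` in pixels.
#' @param source_id Identifier stored on the result; defaults to the
#'   directory name.
#' @return A [pose_sequence()] with attribute `"selection_log"`: a data
#'   frame of frames where more than one person was detected, with the
#'   chosen person index.
#' @export
read_openpose_dir <- function(path, frame_rate, camera_side = c("left", "right"),
                              image_size = c(960L, 540L),
                              source_id = basename(normalizePath(path))) {
  camera_side <- match.arg(camera_side)
  if (!dir.exists(path)) stop("directory not found: ", path)
  files <- list.files(path, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no .json files in ", path)
  suffix <- regmatches(files, regexpr("[0-9]+(?=[^0-9]*\\.json$)", files, perl = TRUE))
  if (length(suffix) != length(files))
    stop("filenames must carry a numeric frame suffix before .json")
  idx <- as.integer(suffix)
  ord <- order(idx)
  files <- files[ord]; idx <- idx[ord]
  if (any(diff(idx) != 1L))
    stop("frame indices are not contiguous (gap after index ",
         idx[which(diff(idx) != 1L)[1]], ")")

  n <- length(files)
  xyc <- array(0, dim = c(n, 25L, 3L))
  log_rows <- list()
  for (i in seq_len(n)) {
    doc <- tryCatch(jsonlite::fromJSON(files[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("malformed JSON in ", files[i], ": ",
                           conditionMessage(e), call. = FALSE))
    people <- doc$people
    if (length(people) == 0L) next  # all-missing frame
    kps <- lapply(people, function(p) {
      v <- unlist(p$pose_keypoints_2d, use.names = FALSE)
      if (length(v) != 75L)
        stop("keypoint array of length ", length(v), " (expected 75) in ",
             files[i], call. = FALSE)
      matrix(as.numeric(v), ncol = 3L, byrow = TRUE)
    })
    sel <- select_person(kps)
    xyc[i, , ] <- sel$keypoints
    if (length(kps) > 1L)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(frame_index = i, n_people = length(kps),
                   selected = sel$selected)
  }
  ps <- pose_sequence(xyc, frame_rate, camera_side, image_size, source_id)
  attr(ps, "selection_log") <- if (length(log_rows))
    do.call(rbind, log_rows)
  else data.frame(frame_index = integer(), n_people = integer(),
                  selected = integer())
  ps
}

#' Select the tracked person among several detections
#'
#' Pose estimators can detect false-positive "people" (posters, tripods).
#' The walker is taken as the candidate with the most confident keypoints
#' (confidence > 0); ties are broken by larger bounding-box area over the
#' confident keypoints, then by lowest person index.
#'
#' @param people List of `25 x 3` keypoint matrices (x, y, confidence).
#' @return List with `keypoints` (the chosen `25 x 3` matrix) and
#'   `selected` (its index). An empty list yields an all-missing frame.
#' @export
select_person <- function(people) {
  if (length(people) == 0L)
    return(list(keypoints = matrix(0, 25L, 3L), selected = NA_integer_))
  score <- vapply(people, function(m) sum(m[, 3] > 0), numeric(1))
  area <- vapply(people, function(m) {
    ok <- m[, 3] > 0
    if (sum(ok) < 2L) return(0)
    diff(range(m[ok, 1])) * diff(range(m[ok, 2]))
  }, numeric(1))
  # lexicographic: confident-keypoint count, then bbox area, then -index
  best <- order(-score, -area, seq_along(people))[1L]
  list(keypoints = people[[best]], selected = best)
}

#' Write a pose sequence as per-frame OpenPose-dialect JSON files
#'
#' Emits one `<source_id>_<%012d>_keypoints.json` file per frame in the
#' BODY_25 dialect (a `people` array of flat 75-float
#' `pose_keypoints_2d` vectors). Frames whose 25 keypoints all carry zero
#' confidence are written with an empty `people` list. Extra (false
#' positive) people attached by [inject_defects()] via the
#' `"extra_people"` attribute are written alongside the walker.
#'
#' @param pose A [pose_sequence()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_openpose_json <- function(pose, dir) {
  stopifnot(inherits(pose, "pose_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  extra <- attr(pose, "extra_people")
  n <- n_frames(pose)
  paths <- character(n)
  for (i in seq_len(n)) {
    kp <- pose$xyc[i, , ]
    people <- list()
    if (any(kp[, 3] > 0))
      people[[1L]] <- list(pose_keypoints_2d = as.numeric(t(kp)))
    if (!is.null(extra) && i <= length(extra) && !is.null(extra[[i]]))
      for (m in extra[[i]])
        people[[length(people) + 1L]] <- list(pose_keypoints_2d = as.numeric(t(m)))
    paths[i] <- file.path(dir, sprintf("%s_%012d_keypoints.json",
                                       pose$source_id, i - 1L))
    jsonlite::write_json(list(version = 1.3, people = people), paths[i],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}
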