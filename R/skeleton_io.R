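#' The 32 tracked joints of the skeletal model
#'
#' Joint names follow the depth-camera body-tracking convention of 32 virtual
#' joints, with `_L`/`_R` suffixes for sided joints. The analysis pipeline
#' itself requires only the nine joints in [required_joints()]; the remaining
#' joints are carried through I/O untouched.
#'
#' @return Character vector of 32 joint names.
#' @export
kinect_joints <- function() {
  c("PELVIS", "SPINE_NAVEL", "SPINE_CHEST", "NECK", "HEAD", "NOSE",
    "CLAVICLE_L", "SHOULDER_L", "ELBOW_L", "WRIST_L", "HAND_L",
    "HANDTIP_L", "THUMB_L", "EYE_L", "EAR_L",
    "HIP_L", "KNEE_L", "ANKLE_L", "FOOT_L",
    "CLAVICLE_R", "SHOULDER_R", "ELBOW_R", "WRIST_R", "HAND_R",
    "HANDTIP_R", "THUMB_R", "EYE_R", "EAR_R",
    "HIP_R", "KNEE_R", "ANKLE_R", "FOOT_R")
}

#' Joints the gait pipeline relies on
#' @return Character vector of the 9 required joint names.
#' @export
required_joints <- function() {
  c("PELVIS", "HIP_L", "HIP_R", "ANKLE_L", "ANKLE_R",
    "SHOULDER_L", "SHOULDER_R", "WRIST_L", "WRIST_R")
}

SCHEMA_VERSION <- 1L

#' Construct a skeletal trial sequence
#'
#' A `skeleton_sequence` holds one walking trial: a strictly increasing
#' timestamp vector (seconds) and, per frame, the 3D position of each of the
#' 32 joints in millimetres, camera frame. Coordinate convention: `x` is
#' mediolateral (positive toward the subject's left), `y` vertical (positive
#' up), `z` distance from the camera (positive away from it, so it decreases
#' as the subject walks toward the sensor).
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   length >= 2.
#' @param xyz Numeric array `n_frames x 3 x 32`; second dimension is
#'   `c("x","y","z")` in mm, third dimension named by [kinect_joints()].
#' @param conf Optional `n_frames x 32` matrix of per-joint confidence
#'   scores in `[0, 1]`. Stored and round-tripped but never used to gate the
#'   analysis.
#' @param subject_id,trial_id,group Free-text trial metadata.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(t, xyz, conf = NULL,
                              subject_id = "unknown", trial_id = 1L,
                              group = "") {
  seq <- structure(
    list(t = as.numeric(t), xyz = xyz, conf = conf,
         meta = list(subject_id = as.character(subject_id),
                     trial_id = trial_id,
                     group = as.character(group))),
    class = "skeleton_sequence")
  validate_sequence(seq)
  seq
}

#' Validate a skeletal sequence against the trial schema invariants
#'
#' Checks frame count (>= 2), strictly increasing timestamps, the presence
#' of all 32 joints (including every required joint), finite coordinates and
#' array shape. Throws a classed error (`kinegait_schema_error` or
#' `kinegait_data_error`) on the first violation.
#'
#' @param seq A `skeleton_sequence`.
#' @return `seq`, invisibly, if valid.
#' @export
validate_sequence <- function(seq) {
  if (!is.list(seq) || is.null(seq$t) || is.null(seq$xyz))
    kg_stop("not a skeleton_sequence", "kinegait_schema_error")
  n <- length(seq$t)
  if (n == 0)
    kg_stop("trial contains no frames", "kinegait_schema_error")
  if (n < 2)
    kg_stop("trial must contain at least 2 frames", "kinegait_schema_error")
  if (any(!is.finite(seq$t)))
    kg_stop("non-finite timestamps", "kinegait_data_error")
  if (any(diff(seq$t) <= 0))
    kg_stop("timestamps are not strictly increasing", "kinegait_data_error")
  d <- dim(seq$xyz)
  if (length(d) != 3 || d[1] != n || d[2] != 3)
    kg_stop("position array must be n_frames x 3 x n_joints",
            "kinegait_schema_error")
  jn <- dimnames(seq$xyz)[[3]]
  missing <- setdiff(kinect_joints(), jn)
  if (length(missing))
    kg_stop(paste0("missing required joint(s): ",
                   paste(missing, collapse = ", ")),
            "kinegait_schema_error")
  if (d[3] != 32)
    kg_stop("expected exactly 32 joints", "kinegait_schema_error")
  if (any(!is.finite(seq$xyz)))
    kg_stop("non-finite joint coordinates", "kinegait_data_error")
  if (!is.null(seq$conf)) {
    if (!is.matrix(seq$conf) || nrow(seq$conf) != n || ncol(seq$conf) != 32)
      kg_stop("confidence matrix must be n_frames x 32",
              "kinegait_schema_error")
  }
  invisible(seq)
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> %d frames, %.2f s, subject '%s' trial %s%s\n",
              length(x$t), diff(range(x$t)), x$meta$subject_id,
              x$meta$trial_id,
              if (nzchar(x$meta$group)) paste0(" [", x$meta$group, "]") else ""))
  invisible(x)
}

#' Read a skeletal trial from a JSON file
#'
#' Parses and validates one trial. The file layout is one JSON object per
#' trial with a `schema_version` field, trial metadata, and a `frames` array;
#' each frame is `{t, joints: {NAME: {p: [x, y, z], c}}}` with positions in
#' millimetres. This layout emulates the per-joint JSON exports of
#' depth-camera body-tracking pipelines; it is this package's own schema, not
#' a vendor format.
#'
#' @param path Path to a trial JSON file.
#' @return A validated [skeleton_sequence()].
#' @seealso [write_trial()]
#' @export
read_trial <- function(path) {
  if (!file.exists(path))
    kg_stop(paste0("file not found: ", path), "kinegait_io_error")
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    kg_stop(paste0("malformed JSON in ", path, ": ",
                                   conditionMessage(e)),
                            "kinegait_parse_error"))
  if (is.null(obj$frames) || length(obj$frames) == 0)
    kg_stop("trial contains no frames", "kinegait_schema_error")
  frames <- obj$frames
  n <- length(frames)
  joints <- kinect_joints()
  t <- vapply(frames, function(f) as.numeric(f$t), numeric(1))
  xyz <- array(NA_real_, dim = c(n, 3, 32),
               dimnames = list(NULL, c("x", "y", "z"), joints))
  has_conf <- FALSE
  conf <- matrix(NA_real_, n, 32, dimnames = list(NULL, joints))
  for (i in seq_len(n)) {
    jl <- frames[[i]]$joints
    present <- names(jl)
    missing <- setdiff(joints, present)
    if (length(missing))
      kg_stop(sprintf("frame %d lists %d joints; missing: %s",
                      i, length(present),
                      paste(missing, collapse = ", ")),
              "kinegait_schema_error")
    for (j in joints) {
      p <- unlist(jl[[j]]$p)
      if (length(p) != 3)
        kg_stop(sprintf("frame %d joint %s: position is not length 3", i, j),
                "kinegait_schema_error")
      xyz[i, , j] <- as.numeric(p)
      if (!is.null(jl[[j]]$c)) {
        has_conf <- TRUE
        conf[i, j] <- as.numeric(jl[[j]]$c)
      }
    }
  }
  meta <- list(subject_id = obj$subject_id %||% "unknown",
               trial_id = obj$trial_id %||% 1L,
               group = obj$group %||% "")
  skeleton_sequence(t, xyz, conf = if (has_conf) conf else NULL,
                    subject_id = meta$subject_id, trial_id = meta$trial_id,
                    group = meta$group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a skeletal trial to a JSON file
#'
#' Serializes with 17 significant digits so that `read_trial(write_trial(x))`
#' restores timestamps and positions bit-exactly. The confidence field is
#' omitted per joint when absent.
#'
#' @param seq A validated [skeleton_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(seq, path) {
  validate_sequence(seq)
  joints <- dimnames(seq$xyz)[[3]]
  frames <- lapply(seq_along(seq$t), function(i) {
    jl <- lapply(joints, function(j) {
      entry <- list(p = seq$xyz[i, , j])
      if (!is.null(seq$conf) && is.finite(seq$conf[i, j]))
        entry$c <- seq$conf[i, j]
      entry
    })
    names(jl) <- joints
    list(t = seq$t[i], joints = jl)
  })
  obj <- list(schema_version = SCHEMA_VERSION,
              subject_id = seq$meta$subject_id,
              trial_id = seq$meta$trial_id,
              group = seq$meta$group,
              frames = frames)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  ok <- tryCatch({writeLines(json, path); TRUE},
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok)
    kg_stop(paste0("cannot write trial file: ", path), "kinegait_io_error")
  invisible(path)
}

#' Extract one joint's trajectory from a sequence or window
#'
#' @param seq A `skeleton_sequence`, `resampled_sequence` or `gait_window`.
#' @param joint A joint name from [kinect_joints()].
#' @return List with `t` (seconds) and `xyz` (`n x 3` matrix, mm).
#' @export
joint_trajectory <- function(seq, joint) {
  jn <- dimnames(seq$xyz)[[3]]
  if (!(joint %in% jn))
    kg_stop(paste0("unknown joint: ", joint), "kinegait_lookup_error")
  list(t = seq$t, xyz = seq$xyz[, , joint, drop = TRUE])
}

# Internal shorthand: one coordinate of one joint as a numeric vector.
jcoord <- function(seq, joint, axis) {
  seq$xyz[, axis, joint]
}
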