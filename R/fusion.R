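# Two depth sensors flank the player to reduce self-occlusion. A T-pose
# (arms abducted to horizontal) is used to estimate the yaw of camera 2
# relative to camera 1 from the wrist-to-wrist vector; both cameras are
# assumed to be at the same height, so the extrinsic model is a rotation
# about the vertical axis plus a translation.

rot_y <- function(yaw_deg) {
  th <- yaw_deg * pi / 180
  matrix(c(cos(th), 0, -sin(th),
           0, 1, 0,
           sin(th), 0, cos(th)), nrow = 3)  # column-major: R %*% c(x,y,z)
}

# signed heading of a vector projected on the XZ plane, degrees; rotating a
# vector by rot_y(a) adds a to its heading
xz_heading <- function(v) atan2(-v[3], v[1]) * 180 / pi

wrap_deg <- function(a) ((a + 180) %% 360) - 180

frame_joint <- function(frame, joint) {
  row <- frame[frame$joint == joint, ]
  if (nrow(row) != 1) abort_validation(paste0("frame lacks joint ", joint))
  row
}

joint_xyz <- function(frame, joint) {
  row <- frame_joint(frame, joint)
  unname(c(row$x, row$y, row$z))
}

#' Calibrate a second camera against the first from a T-pose
#'
#' The participant stands still with arms straight and shoulders abducted to
#' horizontal. The wrist-to-wrist distance must agree between the two cameras
#' to within 10 cm for the calibration to be accepted; the heading difference
#' of the wrist-to-wrist vector in the horizontal (XZ) plane gives the yaw of
#' camera 2 relative to camera 1, and aligning the hip centres after rotation
#' gives the translation.
#'
#' @param tpose_cam1,tpose_cam2 One T-pose frame from each camera (20-row
#'   tibbles, see [stream_frame()]); both wrists must be in state `tracked`.
#' @return An `fms_calibration` object: `yaw_deg`, `translation` (xyz metres
#'   mapping camera-2 coordinates into the camera-1 frame),
#'   `wrist_distance_diff_m`, `valid`.
#' @export
#' @examples
#' tp <- simulate_tpose(yaw_deg = 40, translation = c(0.5, 0, 0.2),
#'                      noise_sd = 0, seed = 1)
#' calibrate_cameras(tp$cam1, tp$cam2)
calibrate_cameras <- function(tpose_cam1, tpose_cam2) {
  for (fr in list(tpose_cam1, tpose_cam2)) {
    for (w in c("wrist_left", "wrist_right")) {
      if (frame_joint(fr, w)$state != "tracked") {
        rlang::abort(paste0("calibration pose has untracked landmark: ", w),
                     class = c("fms_missing_landmark_error",
                               "fms_validation_error"))
      }
    }
  }
  w1 <- joint_xyz(tpose_cam1, "wrist_right") - joint_xyz(tpose_cam1, "wrist_left")
  w2 <- joint_xyz(tpose_cam2, "wrist_right") - joint_xyz(tpose_cam2, "wrist_left")
  span1 <- sqrt(sum(w1^2)); span2 <- sqrt(sum(w2^2))
  diff_m <- abs(span1 - span2)
  if (diff_m >= 0.10) {
    rlang::abort(sprintf(
      "calibration rejected: wrist-to-wrist distance differs by %.3f m (>= 0.10 m)",
      diff_m
    ), class = c("fms_calibration_error", "fms_validation_error"))
  }
  yaw <- wrap_deg(xz_heading(w1) - xz_heading(w2))
  hip1 <- joint_xyz(tpose_cam1, "hip_centre")
  hip2 <- joint_xyz(tpose_cam2, "hip_centre")
  translation <- hip1 - as.vector(rot_y(yaw) %*% hip2)
  new_calibration(yaw, translation, diff_m)
}

new_calibration <- function(yaw_deg, translation, wrist_distance_diff_m,
                            valid = wrist_distance_diff_m < 0.10) {
  structure(
    list(
      yaw_deg = yaw_deg,
      translation = stats::setNames(as.numeric(translation), c("x", "y", "z")),
      wrist_distance_diff_m = wrist_distance_diff_m,
      valid = valid
    ),
    class = "fms_calibration"
  )
}

#' @export
print.fms_calibration <- function(x, ...) {
  cat(sprintf(
    "<fms_calibration: yaw %.3f deg, translation (%.3f, %.3f, %.3f) m, wrist span diff %.3f m, %s>\n",
    x$yaw_deg, x$translation[1], x$translation[2], x$translation[3],
    x$wrist_distance_diff_m, if (x$valid) "valid" else "INVALID"
  ))
  invisible(x)
}

#' Serialize / read a calibration as JSON
#' @param calib An `fms_calibration`.
#' @param path JSON file path.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("calibration file not found: ", path))
  }
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration(rec$yaw_deg, unlist(rec$translation),
                  rec$wrist_distance_diff_m, rec$valid)
}

check_calibration <- function(calib) {
  if (!inherits(calib, "fms_calibration")) {
    abort_validation("calib must be an fms_calibration object")
  }
  if (!isTRUE(calib$valid)) {
    abort_validation("calibration is invalid (wrist span difference >= 0.10 m)")
  }
  invisible(calib)
}

#' Map camera-2 coordinates into the camera-1 frame
#'
#' Rotates every joint position by the calibrated yaw about the vertical axis
#' and then translates; tracking states, orientations and timestamps are
#' unchanged.
#'
#' @param frame A 20-row frame tibble.
#' @param calib A valid [calibrate_cameras()] result.
#' @return The transformed frame (or stream).
#' @export
transform_frame <- function(frame, calib) {
  check_calibration(calib)
  rot <- rot_y(calib$yaw_deg)
  p <- rot %*% rbind(frame$x, frame$y, frame$z) + calib$translation
  frame$x <- p[1, ]; frame$y <- p[2, ]; frame$z <- p[3, ]
  frame
}

#' @rdname transform_frame
#' @param stream A [skeleton_stream()].
#' @export
transform_stream <- function(stream, calib) {
  check_calibration(calib)
  rot <- rot_y(calib$yaw_deg)
  p <- rot %*% rbind(stream$x, stream$y, stream$z) + calib$translation
  stream$x <- p[1, ]; stream$y <- p[2, ]; stream$z <- p[3, ]
  stream
}

#' Fuse two simultaneously recorded streams into one
#'
#' Camera-2 frames are mapped into the camera-1 frame via `calib` and paired
#' to camera-1 frames by nearest timestamp within half a frame period. Per
#' joint: if both cameras hold a usable sample (state `tracked` or
#' `inferred`) in the same state, the coordinate-wise mean is taken
#' (provenance `averaged`); if the states differ, the directly tracked sample
#' wins; if only one camera holds a usable sample, that camera's value is
#' used (`cam1_only` / `cam2_only`); if neither does, camera 1's stored
#' position is kept (`fallback_cam1`). Unpaired camera-1 frames pass through
#' as `cam1_only`. Output timestamps, orientations, metadata and exclusions
#' are camera 1's.
#'
#' @param s1,s2 [skeleton_stream()]s from cameras 1 and 2.
#' @param calib A valid [calibrate_cameras()] result.
#' @return A fused `skeleton_stream` carrying per-joint provenance.
#' @export
fuse_streams <- function(s1, s2, calib) {
  check_calibration(calib)
  n1 <- n_frames(s1); n2 <- n_frames(s2)
  if (n1 == 0 || n2 == 0) abort_validation("both streams must be nonempty")
  s2 <- transform_stream(s2, calib)

  t1 <- frame_times(s1); t2 <- frame_times(s2)
  rate <- attr(s1, "rate")
  tol <- 1 / (2 * rate)
  # nearest s2 frame for each s1 frame
  idx <- findInterval(t1, t2)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, n2)
  nearest <- ifelse(abs(t2[lo] - t1) <= abs(t2[hi] - t1), lo, hi)
  paired <- abs(t2[nearest] - t1) <= tol
  if (!any(paired)) {
    rlang::abort("streams do not overlap in time: no frame pairs within half a frame period",
                 class = c("fms_no_overlap_error", "fms_validation_error"))
  }

  m <- function(s, col) matrix(s[[col]], nrow = 20)
  x1 <- m(s1, "x"); y1 <- m(s1, "y"); z1 <- m(s1, "z"); st1 <- m(s1, "state")
  x2 <- m(s2, "x")[, nearest, drop = FALSE]
  y2 <- m(s2, "y")[, nearest, drop = FALSE]
  z2 <- m(s2, "z")[, nearest, drop = FALSE]
  st2 <- m(s2, "state")[, nearest, drop = FALSE]

  pairmat <- matrix(rep(paired, each = 20), nrow = 20)
  v1 <- st1 != "not_tracked"
  v2 <- (st2 != "not_tracked") & pairmat

  rank1 <- ifelse(st1 == "tracked", 2L, ifelse(st1 == "inferred", 1L, 0L))
  rank2 <- ifelse(st2 == "tracked", 2L, ifelse(st2 == "inferred", 1L, 0L))
  rank2[!pairmat] <- 0L

  use_avg <- v1 & v2 & (rank1 == rank2)
  use_cam2 <- (v2 & !v1) | (v1 & v2 & rank2 > rank1)
  use_cam1 <- !use_avg & !use_cam2  # covers cam1-only and the fallback

  fx <- x1; fy <- y1; fz <- z1
  fx[use_avg] <- (x1[use_avg] + x2[use_avg]) / 2
  fy[use_avg] <- (y1[use_avg] + y2[use_avg]) / 2
  fz[use_avg] <- (z1[use_avg] + z2[use_avg]) / 2
  fx[use_cam2] <- x2[use_cam2]
  fy[use_cam2] <- y2[use_cam2]
  fz[use_cam2] <- z2[use_cam2]

  fstate <- st1
  fstate[use_cam2] <- st2[use_cam2]

  prov <- matrix("cam1_only", 20, n1)
  prov[use_avg] <- "averaged"
  prov[use_cam2] <- "cam2_only"
  prov[use_cam1 & !v1 & pairmat] <- "fallback_cam1"  # invalid in both cameras

  stream_from_matrices(
    t1, t(fx), t(fy), t(fz), t(fstate),
    m(s1, "ox") |> t(), m(s1, "oy") |> t(), m(s1, "oz") |> t(),
    rate = rate, provenance = t(prov),
    participant = attr(s1, "participant"),
    condition = attr(s1, "condition"),
    camera = "fused",
    exclusions = {
      ex <- attr(s1, "exclusions")
      if (nrow(ex) > 0) ex else NULL
    }
  )
}
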