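#' The twenty tracked skeleton joints
#'
#' Consumer depth-sensor pose trackers report a default skeleton of twenty
#' joints arranged in a tree rooted at the centre of the hips. Joint names are
#' snake_case throughout the package; their order here fixes the stable
#' integer codes 0-19 used in the binary stream layout.
#'
#' @return Character vector of the 20 joint names, in file-layout order.
#' @export
#' @examples
#' skeleton_joints()
skeleton_joints <- function() {
  c(
    "hip_centre", "spine", "shoulder_centre", "head",
    "shoulder_left", "elbow_left", "wrist_left", "hand_left",
    "shoulder_right", "elbow_right", "wrist_right", "hand_right",
    "hip_left", "knee_left", "ankle_left", "foot_left",
    "hip_right", "knee_right", "ankle_right", "foot_right"
  )
}

# integer code 0-19 for a joint name (file layout order)
joint_code <- function(joint) {
  match(joint, skeleton_joints()) - 1L
}

#' @rdname skeleton_joints
#' @details `joint_parent()` and `joint_first_child()` give the skeleton
#' hierarchy (root `hip_centre`); they define the two segments whose angle a
#' joint-angle condition measures. Terminal joints (head, hands, feet) have no
#' child and therefore no defined joint angle.
#' @export
joint_parent <- function() {
  c(
    hip_centre = NA_character_, spine = "hip_centre",
    shoulder_centre = "spine", head = "shoulder_centre",
    shoulder_left = "shoulder_centre", elbow_left = "shoulder_left",
    wrist_left = "elbow_left", hand_left = "wrist_left",
    shoulder_right = "shoulder_centre", elbow_right = "shoulder_right",
    wrist_right = "elbow_right", hand_right = "wrist_right",
    hip_left = "hip_centre", knee_left = "hip_left",
    ankle_left = "knee_left", foot_left = "ankle_left",
    hip_right = "hip_centre", knee_right = "hip_right",
    ankle_right = "knee_right", foot_right = "ankle_right"
  )
}

#' @rdname skeleton_joints
#' @export
joint_first_child <- function() {
  c(
    hip_centre = "spine", spine = "shoulder_centre",
    shoulder_centre = "head", head = NA_character_,
    shoulder_left = "elbow_left", elbow_left = "wrist_left",
    wrist_left = "hand_left", hand_left = NA_character_,
    shoulder_right = "elbow_right", elbow_right = "wrist_right",
    wrist_right = "hand_right", hand_right = NA_character_,
    hip_left = "knee_left", knee_left = "ankle_left",
    ankle_left = "foot_left", foot_left = NA_character_,
    hip_right = "knee_right", knee_right = "ankle_right",
    ankle_right = "foot_right", foot_right = NA_character_
  )
}

#' Tracking states and fusion provenance codes
#'
#' Every joint sample carries one of three tracking states reported by the
#' sensor: `tracked` (directly measured, highest confidence), `inferred`
#' (estimated from other tracked joints) or `not_tracked` (no data). Streams
#' produced by [fuse_streams()] additionally carry a provenance code saying
#' which camera(s) contributed each fused sample.
#'
#' @return Character vector of state (or provenance) levels.
#' @export
tracking_states <- function() c("not_tracked", "inferred", "tracked")

#' @rdname tracking_states
#' @export
fusion_provenance <- function() {
  c("cam1_only", "cam2_only", "averaged", "fallback_cam1")
}

# numeric codes used in the validity byte (low 2 bits)
state_code <- function(state) {
  match(state, tracking_states()) - 1L
}

# provenance codes for the validity byte (bits 2-4); 0 = none/unfused
provenance_code <- function(prov) {
  ifelse(is.na(prov), 0L, match(prov, fusion_provenance()))
}
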