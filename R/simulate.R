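# Synthetic labelled sessions: a neutral standing skeleton with Gaussian
# sway, scheduled jump / sidestep events, optional occlusion spans and an
# optional second-camera view, so every analysis path is testable without a
# recording. Movement profiles are smooth (half-sine vertical jumps,
# smoothstep lateral steps); amplitudes, durations and noise levels are
# exposed in the config.

# standing pose, metres, camera ~2.5 m in front; columns joints, rows xyz
base_pose_matrix <- function(tpose = FALSE) {
  arm_y <- if (tpose) c(1.30, 1.30, 1.30) else c(1.05, 0.85, 0.78)
  arm_x <- if (tpose) c(0.45, 0.70, 0.78) else c(0.21, 0.22, 0.22)
  pose <- rbind(
    hip_centre = c(0, 0.95, 2.5),
    spine = c(0, 1.10, 2.5),
    shoulder_centre = c(0, 1.30, 2.5),
    head = c(0, 1.55, 2.5),
    shoulder_left = c(-0.18, 1.30, 2.5),
    elbow_left = c(-arm_x[1], arm_y[1], 2.5),
    wrist_left = c(-arm_x[2], arm_y[2], 2.5),
    hand_left = c(-arm_x[3], arm_y[3], 2.5),
    shoulder_right = c(0.18, 1.30, 2.5),
    elbow_right = c(arm_x[1], arm_y[1], 2.5),
    wrist_right = c(arm_x[2], arm_y[2], 2.5),
    hand_right = c(arm_x[3], arm_y[3], 2.5),
    hip_left = c(-0.09, 0.90, 2.5),
    knee_left = c(-0.10, 0.50, 2.5),
    ankle_left = c(-0.10, 0.08, 2.5),
    foot_left = c(-0.10, 0.02, 2.45),
    hip_right = c(0.09, 0.90, 2.5),
    knee_right = c(0.10, 0.50, 2.5),
    ankle_right = c(0.10, 0.08, 2.5),
    foot_right = c(0.10, 0.02, 2.45)
  )
  stopifnot(identical(rownames(pose), skeleton_joints()))
  pose
}

#' Schedule a movement event
#'
#' @param onset_s Event onset in seconds.
#' @param duration_s Event duration in seconds.
#' @param amplitude_m Event amplitude in metres: the vertical excursion of a
#'   jump, or the lateral displacement of the hips/shoulders in a sidestep
#'   (the lead foot travels twice the amplitude).
#' @return One-row event tibble.
#' @export
jump_event <- function(onset_s, duration_s = 0.4, amplitude_m = 0.10) {
  tibble::tibble(type = "jump", onset_s = onset_s, duration_s = duration_s,
                 amplitude_m = amplitude_m)
}

#' @rdname jump_event
#' @param side `"left"` or `"right"`: the lead-foot side, which is also the
#'   direction of travel (left = -X, right = +X).
#' @export
sidestep_event <- function(side, onset_s, duration_s = 0.6,
                           amplitude_m = 0.20) {
  if (!side %in% c("left", "right")) {
    abort_validation("sidestep side must be 'left' or 'right'")
  }
  tibble::tibble(type = paste0("sidestep_", side), onset_s = onset_s,
                 duration_s = duration_s, amplitude_m = amplitude_m)
}

#' Configure a synthetic session
#'
#' Defaults emulate the recording setup of the validation study: 30 frames
#' per second, centimetre-scale postural sway (0.5 cm SD), supra-threshold
#' movement amplitudes (10 cm jumps, 20 cm sidesteps with a 40 cm lead-foot
#' step) and, when enabled, a second camera viewing the same motion from a
#' different yaw with independent measurement noise.
#'
#' @param duration_s Session length in seconds; must exceed the last event's
#'   end.
#' @param rate Frame rate (frames per second).
#' @param events Event schedule: a tibble from [jump_event()] /
#'   [sidestep_event()] rows (or `NULL` for an idle session). Events must not
#'   overlap.
#' @param sway_sd_m Per-frame, per-coordinate Gaussian sway SD in metres.
#' @param occlusion List: `rate_per_min` (expected occlusion spans per
#'   minute), `mean_span_s`, `states` (drawn for occluded joints).
#' @param camera2 List: `enabled`, `yaw_deg`, `translation`, `noise_sd`
#'   (per-camera measurement noise applied to both views when enabled).
#' @param seed Integer seed; identical configs with identical seeds produce
#'   identical sessions.
#' @return A `session_config` list.
#' @export
session_config <- function(duration_s = 60, rate = 30, events = NULL,
                           sway_sd_m = 0.005,
                           occlusion = list(rate_per_min = 0,
                                            mean_span_s = 0.5,
                                            states = c("inferred",
                                                       "not_tracked")),
                           camera2 = list(enabled = FALSE, yaw_deg = 30,
                                          translation = c(1.5, 0, 0.5),
                                          noise_sd = 0.003),
                           seed = NULL) {
  events <- if (is.null(events)) {
    tibble::tibble(type = character(0), onset_s = numeric(0),
                   duration_s = numeric(0), amplitude_m = numeric(0))
  } else {
    tibble::as_tibble(events)
  }
  if (nrow(events) > 0) {
    events <- events[order(events$onset_s), ]
    if (any(!events$type %in% c("jump", "sidestep_left", "sidestep_right"))) {
      abort_validation("event types must be jump, sidestep_left or sidestep_right")
    }
    if (any(events$amplitude_m <= 0) || any(events$duration_s <= 0)) {
      abort_validation("event amplitudes and durations must be positive")
    }
    ends <- events$onset_s + events$duration_s
    if (nrow(events) > 1 && any(events$onset_s[-1] < ends[-nrow(events)])) {
      abort_validation("events must not overlap")
    }
    if (duration_s <= max(ends)) {
      abort_validation("duration_s must exceed the end of the last event")
    }
  }
  structure(
    list(duration_s = duration_s, rate = rate, events = events,
         sway_sd_m = sway_sd_m, occlusion = occlusion, camera2 = camera2,
         seed = seed),
    class = "session_config"
  )
}

#' @rdname session_config
#' @details `fms_condition_config()` builds the isolated-skills assessment
#' protocol: three jumps followed by twelve sidesteps, six to each side
#' (alternating), well separated in a single continuous recording.
#' @export
fms_condition_config <- function(seed = NULL, ...) {
  onsets <- 2 + 3 * (0:14)
  events <- dplyr::bind_rows(
    purrr::map(onsets[1:3], jump_event),
    purrr::map2(rep(c("left", "right"), 6), onsets[4:15], sidestep_event)
  )
  session_config(duration_s = 50, events = events, seed = seed, ...)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# smooth 0->1 step
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

#' Simulate a labelled skeleton session
#'
#' Generates the ground-truth motion (neutral stance + sway + scheduled
#' events), applies occlusion spans, and renders one camera view — or two,
#' when `config$camera2$enabled`, in which case both views carry independent
#' Gaussian measurement noise and camera 2 records in its own (rotated and
#' translated) coordinate frame.
#'
#' Jump events raise the whole skeleton by a half-sine profile over the event
#' duration. Sidestep events translate the body laterally by the amplitude
#' with a smoothstep profile (displacement persists; alternating sides keeps
#' the player in the capture space), with the lead foot travelling twice the
#' amplitude in under 0.3 s and the trailing foot following within 0.5 s.
#'
#' @param config A [session_config()].
#' @return A list: `stream` (camera-1 [skeleton_stream()]), `cam2` (second
#'   view or `NULL`), `truth` (tibble `type,onset_s,end_s`), `config`.
#' @export
#' @examples
#' sim <- simulate_session(fms_condition_config(seed = 1))
#' match_counts(match_all(sim$stream))
simulate_session <- function(config) {
  if (!inherits(config, "session_config")) {
    abort_validation("config must come from session_config()")
  }
  with_seed(config$seed, {
    n <- round(config$duration_s * config$rate)
    t <- (0:(n - 1)) / config$rate
    pose <- base_pose_matrix()
    xm <- matrix(pose[, 1], n, 20, byrow = TRUE)
    ym <- matrix(pose[, 2], n, 20, byrow = TRUE)
    zm <- matrix(pose[, 3], n, 20, byrow = TRUE)

    torso_dx <- rep(0, n)
    foot_dx <- list(left = rep(0, n), right = rep(0, n))
    dy <- rep(0, n)
    ev <- config$events
    for (i in seq_len(nrow(ev))) {
      on <- ev$onset_s[i]; dur <- ev$duration_s[i]; amp <- ev$amplitude_m[i]
      u <- (t - on) / dur
      if (ev$type[i] == "jump") {
        inside <- u >= 0 & u <= 1
        dy[inside] <- dy[inside] + amp * sin(pi * u[inside])
      } else {
        s <- if (ev$type[i] == "sidestep_left") -1 else 1
        lead <- sub("sidestep_", "", ev$type[i])
        trail <- if (lead == "left") "right" else "left"
        torso_dx <- torso_dx + s * amp * smoothstep(u)
        lead_dur <- min(0.28, dur)
        trail_delay <- min(0.10, dur / 4)
        trail_dur <- min(0.45, dur - trail_delay)
        foot_dx[[lead]] <- foot_dx[[lead]] +
          s * 2 * amp * smoothstep((t - on) / lead_dur)
        foot_dx[[trail]] <- foot_dx[[trail]] +
          s * 2 * amp * smoothstep((t - on - trail_delay) / trail_dur)
      }
    }

    foot_joints <- list(
      left = match(c("ankle_left", "foot_left"), skeleton_joints()),
      right = match(c("ankle_right", "foot_right"), skeleton_joints())
    )
    body_joints <- setdiff(1:20, unlist(foot_joints))
    xm[, body_joints] <- xm[, body_joints] + torso_dx
    xm[, foot_joints$left] <- xm[, foot_joints$left] + foot_dx$left
    xm[, foot_joints$right] <- xm[, foot_joints$right] + foot_dx$right
    ym <- ym + dy

    # postural sway
    xm <- xm + matrix(stats::rnorm(n * 20, 0, config$sway_sd_m), n, 20)
    ym <- ym + matrix(stats::rnorm(n * 20, 0, config$sway_sd_m), n, 20)
    zm <- zm + matrix(stats::rnorm(n * 20, 0, config$sway_sd_m), n, 20)

    # occlusion spans overwrite tracking states; positions are left as
    # recorded (real dropouts return stale or inferred coordinates)
    state <- matrix("tracked", n, 20)
    occ <- config$occlusion
    n_occ <- stats::rpois(1, occ$rate_per_min * config$duration_s / 60)
    for (k in seq_len(n_occ)) {
      start <- stats::runif(1, 0, config$duration_s)
      span <- stats::rexp(1, 1 / occ$mean_span_s)
      joints <- sample(1:20, sample(1:4, 1))
      st <- sample(occ$states, 1)
      rows <- which(t >= start & t < start + span)
      state[rows, joints] <- st
    }

    truth <- tibble::tibble(type = ev$type, onset_s = ev$onset_s,
                            end_s = ev$onset_s + ev$duration_s)

    if (isTRUE(config$camera2$enabled)) {
      ns <- config$camera2$noise_sd
      noise <- function() matrix(stats::rnorm(n * 20, 0, ns), n, 20)
      x1 <- xm + noise(); y1 <- ym + noise(); z1 <- zm + noise()
      # camera 2 records in its own frame: p2 = R(-yaw) (p1_truth - t) + noise
      rot <- rot_y(-config$camera2$yaw_deg)
      tr <- config$camera2$translation
      p2 <- rot %*% rbind(as.vector(xm) - tr[1], as.vector(ym) - tr[2],
                          as.vector(zm) - tr[3])
      x2 <- matrix(p2[1, ], n, 20) + noise()
      y2 <- matrix(p2[2, ], n, 20) + noise()
      z2 <- matrix(p2[3, ], n, 20) + noise()
      stream <- stream_from_matrices(t, x1, y1, z1, state,
                                     rate = config$rate, camera = "cam1")
      cam2 <- stream_from_matrices(t, x2, y2, z2, state,
                                   rate = config$rate, camera = "cam2")
      list(stream = stream, cam2 = cam2, truth = truth, config = config)
    } else {
      stream <- stream_from_matrices(t, xm, ym, zm, state,
                                     rate = config$rate, camera = "cam1")
      list(stream = stream, cam2 = NULL, truth = truth, config = config)
    }
  })
}

#' Simulate a two-camera calibration T-pose
#'
#' Arms abducted to horizontal; camera 2 sees the same pose from a different
#' yaw about the vertical axis (both cameras at the same height), with
#' optional Gaussian noise on camera 2's joints.
#'
#' @param yaw_deg Planted yaw of camera 2 relative to camera 1 (|yaw| < 90).
#' @param translation Planted camera-2 origin offset (xyz metres).
#' @param noise_sd Gaussian noise SD (metres) on camera 2's joint positions.
#' @param seed Optional seed.
#' @return List of two 20-row frames, `cam1` and `cam2`.
#' @export
#' @examples
#' tp <- simulate_tpose(yaw_deg = 60, translation = c(0, 0, 0), noise_sd = 0)
#' calibrate_cameras(tp$cam1, tp$cam2)$yaw_deg
simulate_tpose <- function(yaw_deg = 0, translation = c(0, 0, 0),
                           noise_sd = 0, seed = NULL) {
  if (abs(yaw_deg) >= 90) abort_validation("|yaw_deg| must be < 90")
  with_seed(seed, {
    pose <- base_pose_matrix(tpose = TRUE)
    frame1 <- tibble::tibble(
      frame = 1L, time = 0, joint = skeleton_joints(),
      x = unname(pose[, 1]), y = unname(pose[, 2]), z = unname(pose[, 3]),
      state = "tracked", ox = 0, oy = 0, oz = 0,
      provenance = NA_character_, excluded = FALSE
    )
    rot <- rot_y(-yaw_deg)
    p2 <- rot %*% rbind(pose[, 1] - translation[1],
                        pose[, 2] - translation[2],
                        pose[, 3] - translation[3])
    frame2 <- frame1
    frame2$x <- p2[1, ] + stats::rnorm(20, 0, noise_sd)
    frame2$y <- p2[2, ] + stats::rnorm(20, 0, noise_sd)
    frame2$z <- p2[3, ] + stats::rnorm(20, 0, noise_sd)
    list(cam1 = frame1, cam2 = frame2)
  })
}

#' Score detections against ground truth
#'
#' Greedy one-to-one assignment of detected matches to true events by onset
#' proximity within a tolerance, per rule. By default a rule is scored
#' against the truth event types whose names start with the lower-cased rule
#' name, so `JUMP` scores against `jump` and `SIDESTEP` against both
#' `sidestep_left` and `sidestep_right`.
#'
#' @param truth Ground-truth tibble (`type`, `onset_s`, `end_s`) from
#'   [simulate_session()].
#' @param matches An `fms_matches` table from [match_all()].
#' @param tolerance_s Maximum |detected start - true onset| for a pairing.
#' @param type_map Optional named list mapping rule names to truth types.
#' @return A tibble with one row per rule: counts of true/false positives
#'   and misses, `precision`, `recall`, and `precision_defined` (`FALSE` when
#'   there were no detections, in which case precision is reported as 1).
#' @export
score_detection <- function(truth, matches, tolerance_s = 0.5,
                            type_map = NULL) {
  counts <- attr(matches, "counts")
  rules <- names(counts) %||% unique(matches$rule)
  out <- purrr::map(rules, function(rn) {
    types <- if (!is.null(type_map)) type_map[[rn]] else {
      unique(truth$type)[startsWith(unique(truth$type), tolower(rn))]
    }
    tr <- truth[truth$type %in% types, ]
    det <- matches[matches$rule == rn, ]
    det <- det[order(det$start_s), ]
    assigned <- rep(FALSE, nrow(tr))
    tp <- 0L
    for (i in seq_len(nrow(det))) {
      d <- abs(tr$onset_s - det$start_s[i])
      d[assigned] <- Inf
      j <- which.min(d)
      if (length(j) == 1 && nrow(tr) > 0 && d[j] <= tolerance_s) {
        assigned[j] <- TRUE
        tp <- tp + 1L
      }
    }
    fp <- nrow(det) - tp
    fn <- nrow(tr) - tp
    has_det <- nrow(det) > 0
    tibble::tibble(
      rule = rn, n_truth = nrow(tr), n_detected = nrow(det),
      true_pos = tp, false_pos = fp, false_neg = fn,
      precision = if (has_det) tp / nrow(det) else 1,
      precision_defined = has_det,
      recall = if (nrow(tr) > 0) tp / nrow(tr) else 1
    )
  })
  dplyr::bind_rows(out)
}
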