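#' Build a skeleton stream
#'
#' A skeleton stream is the unit of analysis: an ordered sequence of frames,
#' each holding the twenty joint positions (metres, camera frame), a tracking
#' state per joint, bone orientations (XYZ Euler angles, degrees) and a
#' timestamp in seconds relative to the first frame. In this package a stream
#' is a tibble with one row per frame x joint, ordered frame-major with
#' joints in [skeleton_joints()] order, plus stream-level attributes
#' (nominal frame rate, recording metadata, exclusion intervals).
#'
#' Coordinate convention: X = player's right (+), Y = up (+), Z = away from
#' the camera (+), metres, camera-1 frame. "Vertical" in rule language means
#' Y, "horizontal" means X.
#'
#' @param frames Data frame with columns `time`, `joint`, `x`, `y`, `z`,
#'   `state`, and optionally `ox`, `oy`, `oz` (orientation, degrees),
#'   `provenance` (fused streams only) and `excluded`.
#' @param rate Nominal frame rate in frames per second (default 30).
#' @param participant,condition,camera Optional recording metadata.
#' @param exclusions Optional data frame of `[start_s, end_s)` intervals during
#'   which the participant was outside the capture space; see
#'   [apply_exclusions()].
#' @return A `skeleton_stream` tibble.
#' @export
skeleton_stream <- function(frames, rate = 30, participant = NA_character_,
                            condition = NA_character_, camera = NA_character_,
                            exclusions = NULL) {
  frames <- tibble::as_tibble(frames)
  required <- c("time", "joint", "x", "y", "z", "state")
  missing_cols <- setdiff(required, names(frames))
  if (length(missing_cols) > 0) {
    abort_validation(paste0(
      "stream frames are missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in c("ox", "oy", "oz")) {
    if (is.null(frames[[col]])) frames[[col]] <- 0
  }
  if (is.null(frames[["provenance"]])) frames$provenance <- NA_character_
  if (is.null(frames[["excluded"]])) frames$excluded <- FALSE

  if (nrow(frames) %% 20 != 0) {
    abort_validation("stream must contain exactly 20 joint rows per frame")
  }
  # canonical ordering: frame-major, joints in file-layout order
  frames$joint <- as.character(frames$joint)
  ord <- order(frames$time, match(frames$joint, skeleton_joints()))
  frames <- frames[ord, c("time", "joint", "x", "y", "z", "state",
                          "ox", "oy", "oz", "provenance", "excluded")]
  frames$frame <- rep(seq_len(nrow(frames) / 20), each = 20)
  frames <- frames[, c("frame", names(frames)[names(frames) != "frame"])]

  stream <- structure(
    frames,
    class = c("skeleton_stream", class(tibble::tibble())),
    rate = as.numeric(rate),
    participant = participant,
    condition = condition,
    camera = camera,
    exclusions = normalize_exclusions(exclusions)
  )
  validate_skeleton_stream(stream)
  if (!is.null(exclusions)) stream <- flag_excluded(stream)
  stream
}

# fast constructor from frames x joints matrices (generator, file reader)
stream_from_matrices <- function(time, x, y, z, state, ox = NULL, oy = NULL,
                                 oz = NULL, rate = 30, provenance = NULL,
                                 participant = NA_character_,
                                 condition = NA_character_,
                                 camera = NA_character_,
                                 exclusions = NULL, validate = TRUE) {
  n <- length(time)
  zmat <- function(m) if (is.null(m)) matrix(0, n, 20) else m
  frames <- tibble::tibble(
    frame = rep(seq_len(n), each = 20L),
    time = rep(time, each = 20L),
    joint = rep(skeleton_joints(), n),
    x = as.vector(t(x)), y = as.vector(t(y)), z = as.vector(t(z)),
    state = as.vector(t(state)),
    ox = as.vector(t(zmat(ox))), oy = as.vector(t(zmat(oy))),
    oz = as.vector(t(zmat(oz))),
    provenance = if (is.null(provenance)) NA_character_
                 else as.vector(t(provenance)),
    excluded = FALSE
  )
  stream <- structure(
    frames,
    class = c("skeleton_stream", class(tibble::tibble())),
    rate = as.numeric(rate),
    participant = participant, condition = condition, camera = camera,
    exclusions = normalize_exclusions(exclusions)
  )
  if (validate) validate_skeleton_stream(stream)
  if (!is.null(exclusions)) stream <- flag_excluded(stream)
  stream
}

#' @rdname skeleton_stream
#' @param x Object to test or validate.
#' @export
is_skeleton_stream <- function(x) inherits(x, "skeleton_stream")

#' @rdname skeleton_stream
#' @export
validate_skeleton_stream <- function(x) {
  if (nrow(x) %% 20 != 0) {
    abort_validation("stream must contain exactly 20 joint rows per frame")
  }
  n <- nrow(x) / 20
  if (n > 0) {
    jmat <- matrix(x$joint, nrow = 20)
    if (!all(jmat == skeleton_joints())) {
      abort_validation("each frame must contain the 20 joints in canonical order")
    }
    tm <- matrix(x$time, nrow = 20)
    if (any(tm[1, ] != tm[20, ])) {
      abort_validation("all joints in a frame must share one timestamp")
    }
    ts <- tm[1, ]
    if (n > 1 && any(diff(ts) <= 0)) {
      abort_validation("frame timestamps must be strictly increasing")
    }
    bad_state <- !x$state %in% tracking_states()
    if (any(bad_state)) {
      abort_validation(paste0("unknown tracking state: ",
                              x$state[which(bad_state)[1]]))
    }
    pos_needed <- x$state != "not_tracked"
    if (any(pos_needed & !(is.finite(x$x) & is.finite(x$y) & is.finite(x$z)))) {
      abort_validation("positions must be finite when the joint is tracked or inferred")
    }
  }
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl) > 0 && n > 0) {
    last_t <- x$time[nrow(x)]
    if (any(excl$start_s > last_t)) {
      abort_validation("exclusion interval starts after the last frame")
    }
  }
  invisible(x)
}

#' @export
print.skeleton_stream <- function(x, ...) {
  n <- n_frames(x)
  dur <- if (n > 0) x$time[nrow(x)] else 0
  excl <- attr(x, "exclusions")
  cat(sprintf(
    "<skeleton_stream: %d frames, %.2f s @ %g fps, %d exclusion interval(s)>\n",
    n, dur, attr(x, "rate"), if (is.null(excl)) 0L else nrow(excl)
  ))
  meta <- c(participant = attr(x, "participant"),
            condition = attr(x, "condition"), camera = attr(x, "camera"))
  meta <- meta[!is.na(meta)]
  if (length(meta) > 0) {
    cat("  ", paste(names(meta), meta, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  NextMethod()
}

#' @rdname skeleton_stream
#' @export
n_frames <- function(x) as.integer(nrow(x) / 20)

# frame timestamps (one per frame)
frame_times <- function(stream) {
  matrix(stream$time, nrow = 20)[1, ]
}

# n_frames-length vector of one joint's coordinate along one axis
joint_axis_series <- function(stream, joint, axis) {
  j <- match(joint, skeleton_joints())
  matrix(stream[[tolower(axis)]], nrow = 20)[j, ]
}

joint_state_series <- function(stream, joint) {
  j <- match(joint, skeleton_joints())
  matrix(stream$state, nrow = 20)[j, ]
}

# logical vector: frame lies inside an exclusion interval
excluded_frames <- function(stream) {
  matrix(stream$excluded, nrow = 20)[1, ]
}

#' Extract one frame of a stream
#'
#' Returns the 20-row tibble for a single frame, used e.g. as a calibration
#' pose by [calibrate_cameras()].
#'
#' @param stream A [skeleton_stream()].
#' @param index Frame number (1-based), or `NULL` to select by `time`.
#' @param time Timestamp in seconds; the nearest frame is returned.
#' @return A 20-row tibble (one row per joint).
#' @export
stream_frame <- function(stream, index = NULL, time = NULL) {
  if (is.null(index)) {
    if (is.null(time)) abort_validation("give either a frame index or a time")
    index <- which.min(abs(frame_times(stream) - time))
  }
  n <- n_frames(stream)
  if (index < 1 || index > n) {
    abort_validation(sprintf("frame index %d outside 1..%d", index, n))
  }
  tibble::as_tibble(as.data.frame(stream))[((index - 1) * 20 + 1):(index * 20), ]
}

# ---- exclusion intervals ----------------------------------------------------

normalize_exclusions <- function(intervals) {
  if (is.null(intervals)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  intervals <- tibble::as_tibble(as.data.frame(intervals))
  if (!all(c("start_s", "end_s") %in% names(intervals))) {
    abort_validation("exclusion intervals need columns start_s and end_s")
  }
  intervals <- intervals[order(intervals$start_s), c("start_s", "end_s")]
  if (nrow(intervals) > 0) {
    if (any(intervals$end_s <= intervals$start_s)) {
      abort_validation("exclusion intervals must satisfy start_s < end_s")
    }
    if (any(intervals$start_s < 0)) {
      abort_validation("exclusion intervals must start at or after 0")
    }
    if (nrow(intervals) > 1 &&
        any(intervals$start_s[-1] < intervals$end_s[-nrow(intervals)])) {
      abort_validation("exclusion intervals must not overlap")
    }
  }
  intervals
}

# union of two disjoint-interval sets, coalescing overlaps (idempotency)
merge_exclusions <- function(a, b) {
  all_iv <- rbind(a, b)
  all_iv <- all_iv[order(all_iv$start_s, all_iv$end_s), ]
  if (nrow(all_iv) <= 1) return(all_iv)
  out_s <- out_e <- numeric(0)
  cs <- all_iv$start_s[1]; ce <- all_iv$end_s[1]
  for (i in seq_len(nrow(all_iv))[-1]) {
    if (all_iv$start_s[i] <= ce) {
      ce <- max(ce, all_iv$end_s[i])
    } else {
      out_s <- c(out_s, cs); out_e <- c(out_e, ce)
      cs <- all_iv$start_s[i]; ce <- all_iv$end_s[i]
    }
  }
  tibble::tibble(start_s = c(out_s, cs), end_s = c(out_e, ce))
}

flag_excluded <- function(stream) {
  excl <- attr(stream, "exclusions")
  ts <- frame_times(stream)
  flag <- rep(FALSE, length(ts))
  for (i in seq_len(nrow(excl))) {
    flag <- flag | (ts >= excl$start_s[i] & ts < excl$end_s[i])
  }
  stream$excluded <- rep(flag, each = 20)
  stream
}

#' Flag out-of-view periods of a stream
#'
#' Time a participant spends outside the capture space is removed from
#' analysis: frames inside an exclusion interval `[start_s, end_s)` are
#' flagged (not deleted), the matcher never anchors a window on a flagged
#' frame, and no match window may cross an exclusion boundary.
#'
#' Flagging is idempotent and, for disjoint interval sets, order-independent;
#' new intervals are merged with any already present on the stream.
#'
#' @param stream A [skeleton_stream()].
#' @param intervals Data frame with columns `start_s`, `end_s` (seconds),
#'   sorted and non-overlapping.
#' @return The stream with exclusions merged in and frames flagged.
#' @export
#' @examples
#' s <- simulate_session(session_config(duration_s = 4, events = NULL, seed = 1))$stream
#' s2 <- apply_exclusions(s, data.frame(start_s = 1, end_s = 2))
#' sum(matrix(s2$excluded, nrow = 20)[1, ])
apply_exclusions <- function(stream, intervals) {
  intervals <- normalize_exclusions(intervals)
  merged <- merge_exclusions(attr(stream, "exclusions"), intervals)
  attr(stream, "exclusions") <- merged
  validate_skeleton_stream(stream)
  flag_excluded(stream)
}

#' Read exclusion intervals from CSV
#'
#' @param path CSV file with columns `start_s,end_s`.
#' @return Tibble of validated intervals.
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("exclusions file not found: ", path))
  }
  normalize_exclusions(utils::read.csv(path))
}

# ---- error helpers ----------------------------------------------------------

abort_validation <- function(message) {
  rlang::abort(message, class = "fms_validation_error")
}

abort_format <- function(message) {
  rlang::abort(message, class = c("fms_format_error", "fms_validation_error"))
}
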