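# Sliding-window rule matching.
#
# Anchors are scanned left to right (excluded frames are never anchors). At
# an anchor the window grows frame by frame up to the largest condition
# window; each condition is satisfied at the first admissible frame whose
# anchor-relative displacement meets its comparator, and a match is declared
# at the first frame where the whole Boolean expression is true (with at
# least one satisfied condition). Windows never cross an exclusion boundary.
# A continuous movement keeps re-satisfying a rule at consecutive anchors
# (e.g. the descent of a jump re-triggers an absolute-displacement clause),
# so after a valid match the scan resumes at the match's end frame and
# consumes the run of immediately re-firing anchors without recording them;
# one movement therefore yields one match. The reported interval spans the
# frames that exhibited the displacement: from the earliest satisfying frame
# of the satisfied conditions to the frame where the expression became true.

# per-leaf series and validity over the stream; leaves keyed by signature
prep_leaves <- function(stream, leaves) {
  sigs <- vapply(leaves, leaf_signature, character(1))
  uniq <- !duplicated(sigs)
  prep <- lapply(leaves[uniq], function(cond) {
    if (cond$kind == "disp") {
      list(series = joint_axis_series(stream, cond$joint, cond$axis),
           valid = joint_state_series(stream, cond$joint) != "not_tracked")
    } else {
      angle_series(stream, cond$joint)
    }
  })
  names(prep) <- sigs[uniq]
  prep
}

leaf_signature <- function(cond) {
  paste(cond$kind, cond$joint, cond$axis, sep = "|")
}

# angle (degrees) at a joint: between segments to its parent and first child
angle_series <- function(stream, joint) {
  parent <- joint_parent()[[joint]]
  child <- joint_first_child()[[joint]]
  n <- n_frames(stream)
  if (is.na(parent) || is.na(child)) {
    return(list(series = rep(NA_real_, n), valid = rep(FALSE, n)))
  }
  jx <- joint_axis_series(stream, joint, "x")
  jy <- joint_axis_series(stream, joint, "y")
  jz <- joint_axis_series(stream, joint, "z")
  ux <- joint_axis_series(stream, parent, "x") - jx
  uy <- joint_axis_series(stream, parent, "y") - jy
  uz <- joint_axis_series(stream, parent, "z") - jz
  vx <- joint_axis_series(stream, child, "x") - jx
  vy <- joint_axis_series(stream, child, "y") - jy
  vz <- joint_axis_series(stream, child, "z") - jz
  nu <- sqrt(ux^2 + uy^2 + uz^2)
  nv <- sqrt(vx^2 + vy^2 + vz^2)
  cosang <- (ux * vx + uy * vy + uz * vz) / (nu * nv)
  valid <- joint_state_series(stream, joint) != "not_tracked" &
    joint_state_series(stream, parent) != "not_tracked" &
    joint_state_series(stream, child) != "not_tracked" &
    is.finite(cosang)
  list(series = acos(pmin(1, pmax(-1, cosang))) * 180 / pi, valid = valid)
}

cmp_ok <- function(d, cmp, threshold) {
  switch(cmp,
    abs_ge = abs(d) >= threshold,
    signed_ge = d >= threshold,
    signed_le = d <= threshold
  )
}

# last frame index usable from anchor i without crossing an exclusion
exclusion_limits <- function(excl) {
  n <- length(excl)
  lim <- integer(n)
  nxt <- n + 1L  # index of next excluded frame at or after i+1
  for (i in n:1) {
    lim[i] <- nxt - 1L
    if (excl[i]) nxt <- i
  }
  lim
}

# first admissible satisfying frame for one condition at one anchor, given
# candidate frame indices cand (already exclusion-limited, within W_max)
leaf_sat_index <- function(cond, prep, times, anchor, cand) {
  if (!prep$valid[anchor]) return(Inf)
  if (length(cand) == 0) return(Inf)
  in_window <- times[cand] - times[anchor] < cond$window_s
  d <- prep$series[cand] - prep$series[anchor]
  ok <- in_window & prep$valid[cand] & cmp_ok(d, cond$cmp, cond$threshold)
  hit <- which(ok)
  if (length(hit) == 0) Inf else cand[hit[1]]
}

#' Evaluate one condition at an anchor frame
#'
#' Tests whether, starting from the anchor frame, the condition's joint
#' displacement (or angle change) reaches its threshold at some frame whose
#' elapsed time from the anchor is strictly less than the condition's window,
#' without crossing an exclusion boundary. A joint that is `not_tracked` at
#' the anchor (or at a candidate frame) cannot satisfy the condition; this is
#' not an error, since game-play recordings contain dropouts.
#'
#' @param stream A [skeleton_stream()].
#' @param cond An [disp_condition()] or [angle_condition()].
#' @param anchor_index Anchor frame (1-based); must not lie in an exclusion.
#' @return A list with `satisfied` (logical) and `index` (first satisfying
#'   frame, or `NA` if unsatisfied).
#' @export
evaluate_condition <- function(stream, cond, anchor_index) {
  n <- n_frames(stream)
  if (anchor_index < 1 || anchor_index > n) {
    abort_validation(sprintf("anchor index %d outside 1..%d", anchor_index, n))
  }
  excl <- excluded_frames(stream)
  if (excl[anchor_index]) {
    abort_validation("anchor frame lies inside an exclusion interval")
  }
  times <- frame_times(stream)
  prep <- prep_leaves(stream, list(cond))[[1]]
  lim <- exclusion_limits(excl)[anchor_index]
  jm <- findInterval(times[anchor_index] + cond$window_s, times)
  hi <- min(lim, jm)
  cand <- if (hi > anchor_index) (anchor_index + 1L):hi else integer(0)
  sat <- leaf_sat_index(cond, prep, times, anchor_index, cand)
  list(satisfied = is.finite(sat),
       index = if (is.finite(sat)) as.integer(sat) else NA_integer_)
}

# vectorized truth of an expression over candidate end frames
expr_truth <- function(expr, cand, sat_by_leaf, leaf_counter) {
  if (is_condition(expr)) {
    sat <- sat_by_leaf[leaf_counter$i]
    leaf_counter$i <- leaf_counter$i + 1L
    return(cand >= sat)
  }
  kids <- lapply(expr$children, expr_truth, cand = cand,
                 sat_by_leaf = sat_by_leaf, leaf_counter = leaf_counter)
  if (expr$op == "and") return(Reduce(`&`, kids))
  if (expr$op == "or") return(Reduce(`|`, kids))
  # IF-THEN: true while the antecedent is unsatisfied; once the antecedent is
  # first satisfied, true from the consequent's first satisfaction at or
  # after that frame
  avec <- kids[[1]]; cvec <- kids[[2]]
  ahit <- which(avec)
  if (length(ahit) == 0) return(rep(TRUE, length(cand)))
  afirst <- cand[ahit[1]]
  chit <- which(cvec & cand >= afirst)
  out <- cand < afirst
  if (length(chit) > 0) out <- out | cand >= cand[chit[1]]
  out
}

# evaluate one anchor; returns NULL or list(start, end)
fire_anchor <- function(i, expr, leaves, prep, times, lim_excl, w_max, n) {
  jm <- findInterval(times[i] + w_max, times)
  hi <- min(lim_excl[i], jm, n)
  if (hi <= i) return(NULL)
  cand <- (i + 1L):hi
  cand <- cand[times[cand] - times[i] < w_max]
  if (length(cand) == 0) return(NULL)
  sat <- vapply(leaves, function(cond) {
    leaf_sat_index(cond, prep[[leaf_signature(cond)]], times, i, cand)
  }, numeric(1))
  if (all(!is.finite(sat))) return(NULL)
  counter <- new.env(parent = emptyenv()); counter$i <- 1L
  truth <- expr_truth(expr, cand, sat, counter)
  anyleaf <- cand >= min(sat)
  hit <- which(truth & anyleaf)
  if (length(hit) == 0) return(NULL)
  end <- cand[hit[1]]
  list(start = as.integer(min(sat[sat <= end])), end = as.integer(end))
}

#' Match a rule against a skeleton stream
#'
#' Scans the stream with the sliding-window semantics described in the
#' package vignette and returns one row per detected movement. Matches of a
#' rule never overlap, and a continuous supra-threshold movement is counted
#' once.
#'
#' @param stream A nonempty [skeleton_stream()].
#' @param rule An `fms_rule`.
#' @return A tibble with columns `rule`, `start_s`, `end_s`, `start_frame`,
#'   `end_frame`, `anchor_frame`.
#' @export
#' @examples
#' cfg <- fms_condition_config(seed = 7)
#' sim <- simulate_session(cfg)
#' nrow(match_rule(sim$stream, builtin_jump()))
match_rule <- function(stream, rule) {
  if (!is_rule(rule)) abort_validation("rule must be an fms_rule")
  n <- n_frames(stream)
  if (n == 0) abort_validation("stream must be nonempty")
  leaves <- rule_leaves(rule$expr)
  prep <- prep_leaves(stream, leaves)
  times <- frame_times(stream)
  excl <- excluded_frames(stream)
  lim_excl <- exclusion_limits(excl)
  w_max <- max(vapply(leaves, function(l) l$window_s, numeric(1)))

  starts <- ends <- anchors <- integer(0)
  i <- 1L
  suppress <- FALSE
  while (i <= n) {
    if (excl[i]) {
      suppress <- FALSE
      i <- i + 1L
      next
    }
    res <- fire_anchor(i, rule$expr, leaves, prep, times, lim_excl, w_max, n)
    if (!is.null(res)) {
      if (!suppress) {
        starts <- c(starts, res$start)
        ends <- c(ends, res$end)
        anchors <- c(anchors, i)
        suppress <- TRUE
        i <- res$end  # resume at the match's end frame
      } else {
        i <- i + 1L
      }
    } else {
      suppress <- FALSE
      i <- i + 1L
    }
  }
  tibble::tibble(
    rule = rep(rule$name, length(starts)),
    start_s = times[starts], end_s = times[ends],
    start_frame = starts, end_frame = ends, anchor_frame = anchors
  )
}

#' Match a set of rules and summarise counts
#'
#' Each rule is evaluated independently over the whole stream; the result is
#' a match table carrying per-rule counts and the stream's metadata.
#'
#' @param stream A nonempty [skeleton_stream()].
#' @param rules A list of `fms_rule`s with unique names (default: the
#'   built-in jump and sidestep rules).
#' @return An `fms_matches` tibble (columns as [match_rule()]) with
#'   attributes `counts` (named integer vector over all rules, including
#'   zero-count ones) and `metadata`.
#' @export
match_all <- function(stream, rules = builtin_rules()) {
  if (is_rule(rules)) rules <- list(rules)
  nms <- vapply(rules, function(r) r$name, character(1))
  if (anyDuplicated(nms)) {
    abort_validation(paste0("duplicate rule name: ", nms[duplicated(nms)][1]))
  }
  results <- lapply(rules, function(r) match_rule(stream, r))
  out <- if (length(results) == 0) {
    tibble::tibble(rule = character(0), start_s = numeric(0),
                   end_s = numeric(0), start_frame = integer(0),
                   end_frame = integer(0), anchor_frame = integer(0))
  } else {
    dplyr::bind_rows(results)
  }
  counts <- stats::setNames(
    vapply(results, nrow, integer(1)) |> as.integer(),
    nms
  )
  structure(
    out,
    class = c("fms_matches", class(tibble::tibble())),
    counts = counts,
    metadata = list(participant = attr(stream, "participant"),
                    condition = attr(stream, "condition"),
                    camera = attr(stream, "camera"))
  )
}

#' @export
print.fms_matches <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("<fms_matches: ",
      paste(names(counts), counts, sep = " = ", collapse = ", "),
      ">\n", sep = "")
  NextMethod()
}

#' @rdname match_all
#' @param matches An `fms_matches` table.
#' @export
match_counts <- function(matches) attr(matches, "counts")

#' Write a match summary to JSON or CSV
#'
#' JSON layout: `{rule: {count, matches: [{start_s, end_s}]}}`. CSV layout:
#' flat `rule,start_s,end_s`.
#'
#' @param matches An `fms_matches` table from [match_all()].
#' @param path Destination file.
#' @export
write_matches_json <- function(matches, path) {
  counts <- attr(matches, "counts")
  out <- lapply(names(counts), function(nm) {
    rows <- matches[matches$rule == nm, c("start_s", "end_s")]
    list(count = unname(counts[[nm]]),
         matches = as.data.frame(rows))
  })
  names(out) <- names(counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_matches_json
#' @export
write_matches_csv <- function(matches, path) {
  utils::write.csv(as.data.frame(matches)[, c("rule", "start_s", "end_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matches_json
#' @export
read_matches_json <- function(path) {
  if (!file.exists(path)) {
    abort_validation(paste0("match summary not found: ", path))
  }
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- lapply(names(rec), function(nm) {
    m <- rec[[nm]]$matches
    if (NROW(m) == 0) {
      tibble::tibble(rule = character(0), start_s = numeric(0),
                     end_s = numeric(0))
    } else {
      tibble::tibble(rule = nm, start_s = m$start_s, end_s = m$end_s)
    }
  })
  counts <- vapply(rec, function(m) as.integer(m$count), integer(1))
  structure(
    dplyr::bind_rows(rows),
    class = c("fms_matches", class(tibble::tibble())),
    counts = counts,
    metadata = list()
  )
}
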